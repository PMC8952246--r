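---
title: "Models and methods behind gxpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gxpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxpr)
```

`gxpr` is a headless engine for the routine downstream analyses of
quantitative omics tables: expression profiles, replicate quality control,
overrepresentation analysis, and pathway-sketch visualization. This
vignette explains the statistical choices, the knobs that matter, what the
synthetic-data generator does and does not emulate, and the places where the
design was genuinely open.

## The input model

A quantification table has one row per entity (transcript or metabolite)
and one column per sample. The experimental design lives in the column
names: tokens joined by a separator (default `"."`), parsed from the
right — last token the replicate index, second-to-last the *x-axis factor*
level (the factor whose levels become x-axis ticks, typically treatment or
time), any remaining leading tokens *group factors* (species, genotype).
Right-anchored parsing means any number of group factors, including none,
works without declaring a count. The separator must not occur inside factor
values; it is configurable (e.g. `"*"`) for designs whose level names
contain dots.

Quantification cells must all be finite numbers: a missing count almost
always indicates an upstream join or export problem, and silently imputing
it would mask that. The optional information table is deliberately laxer —
numeric annotation cells may be empty (`NA`), and a column is typed numeric
exactly when every non-empty cell parses as a number. Non-numeric columns
are free text; flagging some as *categorical* (`categorical_columns`)
changes nothing computationally, it only records intent (term indexing and
search treat text and categorical alike), and the session bundle preserves
the flag.

Identifiers present in only one of the two tables are kept but excluded
from joint operations, with a warning; the alternative (hard error) would
make the common case of annotating a subset of the transcriptome
unnecessarily painful.

## Profiles and error bars

Replicates sharing a (group-combination, x-level) pair form a bin; a
profile point is the bin's arithmetic mean with an error bar of ± one
sample standard deviation (denominator *n* − 1). SD rather than SEM is the
default because expression bar plots conventionally show data spread, not
estimator precision; `spread = "sem"` switches. Single-replicate bins get
spread 0 rather than NA so rendering needs no special case. The x-axis
order is taken from the settings when supplied, otherwise first appearance
in the header.

## Likeness of replicates

Values are optionally z-transformed per entity (mean 0, sample SD 1).
Constant rows cannot be scaled; they become all-zero and are flagged,
keeping the matrix shape stable for downstream code.

Two likeness metrics are offered between sample (or, transposed, entity)
vectors: Euclidean distance, and the correlation distance
*d* = 1 − |*c*| with *c* the Pearson correlation (Spearman available).
Folding the sign means perfect anticorrelation counts as maximal likeness —
useful when co-regulated and counter-regulated entities should cluster
together. The flip side, worth knowing: a two-group design in which the
groups are strongly *anti*-correlated after z-transformation is invisible
to this metric by construction. That is why the planted-structure test
below uses the Euclidean route.

Agglomerative clustering is implemented in-package (Lance–Williams
updates) rather than delegated, because the package guarantees a
deterministic merge order: among equally close pairs, the pair whose
clusters contain the lowest original column indices merges first. Single,
complete, average (default — a reasonable compromise between chaining and
crowding) and Ward linkage are available; Ward follows the `ward.D2`
convention (updates on squared distances, reported heights are square
roots), which the test suite verifies against an independent
implementation. Dendrograms export to Newick with branch lengths equal to
height differences, so the tree is ultrametric with tip depth equal to the
root height.

The heatmap displays correlation coefficients in correlation mode (the
more informative quantity; the distance is a lossy fold of it) and
distances in Euclidean mode, permuted to dendrogram leaf order.

PCA treats samples as observations and every entity as a variable — no
pre-filtering of entities. Data are centered (and optionally z-scaled) and
decomposed by SVD; explained variance fractions are the normalized squared
singular values, so they are non-increasing and sum to one by
construction. Because singular vectors are sign-ambiguous, the package
fixes each component deterministically: the loading of largest magnitude
is made positive. Tests compare scores against an
eigendecomposition-of-covariance oracle up to that sign.

## Overrepresentation analysis

The selection of entities of interest is a conjunction of clauses
(numeric comparisons, text equality/substring, or an explicit id list);
missing numeric cells never satisfy a clause. For each term of the chosen
annotation column (multi-valued cells split on the configured delimiter),
a 2×2 table is formed:

|              | annotated | not annotated |
|--------------|-----------|---------------|
| selected     | a         | b             |
| not selected | c         | d             |

with the background *N* = a+b+c+d being **all** rows of the information
table, including entities carrying no term in the tested column — the
background is the genome/metabolome, not the annotated subset.

The test is one-sided ("greater") only: p sums the hypergeometric
probabilities of the observed table and every table with larger *a* at
fixed margins, until an off-diagonal cell hits zero. The pmf is computed
via log-gamma and the sum accumulated in log space, so p-values remain
positive down to the double floor even at genome scale. A two-sided option
is deliberately absent: enrichment questions are directional, and the
one-sided formulation keeps the "more extreme table" enumeration exact and
transparent.

Bonferroni (min(1, m·p)) and Benjamini–Hochberg (step-up, monotone, capped
at 1) corrections are implemented directly; terms with a = 0 are still
reported (p near 1) so the full table remains available, and the
significance flag at the chosen alpha (default 0.05) only marks the subset
a user interface would show first.

## MapMan-style sketches

A sketch layout is this package's own small JSON schema: named areas, each
anchored on a canvas and owning a dot-separated numeric bin prefix. A gene
falls into an area when one of its bins equals the prefix or extends it by
whole components — matching is component-wise, so bin `1.10` does not fall
under prefix `1.1`. Among several matching areas the longest prefix (most
specific function) wins; a gene is placed exactly once (duplication across
areas is deliberately off — one box per gene keeps the summary statistic a
statement about genes, not placements). Every input gene ends up placed,
unassigned (no/malformed/unmatched bins), or excluded (no value), and the
three sets partition the input — a conservation property the tests
enforce.

Colors: divergent blue–white–red over [−L, +L] (the down/up-regulation
convention for log fold changes; L is user-chosen because fold-change
scales are study-specific), or sequential white–red from 0 or the first
quartile up to the third quartile. Quartiles use linear interpolation
between order statistics (R's default type 7) — stated here because
quartile conventions differ and the sequential domain depends on it.
Values outside a domain clamp to the end colors; the mapping is monotone.

## The session bundle

A session (settings, both tables, plot specs, analysis results) exports to
a single zip archive containing `GXP_settings.json`, full-precision TSVs
(`%.17g`, bit-exact on reload) and JSON documents. The archive is written
by a small built-in store-only zip writer (no external `zip` binary is
assumed) with fixed timestamps, so exports are byte-deterministic. Plot
specs and analysis results use jsonlite's type-preserving serialization at
17 significant digits, which round-trips IEEE doubles exactly; the
export→import cycle is deep-equality tested. The schema is versioned and
imports refuse unknown versions. Reading the original browser tool's
bundles is out of scope (their schema is unpublished).

## The synthetic-data generator

`fixture_design()` states a small but recognizable world: two species
(group factor), four x-levels (`ctrl1`, `cold`, `eL`, `N-`), three
replicates per bin, 200 entities. Quantifications are log-normal:
baseline log2 level uniform on [4, 12] (TPM-like dynamic range),
iid replicate noise of SD 0.5 log2, mild shared condition effects of SD
0.15 log2, and a planted set of 40 differentially expressed entities
shifted by −2.5 log2 (= 5 noise SDs, strong down-regulation) in the second
species. A planted term annotates 30 of the 40 DE entities and 10 of the
remaining 160; the info table's `log2FC` column equals the planted shift
plus 0.1-SD scatter, so `log2FC < -1` recovers the DE set exactly (the
clusters sit > 5 scatter-SDs from the threshold on both sides).

Two sizing notes. The condition-effect SD is set an order of magnitude
below the planted group shift: the generator's contract is that the
planted two-group structure is the dominant signal (recoverable by the
root split of the dendrogram and the sign of PC1 in every seeded run), and
treatment effects drawn on the same scale as the species shift would
occasionally dominate it — the world is stated as "species difference ≫
treatment response ≫ noise". Secondly, all planted-effect defaults scale
proportionally with `n_entities` so small test fixtures stay meaningful.

What the generator does *not* emulate: count-specific mean–variance
relationships (negative-binomial dispersion), library-size variation,
correlated gene modules, batch effects, or realistic annotation
hierarchies. A green recovery test therefore establishes that the
algorithms find a strong planted signal — not that they would behave
identically on real RNA-seq counts.

## Numerical choices and degenerate inputs

* Fisher/hypergeometric arithmetic: log-gamma + log-sum-exp; exact to
  < 1e−12 against rational-arithmetic enumeration for all tables N ≤ 30.
* Clustering tie-break: lexicographic (distance, lowest original indices),
  tolerance 1e−12 on distance ties.
* z-transform of a constant row: zeros + flag (not dropped, not NA).
* Correlation of a constant vector: error naming the offending sample —
  there is no principled correlation value to substitute.
* PCA of collinear samples: fine (trailing components have zero variance);
  fewer than two samples: error.
* Empty ORA selection: error (no test is possible, and returning an empty
  table would read as "nothing enriched").
* SVG output is written atomically (temp file + rename) and numbers are
  formatted at fixed precision, so renders are reproducible byte-for-byte.

## Known limitations

One x-axis factor (as in the input grammar); no missing-value imputation;
no two-sided or rank-based (GSEA-style) enrichment; no term-hierarchy-aware
corrections; sketches are static SVG without interactivity; the CLI reads
whole bundles per invocation rather than holding state.
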