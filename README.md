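# gxpr

Headless analysis engine for quantitative omics tables — bulk RNA-seq
expression or metabolite concentrations. `gxpr` is aimed at the step *after*
upstream quantification pipelines: you have a counts/TPM table and perhaps an
annotation table, and you want expression profiles with error bars,
replicate quality control (hierarchical clustering, PCA), overrepresentation
analysis of annotation terms, and MapMan-style pathway sketches — all
scriptable, deterministic, and exportable as a single self-contained session
bundle.

## What it computes

**Input grammar.** Sample column names encode the experimental design,
tokens separated by a configurable character (default `.`): the last token
is the replicate index, the second-to-last the *x-axis factor* level (e.g.
treatment), leading tokens are *group factors* (e.g. species). So
`S_lycopersicum.ctrl1.1` is replicate 1 of *S. lycopersicum* under `ctrl1`.

**Profiles.** Replicates sharing a (group, x) combination form a bin;
profile plots show bin means with error bars (sample SD by default, SEM
optional) as bars, lines, or stacked colored curves, one panel per group
combination.

**Replicate likeness.** Rows can be z-transformed (mean 0, SD 1 per
entity). Sample–sample likeness uses either Euclidean distance or the
correlation distance

```
d_ik = 1 − |c_ik|
```

so complete correlation *and* complete anticorrelation count as maximal
likeness. Agglomerative clustering (single/complete/average/Ward linkage,
deterministic tie-breaking) yields a dendrogram + heatmap; PCA (SVD of
centered samples, deterministic sign convention) yields a scatter with
percent variance per axis.

**Overrepresentation analysis.** For a selection of entities (filter
criterion or explicit id list) and each annotation term, a 2×2 contingency
table against the whole-table background is tested with a from-scratch
one-sided Fisher's exact test: the hypergeometric probabilities

```
P(X = k) = C(K,k) · C(N−K, n−k) / C(N,n)
```

of the observed and all more extreme tables are summed (log-space, no
underflow to machine zero above the double range), then adjusted with
Bonferroni or Benjamini–Hochberg.

**MapMan sketches.** Genes map to diagram areas via component-wise prefix
matching of dot-separated bin paths (`1.1.1.1.1` falls under `1.1`;
`1.10` does not). One colored box per gene, divergent (blue–white–red over
±L, for log-FC) or sequential (white–red over `[0,Q3]` or `[Q1,Q3]`)
color scale, legend, and a five-number summary strip.

**Sessions.** Settings, both tables, plot specs and analysis results export
into one versioned zip bundle (`GXP_settings.json` inside) and import back
to a deeply equal session.

## Worked example

```r
library(gxpr)

# deterministic synthetic two-species stress experiment + truth record
fx <- generate_fixture(fixture_design(seed = 1))
fx$expression
#> gxp expression matrix: 200 entities x 24 samples [TPM]
#>   x values: ctrl1, cold, eL, N-

# replicate QC: cluster and PCA on z-transformed values
z    <- z_transform(fx$expression)
dend <- hierarchical_cluster(euclidean_distance(z), "ward")
root_split(dend)$left[1:3]
#> [1] "S_lycopersicum.ctrl1.1" "S_lycopersicum.ctrl1.3" "S_lycopersicum.eL.3"
run_pca(z)
#> gxp PCA: 24 samples, PC1 18.6%, PC2 6.5%

# which functions are enriched among down-regulated genes?
ora <- run_ora(fx$info, "log2FC < -1", "mapman_bin")
ora
#> gxp overrepresentation analysis on column "mapman_bin": 14 terms,
#>   1 significant at alpha=0.05 (benjamini_hochberg)
#>        term  a term_size selection_size   N     p_raw     p_adj significant
#> 1 1.1.1.1.1 30        40             40 200 9.607e-19 1.345e-17        TRUE
#> 2       5.2 10        29             40 200 3.640e-02 2.162e-01       FALSE
#> ...
```

The top-ranked term `1.1.1.1.1` is the planted enrichment
(`fx$truth$enriched_term`): 30 of the 40 selected genes carry it versus 10
of the 160 background genes, hence the vanishing adjusted p-value. The
Fisher worked example `fisher_exact_greater(3, 1, 1, 3)` returns
`0.2428571` = 17/70, the sum over the observed table and the single more
extreme one.

## Command line

```sh
GXP=$(Rscript -e 'cat(system.file("cli/gxp", package="gxpr"))')
$GXP fixtures --out fx --seed 42
$GXP load --counts fx/quantification.tsv --info fx/info.tsv --unit TPM --out db.zip
$GXP cluster --db db.zip --metric euclidean --linkage ward --z --out heatmap.svg --newick tree.nwk
$GXP pca     --db db.zip --z --out pca.svg
$GXP ora     --db db.zip --select "log2FC < -1" --terms-column mapman_bin --out ora.tsv
$GXP mapman  --db db.zip --layout $(Rscript -e 'cat(system.file("extdata/metabolism_overview_mini.json", package="gxpr"))') \
             --value-column log2FC --scale divergent --limit 2 --out mm.svg
```

Exit codes: 0 success, 1 runtime error, 2 usage error.

## Layout fixtures

The two sketch layouts under `inst/extdata/` (`photosynthesis_mini.json`,
`metabolism_overview_mini.json`) are small synthetic hand-made layouts that
exercise the full mapping logic; they are not redistributed MapMan Store
sketches.
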