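{
  "name": "metabolism_overview_mini",
  "schema_version": "1.0",
  "comment": "synthetic hand-made mini layout (not a MapMan Store sketch)",
  "canvas": { "width": 760, "height": 520 },
  "areas": [
    { "id": "photosynthesis", "bin_prefix": "1",        "x": 40,  "y": 50,  "grid_width": 10, "label": "Photosynthesis" },
    { "id": "cellwall",       "bin_prefix": "21",       "x": 40,  "y": 220, "grid_width": 10, "label": "Cell wall" },
    { "id": "lipid",          "bin_prefix": "5",        "x": 280, "y": 50,  "grid_width": 10, "label": "Lipid metabolism" },
    { "id": "amino",          "bin_prefix": "4",        "x": 280, "y": 220, "grid_width": 10, "label": "Amino acid metabolism" },
    { "id": "terpenes",       "bin_prefix": "9.1",      "x": 520, "y": 50,  "grid_width": 8,  "label": "Terpenoids" },
    { "id": "umamit",         "bin_prefix": "24.2.1.5", "x": 520, "y": 220, "grid_width": 6,  "label": "UmamiT transporters" },
    { "id": "secondary",      "bin_prefix": "9",        "x": 520, "y": 360, "grid_width": 8,  "label": "Secondary metabolism" }
  ]
}
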