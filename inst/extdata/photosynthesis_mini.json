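{
  "name": "photosynthesis_mini",
  "schema_version": "1.0",
  "comment": "synthetic hand-made mini layout (not a MapMan Store sketch)",
  "canvas": { "width": 640, "height": 420 },
  "areas": [
    { "id": "lhc",          "bin_prefix": "1.1.1", "x": 40,  "y": 50,  "grid_width": 8, "label": "Light harvesting complexes" },
    { "id": "photosystems", "bin_prefix": "1.1",   "x": 40,  "y": 170, "grid_width": 8, "label": "Photophosphorylation" },
    { "id": "calvin",       "bin_prefix": "1.3",   "x": 280, "y": 50,  "grid_width": 8, "label": "Calvin cycle" },
    { "id": "photoresp",    "bin_prefix": "1.2",   "x": 280, "y": 170, "grid_width": 8, "label": "Photorespiration" },
    { "id": "tetrapyrrole", "bin_prefix": "7.10",  "x": 480, "y": 50,  "grid_width": 6, "label": "Tetrapyrrole synthesis" }
  ]
}
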