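{
  "comment": "Small demonstration study: one drug arm vs its matched vehicle on a coarse grid.",
  "groups": {
    "group": ["MSX122", "DMSO_CD_ip"],
    "treatment": ["MSX-122 10 mg/kg i.p.", "10% DMSO/45% CD i.p."],
    "matched_vehicle": ["DMSO_CD_ip", ""],
    "n": [5, 5]
  },
  "timepoints": [20],
  "stage_table": {
    "group": ["MSX122", "DMSO_CD_ip"],
    "week": [20, 20],
    "consolidation_fraction": [0.285, 0.95]
  },
  "histology_noise_sd": 0.5,
  "mortality_prob": {"MSX122": 0, "DMSO_CD_ip": 0},
  "assays": {
    "assay": ["CXCL12_BALF"],
    "days": [[0, 1, 3, 7, 14, 28]],
    "mean_by_day": [[0.5, 1.2, 2.0, 2.6, 2.2, 1.5]],
    "sd": [0.25],
    "n_replicates": [6]
  },
  "phantom": {
    "grid_shape": [48, 48, 40],
    "spacing_mm": [0.25, 0.25, 0.25],
    "irradiated_side": "right"
  },
  "n_patch_seeds": 3,
  "rng_seed": 1
}
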