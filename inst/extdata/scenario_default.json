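{
  "comment": "Default synthetic scenario: titratable Asp-Asp blocked tripeptide under acidic conditions. Basin weights follow the typical ranking of the four dominant Ramachandran regions; the state model samples the four carboxyl protonation sites at 96% syn / 4% anti with a 0.1 per-frame trial-switch probability (0.01/ps trial cadence at a 10 ps frame interval).",
  "residue": "ASP",
  "n_frames": 50000,
  "n_coord_frames": 300,
  "spacing": 1,
  "temperature": 300,
  "seed": 20260926,
  "charge_scenario": "backbone_mismatch",
  "basins": [
    {"label": "PII",    "center": [-75, 150],  "kappa": [100, 100], "weight": 0.4},
    {"label": "alphaR", "center": [-57, -47],  "kappa": [100, 100], "weight": 0.3},
    {"label": "C7eq",   "center": [-80, 80],   "kappa": [100, 100], "weight": 0.2},
    {"label": "C5",     "center": [-150, 150], "kappa": [100, 100], "weight": 0.1}
  ],
  "state_model": {
    "labels": ["syn-O2", "syn-O1", "anti-O2", "anti-O1"],
    "fractions": [0.48, 0.48, 0.02, 0.02],
    "switch_prob": 0.1
  }
}
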