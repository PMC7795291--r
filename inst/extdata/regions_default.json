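{
  "comment": "Default nine-region partition of the phi/psi torus (degrees). Rectangular convention placing canonical region centers: C5 (-150,150), PII (-75,150), C7eq (-80,80), alphaR (-57,-47), alphaPrime (-90,-120), alphaL (60,40), C7axial (75,-60), alphaD (90,140), beta2 (90,-140). Vertices are in an unwrapped chart; coordinates beyond +-180 wrap around the seam. Regions are tested in listed (priority) order; boundaries belong to the earlier region.",
  "regions": [
    {"label": "C5",         "vertices": [[-180, 100], [-110, 100], [-110, 220], [-180, 220]]},
    {"label": "PII",        "vertices": [[-110, 100], [0, 100], [0, 220], [-110, 220]]},
    {"label": "C7eq",       "vertices": [[-180, 30], [0, 30], [0, 100], [-180, 100]]},
    {"label": "alphaR",     "vertices": [[-180, -100], [0, -100], [0, 30], [-180, 30]]},
    {"label": "alphaPrime", "vertices": [[-180, -140], [0, -140], [0, -100], [-180, -100]]},
    {"label": "alphaL",     "vertices": [[0, 0], [180, 0], [180, 100], [0, 100]]},
    {"label": "C7axial",    "vertices": [[0, -100], [180, -100], [180, 0], [0, 0]]},
    {"label": "alphaD",     "vertices": [[0, 100], [180, 100], [180, 180], [0, 180]]},
    {"label": "beta2",      "vertices": [[0, -180], [180, -180], [180, -100], [0, -100]]}
  ]
}
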