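{
  "materials": {
    "air": {
      "mu_a": 0,
      "mu_s": 0,
      "g": 0,
      "n": 1
    },
    "normal_tissue": {
      "mu_a": 0.7,
      "mu_s": 36.7,
      "g": 0.9,
      "n": 1.38
    },
    "tumour": {
      "mu_a": 2.3,
      "mu_s": 21.2,
      "g": 0.9,
      "n": 1.38
    },
    "gold_nanorods": {
      "mu_a": 12,
      "mu_s": 1.2,
      "g": 0.9,
      "n": 1.38
    },
    "tumour_gnr": {
      "mu_a": 14.3,
      "mu_s": 22.4,
      "g": 0.9,
      "n": 1.38
    }
  },
  "ambient": "air",
  "entities": [
    {
      "label": "flesh",
      "shape": "cuboid",
      "center": [0, 0, 0],
      "size": [6, 6, 6],
      "material": "normal_tissue",
      "priority": 1
    },
    {
      "label": "tumour",
      "shape": "ellipsoid",
      "center": [0, 0, 1.75],
      "semi_axes": [0.5, 0.5, 0.25],
      "material": "tumour",
      "priority": 2
    }
  ],
  "source": {
    "center": [0, 0, 4],
    "radius": 3,
    "n_fan": 16,
    "power": 1,
    "direction": [0, 0, -1]
  },
  "grid": {
    "extent": [-5, 5],
    "n_cells": 101
  },
  "transport": {
    "packets": 10000000,
    "seed": 1,
    "w_min": 0.0001,
    "p_survive": 0.1
  },
  "heat": {
    "duration": 600,
    "record_interval": 20,
    "boundary": "clamped-sides",
    "params": {
      "rho": 1079,
      "c": 3540,
      "k": 0.53,
      "rho_b": 1060,
      "c_b": 3617,
      "w_b": 0.01,
      "T_a": 37
    }
  },
  "dose": {
    "r_above": 0.5,
    "r_below": 0.25,
    "anchor_minutes": 120,
    "anchor_fraction": 0.1
  }
}
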