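{
  "_comment": "Literature-informed default N2O pathway endmembers (permil): [mean, sd] per signal. Editable; mu uses the negative-epsilon convention (residual N2O enriched by mu*ln(r) during partial reduction). These are synthetic stand-in defaults, not a published compilation.",
  "pathways": {
    "aN": { "d15n_bulk": [-47, 6], "d18o": [35, 5], "sp": [30, 4] },
    "bN": { "d15n_bulk": [-55, 6], "d18o": [23, 5], "sp": [33, 4] },
    "nD": { "d15n_bulk": [-47, 6], "d18o": [13, 5], "sp": [-2, 4] },
    "bD": { "d15n_bulk": [-15, 5], "d18o": [43, 5], "sp": [5, 5] }
  },
  "mu": { "d15n_bulk": [-6, 1], "d18o": [-15, 2], "sp": [-5, 1] },
  "priors": { "dirichlet_alpha": [1, 1, 1, 1], "r_min": 0.1 },
  "mcmc": { "chains": 4, "iter": 20000, "burn_frac": 0.5 },
  "atmosphere": { "d15n_bulk": 6.3, "d18o": 44.4, "sp": 18.7, "c_n2o": 7.0 }
}
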