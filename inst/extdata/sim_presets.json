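{
  "human": {
    "producer": "human",
    "length0": 140,
    "content_frac": 0.45,
    "length_decay": 0.75,
    "p_surv": 0.42,
    "p_syn": 0.3,
    "aoa_shift": 0,
    "innovation_rate": null,
    "negation_rates": {
      "happy": 0.0088, "mildly_happy": 0.0088,
      "mildly_sad": 0.0113, "sad": 0.0113
    },
    "valence_bias": {
      "happy": 0.3, "mildly_happy": 0.15,
      "mildly_sad": -0.15, "sad": -0.3
    },
    "rating": {
      "beta0": 0, "beta1": 0, "gamma": 0, "sigma": 0.3, "tau": 1,
      "scale_min": 0, "scale_max": 100, "center": 50, "spread": 12,
      "rater_sd": 10
    }
  },
  "llm": {
    "producer": "llm",
    "length0": 140,
    "content_frac": 0.45,
    "length_decay": 0.95,
    "p_surv": 0.9,
    "p_syn": 0.4,
    "aoa_shift": 1.5,
    "innovation_rate": null,
    "negation_rates": {
      "happy": 0.0036, "mildly_happy": 0.0036,
      "mildly_sad": 0.0058, "sad": 0.0058
    },
    "valence_bias": {
      "happy": 0.3, "mildly_happy": 0.15,
      "mildly_sad": -0.15, "sad": -0.3
    },
    "rating": {
      "beta0": 0, "beta1": 0, "gamma": 0, "sigma": 0.3, "tau": 1,
      "scale_min": 0, "scale_max": 100, "center": 50, "spread": 12,
      "rater_sd": 10
    }
  }
}
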