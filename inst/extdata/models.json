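{
  "schema_version": "1.0",
  "description": "Identified SOPDT elbow-plant parameters per subject (zeta = 1 throughout). 'demo' is the worked-example transfer function used in the validation experiments.",
  "models": {
    "A": {"k": 11.22, "omega_n": 20.5, "zeta": 1.0, "tau": 0.050},
    "B": {"k": 8.91, "omega_n": 20.5, "zeta": 1.0, "tau": 0.045},
    "C": {"k": 1.73, "omega_n": 31.4, "zeta": 1.0, "tau": 0.090},
    "D": {"k": 1.04, "omega_n": 14.0, "zeta": 1.0, "tau": 0.100},
    "E": {"k": 6.61, "omega_n": 25.1, "zeta": 1.0, "tau": 0.100},
    "F": {"k": 6.96, "omega_n": 18.0, "zeta": 1.0, "tau": 0.095},
    "demo": {"k": 11.22, "omega_n": 20.5, "zeta": 1.0, "tau": 0.050}
  }
}
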