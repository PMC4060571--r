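{
  "schema_version": "1.0",
  "description": "Natural angular frequency of the identified elbow plant at three EAA activity levels (subject A): joint stiffness, and with it omega_n, grows with total drive.",
  "subject": "A",
  "anchors": [
    {"a_e": 0.5, "omega_n": 14.3},
    {"a_e": 0.8, "omega_n": 19.0},
    {"a_e": 1.0, "omega_n": 20.5}
  ]
}
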