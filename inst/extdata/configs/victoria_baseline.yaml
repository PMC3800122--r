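scenarios:
  - name: victoria_baseline
    type: logistic
    r: 0.73
    K_tonnes: 963200
    N0_tonnes: 0.00039
    t0_year: 1954
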