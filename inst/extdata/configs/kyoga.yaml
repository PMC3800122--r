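scenarios:
  - name: kyoga_backcast
    type: logistic
    r: 0.73
    K_tonnes: 24080
    N0_fish: 147
    length_cm: 30
    t0_year: 1955
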