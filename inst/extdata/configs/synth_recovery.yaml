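scenarios:
  - name: synthetic_recovery
    type: synth
    r: 0.73
    K_tonnes: 963200
    N0_tonnes: 0.00039
    t0_year: 1954
    q: 1.0
    noise_sd: 0.3
    seed: 42
    first_year: 1960
    last_year: 1979
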