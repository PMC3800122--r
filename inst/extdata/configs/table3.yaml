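scenarios:
  - name: depensation_table
    type: depensation_grid
    r: 0.73
    K_tonnes: 963200
    N0_tonnes: 0.00039
    t0_year: 1954
    f_values: [1.0, 0.9, 0.8, 0.7, 0.5]
    c_values: [0.5, 1.0, 2.0]
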