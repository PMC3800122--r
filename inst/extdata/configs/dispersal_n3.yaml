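scenarios:
  - name: dispersal_wave_n3
    type: dispersal
    r: 0.73
    K_tonnes: 963200
    N0_tonnes: 0.00039
    t0_year: 1954
    n_cells: 3
    m: 0.005
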