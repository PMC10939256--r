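# Default 9-pool library for brain tissue at 9.4 T.
# Editable configuration with literature-typical values, not fitted constants.
# fraction: relative proton fraction (water = 1)
# k_exch:   solute -> water exchange rate (s^-1)
# t1, t2:   relaxation times (s)
# The mt center is set at load time from mt_mode (0 or -2.3 ppm).
pools:
  - {name: water,    delta_ppm:  0.0,  fraction: 1.0,     k_exch: 0,    t1: 2.0,  t2: 0.045}
  - {name: amine,    delta_ppm:  3.0,  fraction: 0.0009,  k_exch: 5500, t1: 1.3,  t2: 0.005}
  - {name: cr,       delta_ppm:  2.0,  fraction: 0.0005,  k_exch: 950,  t1: 1.3,  t2: 0.01}
  - {name: pcr,      delta_ppm:  2.64, fraction: 0.0004,  k_exch: 140,  t1: 1.3,  t2: 0.01}
  - {name: amide,    delta_ppm:  3.5,  fraction: 0.0007,  k_exch: 30,   t1: 1.3,  t2: 0.01}
  - {name: gaba,     delta_ppm:  2.91, fraction: 0.0004,  k_exch: 1200, t1: 1.3,  t2: 0.01}
  - {name: noe_m3p5, delta_ppm: -3.5,  fraction: 0.005,   k_exch: 20,   t1: 1.3,  t2: 0.0005}
  - {name: noe_m1p6, delta_ppm: -1.6,  fraction: 0.001,   k_exch: 10,   t1: 1.3,  t2: 0.001}
  - {name: mt,       delta_ppm:  0.0,  fraction: 0.05,    k_exch: 30,   t1: 1.0,  t2: 0.00001}
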