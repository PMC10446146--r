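# Reference room scenario: 20 m3 room ventilated at 0.5 1/h, two
# photocatalytic purifiers recirculating 10 m3/h each across three 90 cm2
# honeycombs, emitting at the LOQ-bounded release factor 0.185 ng/(m2 m3),
# with no particle filtration by the purifiers themselves.
room:
  volume_m3: 20
  ach_per_h: 0.5
purifiers:
  - flow_m3h: 10
    n_units: 3
    area_per_unit_m2: 0.009
    release_factor_ngm2m3: 0.185
    filtration_efficiency: 0
  - flow_m3h: 10
    n_units: 3
    area_per_unit_m2: 0.009
    release_factor_ngm2m3: 0.185
    filtration_efficiency: 0
oels:
  - name: proposed OEL low (0.8 ug/m3)
    value_ugm3: 0.8
    averaging: 8h_occupational
  - name: proposed OEL high (5000 ug/m3)
    value_ugm3: 5000
    averaging: 8h_occupational
  - name: proposed OEL low, 24 h population
    value_ugm3: 0.8
    averaging: 24h_population
    divisor: 3
duration_h: 10
init_conc_ngm3: 0
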