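# Default birdstrikeR model configuration (all values match the built-in
# defaults; edit a copy to customise).
likelihood_bounds: [15, 30, 50, 70]
severity_bounds: [4, 7, 14, 40]
# rows: likelihood very_low..very_high; columns: severity very_low..very_high
matrix:
  - [1, 1, 1, 2, 2]
  - [1, 1, 2, 2, 2]
  - [1, 2, 2, 2, 3]
  - [2, 2, 2, 3, 3]
  - [2, 2, 3, 3, 3]
crossing_threshold: 3
raptor_bump: true
height_stat: median
cluster_stat: max
weight_basis: total
season_months: [winter, winter, spring, spring, spring, summer, summer,
                summer, autumn, autumn, autumn, winter]
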