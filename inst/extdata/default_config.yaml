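# Reference configuration: the best-survival female right whale analysis.
vital_rates:
  sigma_calf: 0.96299
  sigma_juv: 0.97507
  sigma_adult: 0.97314
  d_calf: 1
  d_juv: 8
  d_adult: 59
  calving_interval: 4.0
  female_fraction: 0.5
projection:
  start_total: 123
  start_year: 1990
  years: 25
  reps: 1000
  seed: 20150101
  quantiles: [0.025, 0.975]
trend:
  counts_file: null
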