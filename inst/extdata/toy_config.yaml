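# Small demonstration study: two scenarios, 20 Monte Carlo samples,
# 2035-2050 horizon. Inherits all other defaults.
study:
  scenarios: ["SSP1-2.6", "SSP5-8.5"]
  n_samples: 20
  seed: 11
  horizon: [2035, 2050]
thermal:
  fit_years: [2019, 2022]
climate:
  n_members: 3
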