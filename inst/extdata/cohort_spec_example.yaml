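# Example synthetic cohort: a mixed CHC population.
n: 200
mixture:
  low: 0.45
  high: 0.4
  frail_senior: 0.15
seed: 42
as_of_date: "2019-01-01"
lookback_months: 18
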