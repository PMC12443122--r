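{
  "comment": "Canonical coding scenario: a medication taken twice daily with a 3-h safe window. The one-row formulary is synthetic (no printed row has this frequency/window pair).",
  "medication": "examplepril",
  "frequency_per_day": 2,
  "dose": [20],
  "anchor_times": ["08:00", "20:00"],
  "timezone": "UTC",
  "start_date": "2026-01-05",
  "n_days": 14,
  "formulary": "synthetic_bid3h_formulary.csv",
  "model": {
    "open_probability": 0.9,
    "delay": { "family": "lognormal", "median_minutes": 5 },
    "overdue_take_probability": 0.25,
    "snooze_probability": 0.2
  }
}
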