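{
  "_comment": "Pain-model parameters. Baseline pain declines across the three postoperative days with mild intra-day variation; anchors are NRS values at hour offsets from 09:00. relaxation_rate is the per-minute pull of pain toward (baseline - relief).",
  "dt": 5,
  "relief_cap": 8,
  "relaxation_rate": 0.05,
  "baseline_curve": {
    "anchor_hours": [0, 6, 12, 18, 24],
    "day1": [7.0, 6.8, 6.4, 6.6, 6.0],
    "day2": [6.0, 5.8, 5.4, 5.6, 5.0],
    "day3": [5.0, 4.8, 4.4, 4.6, 4.0]
  },
  "mobility_min": 0.2,
  "immobility_threshold": 9,
  "consult_hold_minutes": 180,
  "monologue": {
    "enabled": true,
    "flavor_rate": 0.02
  }
}
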