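{
  "_comment": "Synthetic default definition of the 12-item postoperative pain-management game survey (technology-acceptance style): perceived ease of use (6 items) and usefulness (6 items), 0-5 Likert, higher = better. Reported per item and as subscale medians/means.",
  "name": "popmgs",
  "type": "likert",
  "scale_min": 0,
  "scale_max": 5,
  "subscales": [
    { "id": "ease_of_use", "label": "perceived ease of use", "aggregation": "mean" },
    { "id": "usefulness",  "label": "perceived usefulness",  "aggregation": "mean" }
  ],
  "report_items": true,
  "items": [
    { "id": "EOU1", "subscale": "ease_of_use", "reverse": false },
    { "id": "EOU2", "subscale": "ease_of_use", "reverse": false },
    { "id": "EOU3", "subscale": "ease_of_use", "reverse": false },
    { "id": "EOU4", "subscale": "ease_of_use", "reverse": false },
    { "id": "EOU5", "subscale": "ease_of_use", "reverse": false },
    { "id": "EOU6", "subscale": "ease_of_use", "reverse": false },
    { "id": "USE1", "subscale": "usefulness",  "reverse": false },
    { "id": "USE2", "subscale": "usefulness",  "reverse": false },
    { "id": "USE3", "subscale": "usefulness",  "reverse": false },
    { "id": "USE4", "subscale": "usefulness",  "reverse": false },
    { "id": "USE5", "subscale": "usefulness",  "reverse": false },
    { "id": "USE6", "subscale": "usefulness",  "reverse": false }
  ]
}
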