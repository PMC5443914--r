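{
  "_comment": "Synthetic default definition of the 27-item Barriers Questionnaire II, 0-5 Likert, higher = more barriers to pain management. Subscale membership is configuration: the four subscales are named in the literature but item assignment here is a synthetic default; override to match a licensed form.",
  "name": "bqii",
  "type": "likert",
  "scale_min": 0,
  "scale_max": 5,
  "subscales": [
    { "id": "harmful_effects",       "label": "harmful effects of analgesics",   "aggregation": "mean" },
    { "id": "physiological_effects", "label": "physiological effects",           "aggregation": "mean" },
    { "id": "communication",         "label": "communication about pain",        "aggregation": "mean" },
    { "id": "fatalism",              "label": "fatalism about pain",             "aggregation": "mean" }
  ],
  "report_total": true,
  "items": [
    { "id": "BQ1",  "subscale": "harmful_effects",       "reverse": false },
    { "id": "BQ2",  "subscale": "harmful_effects",       "reverse": false },
    { "id": "BQ3",  "subscale": "harmful_effects",       "reverse": false },
    { "id": "BQ4",  "subscale": "harmful_effects",       "reverse": false },
    { "id": "BQ5",  "subscale": "harmful_effects",       "reverse": false },
    { "id": "BQ6",  "subscale": "harmful_effects",       "reverse": false },
    { "id": "BQ7",  "subscale": "harmful_effects",       "reverse": false },
    { "id": "BQ8",  "subscale": "harmful_effects",       "reverse": false },
    { "id": "BQ9",  "subscale": "physiological_effects", "reverse": false },
    { "id": "BQ10", "subscale": "physiological_effects", "reverse": false },
    { "id": "BQ11", "subscale": "physiological_effects", "reverse": false },
    { "id": "BQ12", "subscale": "physiological_effects", "reverse": false },
    { "id": "BQ13", "subscale": "physiological_effects", "reverse": false },
    { "id": "BQ14", "subscale": "physiological_effects", "reverse": false },
    { "id": "BQ15", "subscale": "physiological_effects", "reverse": false },
    { "id": "BQ16", "subscale": "physiological_effects", "reverse": false },
    { "id": "BQ17", "subscale": "physiological_effects", "reverse": false },
    { "id": "BQ18", "subscale": "physiological_effects", "reverse": false },
    { "id": "BQ19", "subscale": "physiological_effects", "reverse": false },
    { "id": "BQ20", "subscale": "physiological_effects", "reverse": false },
    { "id": "BQ21", "subscale": "communication",         "reverse": false },
    { "id": "BQ22", "subscale": "communication",         "reverse": false },
    { "id": "BQ23", "subscale": "communication",         "reverse": false },
    { "id": "BQ24", "subscale": "fatalism",              "reverse": false },
    { "id": "BQ25", "subscale": "fatalism",              "reverse": false },
    { "id": "BQ26", "subscale": "fatalism",              "reverse": false },
    { "id": "BQ27", "subscale": "fatalism",              "reverse": false }
  ]
}
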