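{
  "_comment": "Synthetic default definition of the 28-item AttrakDiff2 semantic differential (7 steps, raw 1..7, scored -3..+3). Word-pair orientation (reverse keys) is configuration: override this file to match a licensed questionnaire form. Items marked reverse=true are presented positive-pole-first.",
  "name": "attrakdiff2",
  "type": "semantic_differential",
  "scale_min": 1,
  "scale_max": 7,
  "subscales": [
    { "id": "PQ",  "label": "pragmatic quality",          "aggregation": "mean" },
    { "id": "HQI", "label": "hedonic quality-identification", "aggregation": "mean" },
    { "id": "HQS", "label": "hedonic quality-stimulation", "aggregation": "mean" },
    { "id": "ATT", "label": "attractiveness",              "aggregation": "mean" }
  ],
  "items": [
    { "id": "PQ1",  "subscale": "PQ",  "left": "technical",     "right": "human",             "reverse": false },
    { "id": "PQ2",  "subscale": "PQ",  "left": "simple",        "right": "complicated",       "reverse": true  },
    { "id": "PQ3",  "subscale": "PQ",  "left": "impractical",   "right": "practical",         "reverse": false },
    { "id": "PQ4",  "subscale": "PQ",  "left": "cumbersome",    "right": "straightforward",   "reverse": false },
    { "id": "PQ5",  "subscale": "PQ",  "left": "predictable",   "right": "unpredictable",     "reverse": true  },
    { "id": "PQ6",  "subscale": "PQ",  "left": "confusing",     "right": "clearly structured","reverse": false },
    { "id": "PQ7",  "subscale": "PQ",  "left": "unruly",        "right": "manageable",        "reverse": false },
    { "id": "HQI1", "subscale": "HQI", "left": "isolating",     "right": "connective",        "reverse": false },
    { "id": "HQI2", "subscale": "HQI", "left": "professional",  "right": "unprofessional",    "reverse": true  },
    { "id": "HQI3", "subscale": "HQI", "left": "tasteless",     "right": "stylish",           "reverse": false },
    { "id": "HQI4", "subscale": "HQI", "left": "cheap",         "right": "premium",           "reverse": false },
    { "id": "HQI5", "subscale": "HQI", "left": "alienating",    "right": "integrating",       "reverse": false },
    { "id": "HQI6", "subscale": "HQI", "left": "separates me",  "right": "brings me closer",  "reverse": false },
    { "id": "HQI7", "subscale": "HQI", "left": "unpresentable", "right": "presentable",       "reverse": false },
    { "id": "HQS1", "subscale": "HQS", "left": "conventional",  "right": "inventive",         "reverse": false },
    { "id": "HQS2", "subscale": "HQS", "left": "creative",      "right": "unimaginative",     "reverse": true  },
    { "id": "HQS3", "subscale": "HQS", "left": "cautious",      "right": "bold",              "reverse": false },
    { "id": "HQS4", "subscale": "HQS", "left": "conservative",  "right": "innovative",        "reverse": false },
    { "id": "HQS5", "subscale": "HQS", "left": "dull",          "right": "captivating",       "reverse": false },
    { "id": "HQS6", "subscale": "HQS", "left": "undemanding",   "right": "challenging",       "reverse": false },
    { "id": "HQS7", "subscale": "HQS", "left": "ordinary",      "right": "novel",             "reverse": false },
    { "id": "ATT1", "subscale": "ATT", "left": "unpleasant",    "right": "pleasant",          "reverse": false },
    { "id": "ATT2", "subscale": "ATT", "left": "attractive",    "right": "ugly",              "reverse": true  },
    { "id": "ATT3", "subscale": "ATT", "left": "disagreeable",  "right": "likeable",          "reverse": false },
    { "id": "ATT4", "subscale": "ATT", "left": "rejecting",     "right": "inviting",          "reverse": false },
    { "id": "ATT5", "subscale": "ATT", "left": "bad",           "right": "good",              "reverse": false },
    { "id": "ATT6", "subscale": "ATT", "left": "repelling",     "right": "appealing",         "reverse": false },
    { "id": "ATT7", "subscale": "ATT", "left": "discouraging",  "right": "motivating",        "reverse": false }
  ]
}
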