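{
  "_comment": "Synthetic default definition of the 15-item multiple-choice knowledge test on postoperative pain management. Each item offers 6 options (a-f); exactly one is correct and option f is always 'do not know' (scored incorrect). Scored as percent correct. Components: pain after surgery (2), medications and dosages (7), management strategies (2), side effects (2), problem handling (2).",
  "name": "pakppm",
  "type": "multiple_choice",
  "n_options": 6,
  "do_not_know_option": "f",
  "items": [
    { "id": "K1",  "component": "pain_after_surgery", "correct": "b" },
    { "id": "K2",  "component": "pain_after_surgery", "correct": "d" },
    { "id": "K3",  "component": "medications",        "correct": "a" },
    { "id": "K4",  "component": "medications",        "correct": "c" },
    { "id": "K5",  "component": "medications",        "correct": "b" },
    { "id": "K6",  "component": "medications",        "correct": "e" },
    { "id": "K7",  "component": "medications",        "correct": "a" },
    { "id": "K8",  "component": "medications",        "correct": "d" },
    { "id": "K9",  "component": "medications",        "correct": "c" },
    { "id": "K10", "component": "strategies",         "correct": "b" },
    { "id": "K11", "component": "strategies",         "correct": "e" },
    { "id": "K12", "component": "side_effects",       "correct": "a" },
    { "id": "K13", "component": "side_effects",       "correct": "c" },
    { "id": "K14", "component": "problem_handling",   "correct": "d" },
    { "id": "K15", "component": "problem_handling",   "correct": "b" }
  ]
}
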