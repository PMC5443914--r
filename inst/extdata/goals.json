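{
  "_comment": "Daily goals, star thresholds and the unmanageable-pain event. 'under' thresholds are strict: a minute sampled exactly at the threshold does not count as achieved.",
  "goals": [
    {
      "day_index": 1,
      "kind": "minimize_doses",
      "dose_ceiling": 12,
      "description": "Use as little pain medication as you can today."
    },
    {
      "day_index": 2,
      "kind": "pain_under_threshold",
      "threshold": 3,
      "description": "Keep pain below 3 on the NRS all day, whatever the side effects."
    },
    {
      "day_index": 3,
      "kind": "pain_under_threshold",
      "threshold": 5,
      "description": "Keep pain below 5 on the NRS for the whole day."
    }
  ],
  "star_thresholds": { "three": 0.95, "two": 0.6 },
  "unmanageable_event": {
    "probability": 0.3,
    "pain_floor": 8,
    "post_consult_pain": 5
  }
}
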