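{
  "_comment": "Required daily tasks (activity ids) per game day.",
  "1": ["shower", "cook", "dishes"],
  "2": ["shower", "cook", "dishes"],
  "3": ["shower", "cook", "dishes"]
}
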