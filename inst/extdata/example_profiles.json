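[
 {"tool_name":"toolA","score_kind":"probability",
  "bins":[{"label":"low","lower":0,"upper":0.5},{"label":"high","lower":0.5,"upper":1}],
  "high_conf_bin":"high",
  "predictive_range":["1.1.1.1","2.1.1.2","3.1.1.3","4.1.1.4"]},
 {"tool_name":"toolB","score_kind":"probability",
  "bins":[{"label":"low","lower":0,"upper":0.5},{"label":"high","lower":0.5,"upper":1}],
  "high_conf_bin":"high",
  "predictive_range":["1.1.1.1","2.1.1.2","3.1.1.3","4.1.1.4"]}
]
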