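{
  "features": {
    "shade": ["1", "2", "3", "4"],
    "edge": ["3", "4", "5", "6", "7"]
  },
  "kind": {"shade": "ordinal", "edge": "ordinal"},
  "rules": {
    "rule1": "(and (plus1 (edge R') (edge A)) (plus1 (shade R') (shade R)))",
    "rule2": "(and (plus1 (edge R') (edge R)) (plus1 (shade R') (shade A)))"
  },
  "conditions": {
    "B1": {
      "rule": "rule1", "fixed_role": "agent",
      "fixed": {"shade": "3", "edge": "3"},
      "varied": [
        {"shade": "1", "edge": "3"}, {"shade": "2", "edge": "4"},
        {"shade": "1", "edge": "5"}, {"shade": "2", "edge": "3"},
        {"shade": "1", "edge": "4"}, {"shade": "2", "edge": "5"}
      ]
    },
    "B2": {
      "rule": "rule1", "fixed_role": "recipient",
      "fixed": {"shade": "1", "edge": "5"},
      "varied": [
        {"shade": "1", "edge": "3"}, {"shade": "2", "edge": "4"},
        {"shade": "3", "edge": "3"}, {"shade": "1", "edge": "4"},
        {"shade": "2", "edge": "3"}, {"shade": "3", "edge": "4"}
      ]
    },
    "B3": {
      "rule": "rule2", "fixed_role": "agent",
      "fixed": {"shade": "1", "edge": "5"},
      "varied": [
        {"shade": "1", "edge": "3"}, {"shade": "2", "edge": "4"},
        {"shade": "3", "edge": "3"}, {"shade": "1", "edge": "4"},
        {"shade": "2", "edge": "3"}, {"shade": "3", "edge": "4"}
      ]
    },
    "B4": {
      "rule": "rule2", "fixed_role": "recipient",
      "fixed": {"shade": "3", "edge": "3"},
      "varied": [
        {"shade": "1", "edge": "3"}, {"shade": "2", "edge": "4"},
        {"shade": "1", "edge": "5"}, {"shade": "2", "edge": "3"},
        {"shade": "1", "edge": "4"}, {"shade": "2", "edge": "5"}
      ]
    }
  },
  "task_grid": [
    {"fixed": [0, 0], "varied": [0, 0]},
    {"fixed": [0, 0], "varied": [0, 1]},
    {"fixed": [0, 0], "varied": [1, 0]},
    {"fixed": [0, 0], "varied": [1, 1]},
    {"fixed": [0, 1], "varied": [0, 0]},
    {"fixed": [0, 1], "varied": [0, 1]},
    {"fixed": [0, 1], "varied": [1, 0]},
    {"fixed": [0, 1], "varied": [1, 1]},
    {"fixed": [1, 0], "varied": [0, 0]},
    {"fixed": [1, 0], "varied": [0, 1]},
    {"fixed": [1, 0], "varied": [1, 0]},
    {"fixed": [1, 0], "varied": [1, 1]},
    {"fixed": [1, 1], "varied": [0, 0]},
    {"fixed": [1, 1], "varied": [0, 1]},
    {"fixed": [1, 1], "varied": [1, 0]},
    {"fixed": [1, 1], "varied": [1, 1]}
  ],
  "menu": "full"
}
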