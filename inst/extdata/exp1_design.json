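{
  "features": {
    "color": ["red", "yellow", "blue"],
    "shape": ["circle", "square", "diamond"]
  },
  "learning_agent": {"color": "red", "shape": "square"},
  "learning_recipient": {"color": "yellow", "shape": "circle"},
  "conditions": {
    "A1": {"color": "recipient", "shape": "agent"},
    "A2": {"color": "recipient", "shape": "new"},
    "A3": {"color": "agent", "shape": "recipient"},
    "A4": {"color": "new", "shape": "recipient"},
    "A5": {"color": "agent", "shape": "agent"},
    "A6": {"color": "new", "shape": "new"}
  },
  "task_grid": [
    {"agent": [0, 0], "recipient": [1, 0]},
    {"agent": [0, 0], "recipient": [0, 1]},
    {"agent": [0, 0], "recipient": [1, 1]},
    {"agent": [1, 0], "recipient": [0, 0]},
    {"agent": [1, 0], "recipient": [1, 0]},
    {"agent": [1, 0], "recipient": [0, 1]},
    {"agent": [1, 0], "recipient": [1, 1]},
    {"agent": [0, 1], "recipient": [0, 0]},
    {"agent": [0, 1], "recipient": [1, 0]},
    {"agent": [0, 1], "recipient": [0, 1]},
    {"agent": [0, 1], "recipient": [1, 1]},
    {"agent": [1, 1], "recipient": [0, 0]},
    {"agent": [1, 1], "recipient": [1, 0]},
    {"agent": [1, 1], "recipient": [0, 1]},
    {"agent": [1, 1], "recipient": [1, 1]}
  ],
  "menu": "full"
}
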