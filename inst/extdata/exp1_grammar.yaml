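# One-shot experiment grammar: categorical color/shape features with
# assign and negated-assign relations; uniform production probabilities.
features:
  color: [red, yellow, blue]
  shape: [circle, square, diamond]
kind:
  color: categorical
  shape: categorical
relations:
  categorical: [assign, nassign]
  ordinal: [assign, nassign]
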