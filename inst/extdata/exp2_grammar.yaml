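# Few-shot experiment grammar: ordinal shade/edge features; the relation
# set adds +1, -1, > and < at the bind-relation step, uniformly weighted.
features:
  shade: ['1', '2', '3', '4']
  edge: ['3', '4', '5', '6', '7']
kind:
  shade: ordinal
  edge: ordinal
relations:
  categorical: [assign, nassign]
  ordinal: [assign, nassign, plus1, minus1, gt, lt]
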