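# Shared fixtures: spaces, grammars and enumerated law tables are built once
# per test run; all simulated data is generated in code under fixed seeds.

e1_space <- exp1_space()
e1_grammar <- exp1_grammar()
e1_table <- enumerate_laws(e1_grammar)

e2_space <- exp2_space()
e2_grammar <- exp2_grammar()
e2_table <- enumerate_laws(e2_grammar)

# a small two-value space for brute-force oracle comparisons
tiny_space <- feature_space(list(color = c("red", "blue"),
                                 shape = c("circle", "square")))
tiny_grammar <- causal_grammar(tiny_space)

# a three-feature space for the geometric conjunction-decay property
three_space <- feature_space(list(color = c("red", "blue"),
                                  shape = c("circle", "square"),
                                  size = c("small", "big")))
three_grammar <- causal_grammar(three_space)

st <- function(...) stone(...)

a1_learning <- function() {
  causal_event(st(color = "red", shape = "square"),
               st(color = "yellow", shape = "circle"),
               st(color = "yellow", shape = "square"))
}

full_task <- function(agent, recipient, space) {
  generalization_task(agent, recipient, space = space)
}
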