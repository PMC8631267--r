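test_that("outcome domains follow the assertion semantics", {
  # deterministic conjunction: copy agent's color, become square
  law <- parse_law("(and (assign (color R') (color A)) (assign (shape R') square))")
  dom <- outcome_domain(law, st(color = "red", shape = "circle"),
                        st(color = "blue", shape = "diamond"), e1_space)
  expect_equal(dom$size, 1L)
  expect_equal(unlist(dom$stones[1, ]), c(color = "red", shape = "square"))

  # negated constant: two admissible shapes, each keeping the recipient color
  law2 <- parse_law("(nassign (shape R') circle)")
  dom2 <- outcome_domain(law2, st(color = "red", shape = "circle"),
                         st(color = "blue", shape = "square"), e1_space)
  expect_equal(dom2$size, 2L)
  expect_true(all(dom2$stones$color == "blue"))
  expect_setequal(dom2$stones$shape, c("square", "diamond"))

  # a law mentioning nothing else leaves the recipient unchanged
  law3 <- causal_law(assertion("color", "assign", "recipient"))
  dom3 <- outcome_domain(law3, st(color = "red", shape = "circle"),
                         st(color = "blue", shape = "square"), e1_space)
  expect_equal(dom3$size, 1L)
  expect_equal(unlist(dom3$stones[1, ]), c(color = "blue", shape = "square"))
})

test_that("ordinal increments and inequalities act on the value order", {
  plus <- parse_law("(plus1 (edge R') (edge A))")
  dom <- outcome_domain(plus, st(shade = "1", edge = "4"),
                        st(shade = "2", edge = "6"), e2_space)
  expect_equal(unlist(dom$stones[1, ]), c(shade = "2", edge = "5"))
  # +1 past the end of the range empties the domain (law inapplicable)
  dom_oob <- outcome_domain(plus, st(shade = "1", edge = "7"),
                            st(shade = "2", edge = "6"), e2_space)
  expect_equal(dom_oob$size, 0L)
  gt <- parse_law("(gt (edge R') (edge R))")
  dom_gt <- outcome_domain(gt, st(shade = "1", edge = "3"),
                           st(shade = "2", edge = "5"), e2_space)
  expect_setequal(dom_gt$stones$edge, c("6", "7"))
  expect_true(all(dom_gt$stones$shade == "2"))
})

test_that("event likelihoods are uniform over the outcome domain", {
  a <- st(color = "red", shape = "circle"); r <- st(color = "blue", shape = "square")
  det <- parse_law("(assign (shape R') (shape A))")
  expect_equal(event_likelihood(causal_event(a, r, st(color = "blue", shape = "circle")),
                                det, e1_space), 1)
  expect_equal(event_likelihood(causal_event(a, r, st(color = "blue", shape = "diamond")),
                                det, e1_space), 0)
  neg <- parse_law("(nassign (shape R') circle)")
  expect_equal(event_likelihood(causal_event(a, r, st(color = "blue", shape = "diamond")),
                                neg, e1_space), 1 / 2)
  # per-pair likelihoods sum to 1 over the outcome space for every table law
  pid <- localaws:::table_pair_index(e1_table, a, r)
  d <- e1_table$dsize[pid, ]
  probs <- localaws:::table_outcome_probs(e1_table, a, r)
  expect_equal(unname(rowSums(probs)[d > 0]),
               rep(1, sum(d > 0)), tolerance = 1e-12)
})

test_that("the fast mask-based likelihood agrees with the direct semantics", {
  set.seed(5)
  cfgs <- space_configs(e2_space)
  pick <- function() {
    i <- sample.int(nrow(cfgs), 1L)
    stone(stats::setNames(as.character(cfgs[i, ]), names(cfgs)))
  }
  for (rep in 1:10) {
    ev <- causal_event(pick(), pick(), pick())
    idx <- sample(seq_along(e2_table$laws), 25)
    fast <- localaws:::table_event_likelihood(e2_table, ev)[idx]
    slow <- vapply(idx, function(li)
      event_likelihood(ev, e2_table$laws[[li]], e2_space), numeric(1))
    expect_equal(fast, slow, ignore_attr = TRUE)
  }
})

test_that("the law posterior is exact Bayes on the enumerated table", {
  ev <- a1_learning()
  post <- posterior_over_laws(e1_table, list(ev))
  # brute-force oracle recomputation with the slow semantics path
  oracle <- e1_table$prior * vapply(e1_table$laws, function(l)
    event_likelihood(ev, l, e1_space), numeric(1))
  oracle <- oracle / sum(oracle)
  expect_equal(post$posterior, oracle, tolerance = 1e-12)

  # empty data returns the prior
  expect_equal(posterior_over_laws(e1_table)$posterior, e1_table$prior)

  # agent's-color-copied event keeps both relational and constant color laws
  ev2 <- causal_event(st(color = "blue", shape = "square"),
                      st(color = "red", shape = "diamond"),
                      st(color = "blue", shape = "diamond"))
  p2 <- posterior_over_laws(e1_table, list(ev2))
  expect_gt(p2$posterior[match("(assign (color R') (color A))", e1_table$strings)], 0)
  expect_gt(p2$posterior[match("(assign (color R') blue)", e1_table$strings)], 0)

  # consistent evidence never revives a refuted law
  refuted <- post$posterior == 0
  post2 <- posterior_over_laws(e1_table, list(ev, ev))
  expect_true(all(post2$posterior[refuted] == 0))

  # contradictory evidence (three different results for one pair) leaves no
  # law standing and must be flagged, not silently renormalized
  tiny_tab <- enumerate_laws(tiny_grammar)
  c1 <- causal_event(st(color = "red", shape = "circle"),
                     st(color = "blue", shape = "square"),
                     st(color = "red", shape = "circle"))
  c2 <- causal_event(st(color = "red", shape = "circle"),
                     st(color = "blue", shape = "square"),
                     st(color = "blue", shape = "square"))
  c3 <- causal_event(st(color = "red", shape = "circle"),
                     st(color = "blue", shape = "square"),
                     st(color = "red", shape = "square"))
  expect_warning(pd <- posterior_over_laws(tiny_tab, list(c1, c2, c3)),
                 "degenerate")
  expect_true(pd$degenerate)
})

test_that("universal predictions marginalize the posterior and ignore order", {
  # learning: blue-square agent turns a red-diamond blue
  ev <- causal_event(st(color = "blue", shape = "square"),
                     st(color = "red", shape = "diamond"),
                     st(color = "blue", shape = "diamond"))
  post <- posterior_over_laws(e1_table, list(ev))
  task <- full_task(st(color = "blue", shape = "square"),
                    st(color = "red", shape = "diamond"), e1_space)
  pred <- uncala_predict(post, task)
  expect_equal(unclass(argmax_choice(pred)$stone),
               c(color = "blue", shape = "diamond"))
  expect_equal(sum(pred$prob), 1)

  # two laws agreeing deterministically concentrate all mass on one outcome
  w <- numeric(n_laws(e1_table))
  i1 <- match("(assign (color R') (color A))", e1_table$strings)
  i2 <- match("(assign (color R') blue)", e1_table$strings)
  w[c(i1, i2)] <- 0.5
  fake_post <- structure(list(table = e1_table, posterior = w, evidence = 1,
                              degenerate = FALSE, n_events = 0),
                         class = "law_posterior")
  pr <- uncala_predict(fake_post, task)
  expect_equal(max(pr$prob), 1)

  # no sequential state: evaluating tasks in any order gives identical rows
  d <- exp1_design("A2", "near_first", 3)
  postd <- posterior_over_laws(e1_table, d$learning)
  preds <- lapply(d$tasks, function(t) uncala_predict(postd, t)$prob)
  perm <- sample(seq_along(d$tasks))
  preds_perm <- lapply(d$tasks[perm], function(t) uncala_predict(postd, t)$prob)
  expect_equal(preds[perm], preds_perm)
})
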