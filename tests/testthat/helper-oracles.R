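# Independent brute-force oracles used to validate the constructive
# implementations. These deliberately re-derive everything from first
# principles: derivations are expanded recursively from the grammar's
# choice points, and semantic equivalence is decided by literal
# satisfaction checks per (agent, recipient, outcome) triple.

# Does `outcome` satisfy the law for this (agent, recipient) pair?
oracle_holds <- function(law, agent, recipient, outcome, space) {
  asserted <- vapply(law$assertions, function(a) a$feature, character(1))
  for (f in space$features) {
    i <- match(f, asserted)
    if (is.na(i)) {
      if (outcome[[f]] != recipient[[f]]) return(FALSE)
      next
    }
    a <- law$assertions[[i]]
    refv <- switch(a$ref, agent = agent[[f]], recipient = recipient[[f]],
                   constant = a$value)
    oi <- match(outcome[[f]], space$values[[f]])
    ri <- match(refv, space$values[[f]])
    ok <- switch(a$relation,
                 assign = outcome[[f]] == refv,
                 nassign = outcome[[f]] != refv,
                 plus1 = oi == ri + 1,
                 minus1 = oi == ri - 1,
                 gt = oi > ri,
                 lt = oi < ri)
    if (!ok) return(FALSE)
  }
  TRUE
}

# Truth-table signature of a law: admissible-outcome indicator over every
# (agent, recipient, outcome) triple in the space.
oracle_signature <- function(law, space) {
  cfg <- space_configs(space)
  stones <- lapply(seq_len(nrow(cfg)), function(i)
    stone(stats::setNames(as.character(cfg[i, ]), names(cfg))))
  bits <- logical(0)
  for (a in stones) for (r in stones) for (o in stones)
    bits <- c(bits, oracle_holds(law, a, r, o, space))
  paste(as.integer(bits), collapse = "")
}

# Expand every derivation tree of the grammar (conjuncts bound without
# replacement), recording the produced law and its derivation probability.
oracle_derivations <- function(grammar) {
  space <- grammar$space
  res <- list()
  expand <- function(remaining, prob, acc) {
    for (f in remaining) {
      p1 <- prob / length(remaining)
      rem2 <- setdiff(remaining, f)
      rels <- localaws:::relations_for(grammar, f)
      for (rel in rels) {
        p2 <- p1 / length(rels)
        refs <- list(list(ref = "agent", p = p2 / 4),
                     list(ref = "recipient", p = p2 / 4))
        for (v in space$values[[f]])
          refs <- c(refs, list(list(ref = "constant", value = v,
                                    p = p2 / 2 / length(space$values[[f]]))))
        for (rf in refs) {
          a <- assertion(f, rel, rf$ref, rf$value)
          acc2 <- c(acc, list(a))
          if (length(rem2) == 0L) {
            res[[length(res) + 1L]] <<- list(law = causal_law(acc2), prob = rf$p)
          } else {
            res[[length(res) + 1L]] <<- list(law = causal_law(acc2), prob = rf$p / 2)
            expand(rem2, rf$p / 2, acc2)
          }
        }
      }
    }
  }
  expand(space$features, 1, list())
  res
}

# Semantic classes of the full depth-limited derivation expansion:
# signature -> total prior mass (renormalized) and representative strings.
oracle_law_classes <- function(grammar) {
  ders <- oracle_derivations(grammar)
  sigs <- vapply(ders, function(d) oracle_signature(d$law, grammar$space),
                 character(1))
  mass <- tapply(vapply(ders, `[[`, numeric(1), "prob"), sigs, sum)
  mass / sum(mass)
}

# Two-hypothesis oracle for the single-example local-law model: explicit
# enumeration over {join learning category, new category} x laws, using the
# slow per-law semantics path.
oracle_single_example <- function(learning, task, params, table) {
  space <- table$space
  liks <- vapply(table$laws, function(l)
    event_likelihood(learning, l, space), numeric(1))
  post <- table$prior * liks
  post <- post / sum(post)
  mu1 <- category_mean(list(learning), params, space)
  mu0 <- category_mean(list(), params, space)
  w1 <- 1 / (1 + params$alpha) *
    pair_feature_likelihood(task$agent, task$recipient, mu1)
  w0 <- params$alpha / (1 + params$alpha) *
    pair_feature_likelihood(task$agent, task$recipient, mu0)
  p <- numeric(nrow(task$panel))
  for (ci in seq_len(nrow(task$panel))) {
    o <- stone(stats::setNames(as.character(task$panel[ci, ]), names(task$panel)))
    for (li in seq_along(table$laws)) {
      dom <- outcome_domain(table$laws[[li]], task$agent, task$recipient, space)
      if (dom$size == 0) next
      hit <- any(apply(dom$stones, 1, function(row) all(row == unclass(o)[names(dom$stones)])))
      if (hit) {
        p[ci] <- p[ci] + (w1 / (w1 + w0) * post[li] +
                          w0 / (w1 + w0) * table$prior[li]) / dom$size
      }
    }
  }
  p / sum(p)
}

# Exact posterior co-assignment probability for two events under the DP
# mixture: enumerate the two partitions, with Dirichlet-categorical
# predictive feature terms and law-marginal likelihoods.
oracle_two_event_coassignment <- function(events, params, table) {
  stopifnot(length(events) == 2L)
  space <- table$space
  marg <- function(members) {
    w <- table$prior
    for (ev in members)
      w <- w * vapply(table$laws, function(l) event_likelihood(ev, l, space),
                      numeric(1))
    sum(w)
  }
  mu0 <- category_mean(list(), params, space)
  f0 <- function(ev) pair_feature_likelihood(ev$agent, ev$recipient, mu0)
  mu1 <- category_mean(events[1], params, space)
  f21 <- pair_feature_likelihood(events[[2]]$agent, events[[2]]$recipient, mu1)
  p_together <- 1 / (1 + params$alpha) * f0(events[[1]]) * f21 * marg(events)
  p_apart <- params$alpha / (1 + params$alpha) * f0(events[[1]]) * f0(events[[2]]) *
    marg(events[1]) * marg(events[2])
  p_together / (p_together + p_apart)
}
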