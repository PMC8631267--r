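# Outcome semantics of causal laws.
#
# A law constrains each mentioned feature of the result stone; unmentioned
# features keep the recipient's value. The admissible-outcome set D(f(a, r))
# is the Cartesian product of the per-feature allowed value sets; it is empty
# as soon as one assertion admits no value (e.g. +1 past the end of an
# ordinal range, which we treat as the law being inapplicable rather than
# clamping to the boundary).

# Allowed value indices for one assertion given the reference value index.
allowed_indices <- function(relation, v, V) {
  switch(relation,
         assign  = v,
         nassign = setdiff(seq_len(V), v),
         plus1   = if (v + 1 <= V) v + 1 else integer(0),
         minus1  = if (v - 1 >= 1) v - 1 else integer(0),
         gt      = if (v < V) seq.int(v + 1, V) else integer(0),
         lt      = if (v > 1) seq.int(1, v - 1) else integer(0),
         stop("unknown relation: ", relation))
}

ref_value_index <- function(a, space, agent, recipient) {
  f <- a$feature
  val <- switch(a$ref, agent = agent[[f]], recipient = recipient[[f]],
                constant = a$value)
  idx <- match(val, space$values[[f]])
  if (is.na(idx)) stop(sprintf("value '%s' outside the support of '%s'", val, f))
  idx
}

#' Admissible result stones of a law applied to an agent-recipient pair
#'
#' Features asserted by the law are constrained accordingly; features the law
#' does not mention keep the recipient's value. Negated assignments allow
#' every admissible value except the referenced one; increments shift one
#' step along the ordinal order (an out-of-range step empties the domain);
#' inequalities allow all strictly greater/less values.
#'
#' @param law A `causal_law`.
#' @param agent,recipient Stones.
#' @param space The `feature_space`.
#' @return List of class `outcome_domain` with elements `stones`
#'   (data.frame, one admissible result per row) and `size`.
#' @export
outcome_domain <- function(law, agent, recipient, space) {
  validate_stone(space, agent, "agent")
  validate_stone(space, recipient, "recipient")
  allowed <- lapply(space$features, function(f) {
    match(recipient[[f]], space$values[[f]])
  })
  names(allowed) <- space$features
  for (a in law$assertions) {
    v <- ref_value_index(a, space, agent, recipient)
    allowed[[a$feature]] <- allowed_indices(a$relation, v, length(space$values[[a$feature]]))
  }
  if (any(vapply(allowed, length, integer(1)) == 0L)) {
    stones <- space_configs(space)[0, , drop = FALSE]
  } else {
    vals <- lapply(space$features, function(f) space$values[[f]][allowed[[f]]])
    names(vals) <- space$features
    grids <- rev(vals)
    stones <- expand.grid(grids, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    stones <- stones[, rev(names(stones)), drop = FALSE]
  }
  structure(list(stones = stones, size = nrow(stones)), class = "outcome_domain")
}

#' @export
print.outcome_domain <- function(x, ...) {
  cat("<outcome domain>", x$size, "admissible result(s)\n")
  if (x$size > 0) print(utils::head(x$stones, 10))
  invisible(x)
}

#' Likelihood of an observed causal event under a law
#'
#' Uniform over the law's admissible-outcome set: `1/|D(f(a, r))|` when the
#' observed result lies in the domain, otherwise 0. The optional
#' `epsilon` softens the law into a mixture with the uniform distribution
#' over all configurations, modelling fallible functional relationships.
#'
#' @param event A `causal_event` with known result.
#' @param law A `causal_law`.
#' @param space The `feature_space`.
#' @param epsilon Mixture weight on the uniform outcome distribution
#'   (default 0: fully deterministic law semantics).
#' @return Probability.
#' @export
event_likelihood <- function(event, law, space, epsilon = 0) {
  if (is.null(event$result)) stop("event result must be known")
  dom <- outcome_domain(law, event$agent, event$recipient, space)
  lik <- if (dom$size == 0L) 0 else {
    idx <- config_index(space, event$result)
    hit <- any(apply(dom$stones, 1L, function(row)
      config_index(space, as_stone(stats::setNames(as.character(row), names(dom$stones)))) == idx))
    if (hit) 1 / dom$size else 0
  }
  (1 - epsilon) * lik + epsilon / n_configs(space)
}
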