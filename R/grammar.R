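#' Construct a probabilistic grammar over causal laws
#'
#' The grammar generates conjunctions of feature assertions by (i) binding a
#' feature (sampled uniformly without replacement from the unbound
#' features), (ii) deciding whether to bind an additional feature (the
#' conjunction production, probability 1/2 while unbound features remain),
#' (iii) choosing a relation uniformly from the relations admissible for the
#' feature's kind, (iv) choosing a relative (agent/recipient, 1/2 each) or
#' absolute reference (a constant drawn uniformly from the feature's value
#' support). All choice points use uniform production probabilities.
#'
#' @param space A `feature_space` the laws range over.
#' @param relations Named list giving the admissible relations for
#'   `categorical` and `ordinal` features. Increments and inequalities are
#'   only meaningful on ordinal features.
#' @return Object of class `causal_grammar`.
#' @seealso [exp1_grammar()], [exp2_grammar()]
#' @export
causal_grammar <- function(space,
                           relations = list(categorical = c("assign", "nassign"),
                                            ordinal = c("assign", "nassign"))) {
  stopifnot(inherits(space, "feature_space"))
  ok <- c("assign", "nassign", "plus1", "minus1", "gt", "lt")
  for (kind in names(relations)) {
    if (!all(relations[[kind]] %in% ok))
      stop("unknown relations: ", paste(setdiff(relations[[kind]], ok), collapse = ", "))
    if (anyDuplicated(relations[[kind]])) stop("duplicate relations for kind ", kind)
  }
  if (any(c("plus1", "minus1", "gt", "lt") %in% relations$categorical))
    stop("increment and inequality relations require ordinal features")
  structure(list(space = space, relations = relations), class = "causal_grammar")
}

#' @export
print.causal_grammar <- function(x, ...) {
  cat("Probabilistic grammar over causal laws\n")
  for (f in x$space$features)
    cat(sprintf("  %s (%s): relations %s\n", f, x$space$kind[[f]],
                paste(relations_for(x, f), collapse = ", ")))
  invisible(x)
}

relations_for <- function(grammar, feature) {
  grammar$relations[[grammar$space$kind[[feature]]]]
}

#' The Experiment 1 grammar
#'
#' Assign and negated-assign relations over the color/shape space.
#' @param space Feature space (defaults to [exp1_space()]).
#' @return A `causal_grammar`.
#' @export
exp1_grammar <- function(space = exp1_space()) {
  causal_grammar(space)
}

#' The Experiment 2 grammar
#'
#' Extends the relation set with `+1`, `-1`, `>` and `<` at the bind-relation
#' step, uniformly weighted alongside assign and negated-assign, for the
#' ordinal shade/edge space.
#' @param space Feature space (defaults to [exp2_space()]).
#' @return A `causal_grammar`.
#' @export
exp2_grammar <- function(space = exp2_space()) {
  causal_grammar(space, relations = list(
    categorical = c("assign", "nassign"),
    ordinal = c("assign", "nassign", "plus1", "minus1", "gt", "lt")))
}

#' Sample a causal law from the grammar
#'
#' Expands stochastically from the start symbol until no transition symbols
#' remain. Expansion terminates with certainty: the conjunction production
#' halves in probability at each step and becomes unavailable once every
#' feature is bound. Uses R's global RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param grammar A `causal_grammar`.
#' @return A `causal_law` with attribute `"derivation_prob"`, the product of
#'   the production probabilities along the sampled derivation.
#' @export
sample_law <- function(grammar) {
  space <- grammar$space
  remaining <- space$features
  assertions <- list()
  p <- 1
  repeat {
    f <- remaining[sample.int(length(remaining), 1L)]
    p <- p / length(remaining)
    remaining <- setdiff(remaining, f)

    rels <- relations_for(grammar, f)
    rel <- rels[sample.int(length(rels), 1L)]
    p <- p / length(rels)

    if (stats::runif(1) < 0.5) {         # relative reference
      role <- if (stats::runif(1) < 0.5) "agent" else "recipient"
      p <- p / 4
      assertions[[length(assertions) + 1L]] <- assertion(f, rel, role)
    } else {                             # absolute reference
      vals <- space$values[[f]]
      v <- vals[sample.int(length(vals), 1L)]
      p <- p / 2 / length(vals)
      assertions[[length(assertions) + 1L]] <- assertion(f, rel, "constant", v)
    }

    if (length(remaining) == 0L) break   # conjunction production unavailable
    p <- p / 2
    if (stats::runif(1) < 0.5) break     # stop: A -> B
    # continue: A -> and(B, S)
  }
  law <- causal_law(assertions)
  attr(law, "derivation_prob") <- p
  law
}

#' Prior probability of a causal law under the grammar
#'
#' The product of the production probabilities over all rules used in the
#' law's derivation, summed over the distinct derivations (orderings of the
#' conjuncts) that produce the same law.
#'
#' @param law A `causal_law`.
#' @param grammar A `causal_grammar`.
#' @return Probability in (0, 1].
#' @export
law_prior <- function(law, grammar) {
  space <- grammar$space
  k <- n_assertions(law)
  nf <- length(space$features)
  if (k < 1) stop("law has no assertions")
  if (k > nf) stop("law binds more features than the space has")
  prod_assert <- 1
  for (a in law$assertions) {
    if (!(a$feature %in% space$features))
      stop("law uses feature absent from the space: ", a$feature)
    rels <- relations_for(grammar, a$feature)
    if (!(a$relation %in% rels))
      stop(sprintf("law uses relation '%s' absent from the grammar for feature '%s'",
                   a$relation, a$feature))
    refp <- if (a$ref == "constant") {
      if (!(a$value %in% space$values[[a$feature]]))
        stop(sprintf("constant '%s' outside the support of feature '%s'",
                     a$value, a$feature))
      (1 / 2) * (1 / length(space$values[[a$feature]]))
    } else {
      1 / 4
    }
    prod_assert <- prod_assert * (1 / length(rels)) * refp
  }
  # all k! conjunct orderings have equal probability
  feat_factor <- factorial(k) * factorial(nf - k) / factorial(nf)
  conj_factor <- (1 / 2)^(k - 1) * (if (nf - k >= 1) 1 / 2 else 1)
  feat_factor * conj_factor * prod_assert
}

#' Probability that a sampled law has more than k conjoined assertions
#'
#' Computed analytically from the uniform probability of the conjunction
#' production: each additional conjunct requires one more `and` choice
#' (probability 1/2), available only while unbound features remain.
#'
#' @param grammar A `causal_grammar`.
#' @param k Integer threshold (default 1, i.e. the fraction of laws
#'   combining more than one assertion).
#' @return Probability.
#' @export
prob_extra_conjuncts <- function(grammar, k = 1) {
  nf <- length(grammar$space$features)
  if (k >= nf) return(0)
  (1 / 2)^k
}
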