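# Depth-bounded enumeration of semantically distinct causal laws.
#
# All laws with up to `max_conjuncts` assertions are generated, their
# grammar priors computed exactly, and semantic duplicates merged: two laws
# are equivalent iff their admissible-outcome sets agree for every
# (agent, recipient) pair in the finite space. Outcome sets are encoded as
# bitmasks over the canonical configuration index, so the equivalence check
# is an exhaustive truth-table comparison.

pair_id <- function(nc, ai, ri) as.integer((ai - 1L) * nc + ri)

# Per-feature value-index matrix of all configurations.
config_value_matrix <- function(space) {
  cfg <- space_configs(space)
  vi <- vapply(space$features, function(f) match(cfg[[f]], space$values[[f]]),
               integer(nrow(cfg)))
  matrix(vi, nrow = nrow(cfg), dimnames = list(NULL, space$features))
}

# pairs x values logical matrix of allowed result values for one assertion,
# given per-pair agent/recipient value indices for the assertion's feature.
allowed_matrix <- function(relation, w, V) {
  vals <- seq_len(V)
  switch(relation,
         assign  = outer(w, vals, `==`),
         nassign = outer(w, vals, `!=`),
         plus1   = outer(w + 1L, vals, `==`),
         minus1  = outer(w - 1L, vals, `==`),
         gt      = outer(w, vals, `<`),
         lt      = outer(w, vals, `>`),
         stop("unknown relation: ", relation))
}

# Outcome bitmask (one integer per (a, r) pair) and domain sizes for a law.
law_masks <- function(law, space, vi, av, rv) {
  nc <- nrow(vi)
  npair <- nc * nc
  asserted <- vapply(law$assertions, function(a) a$feature, character(1))
  ok <- matrix(TRUE, npair, nc)
  for (f in space$features) {
    V <- length(space$values[[f]])
    i <- match(f, asserted)
    L <- if (is.na(i)) {
      outer(rv[, f], seq_len(V), `==`)           # unmentioned: keep recipient
    } else {
      a <- law$assertions[[i]]
      w <- switch(a$ref,
                  agent = av[, f],
                  recipient = rv[, f],
                  constant = rep.int(match(a$value, space$values[[f]]), npair))
      allowed_matrix(a$relation, w, V)
    }
    ok <- ok & L[, vi[, f], drop = FALSE]
  }
  list(mask = as.integer(ok %*% 2^(seq_len(nc) - 1)),
       dsize = as.integer(rowSums(ok)))
}

all_assertions_for_feature <- function(grammar, f) {
  space <- grammar$space
  out <- list()
  for (rel in relations_for(grammar, f)) {
    out[[length(out) + 1L]] <- assertion(f, rel, "agent")
    out[[length(out) + 1L]] <- assertion(f, rel, "recipient")
    for (v in space$values[[f]])
      out[[length(out) + 1L]] <- assertion(f, rel, "constant", v)
  }
  out
}

#' Enumerate all semantically distinct causal laws up to a conjunction depth
#'
#' Generates every law with at most `max_conjuncts` assertions (each binding
#' a distinct feature), computes its exact grammar prior, merges semantic
#' duplicates by exhaustive outcome comparison over all (agent, recipient)
#' pairs (summing their prior mass), and renormalizes the priors to 1. With
#' two-feature spaces and `max_conjuncts = 2` this table is semantically
#' exhaustive: any deeper law the grammar can produce is equivalent to an
#' entry.
#'
#' @param grammar A `causal_grammar`.
#' @param max_conjuncts Maximum number of conjoined assertions (default 2).
#' @return Object of class `law_table`: semantically distinct laws,
#'   renormalized prior vector, and precomputed outcome bitmasks.
#' @export
enumerate_laws <- function(grammar, max_conjuncts = 2) {
  if (max_conjuncts < 1) stop("max_conjuncts must be at least 1")
  space <- grammar$space
  nc <- n_configs(space)
  if (nc > 30) stop("law tables support at most 30 object configurations")
  max_conjuncts <- min(max_conjuncts, length(space$features))

  per_feature <- lapply(space$features, function(f) all_assertions_for_feature(grammar, f))
  names(per_feature) <- space$features

  laws <- list()
  for (k in seq_len(max_conjuncts)) {
    subsets <- utils::combn(space$features, k, simplify = FALSE)
    for (fs in subsets) {
      idx <- lapply(fs, function(f) seq_along(per_feature[[f]]))
      grid <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(grid))) {
        as_ <- lapply(seq_along(fs), function(j) per_feature[[fs[j]]][[grid[r, j]]])
        laws[[length(laws) + 1L]] <- causal_law(as_)
      }
    }
  }

  priors <- vapply(laws, law_prior, numeric(1), grammar = grammar)

  vi <- config_value_matrix(space)
  ai <- rep(seq_len(nc), each = nc)
  ri <- rep(seq_len(nc), times = nc)
  av <- vi[ai, , drop = FALSE]
  rv <- vi[ri, , drop = FALSE]

  masks <- matrix(0L, nc * nc, length(laws))
  dsize <- matrix(0L, nc * nc, length(laws))
  for (l in seq_along(laws)) {
    m <- law_masks(laws[[l]], space, vi, av, rv)
    masks[, l] <- m$mask
    dsize[, l] <- m$dsize
  }

  sig <- apply(masks, 2L, paste, collapse = ",")
  groups <- split(seq_along(laws), sig)
  keep <- integer(length(groups))
  prior <- numeric(length(groups))
  for (g in seq_along(groups)) {
    ids <- groups[[g]]
    prior[g] <- sum(priors[ids])
    keep[g] <- ids[which.max(priors[ids])]   # highest-prior syntactic representative
  }
  ord <- order(keep)
  keep <- keep[ord]; prior <- prior[ord]

  structure(list(space = space, grammar = grammar,
                 laws = laws[keep],
                 strings = vapply(laws[keep], law_to_string, character(1)),
                 prior = prior / sum(prior),
                 masks = masks[, keep, drop = FALSE],
                 dsize = dsize[, keep, drop = FALSE],
                 n_configs = nc),
            class = "law_table")
}

#' @export
print.law_table <- function(x, ...) {
  cat(sprintf("Law table: %d semantically distinct laws over %d configurations\n",
              length(x$laws), x$n_configs))
  top <- order(x$prior, decreasing = TRUE)[seq_len(min(5, length(x$prior)))]
  for (i in top)
    cat(sprintf("  %.4f  %s\n", x$prior[i], x$strings[i]))
  invisible(x)
}

#' Number of laws in a law table
#' @param table A `law_table`.
#' @return Integer.
#' @export
n_laws <- function(table) length(table$laws)

table_pair_index <- function(table, agent, recipient) {
  pair_id(table$n_configs,
          config_index(table$space, agent),
          config_index(table$space, recipient))
}

# Likelihood of one event under every law in the table (vectorized
# uniform-over-domain likelihood).
table_event_likelihood <- function(table, event, epsilon = 0) {
  if (is.null(event$result)) return(rep(1, n_laws(table)))  # unknown result: uninformative
  p <- table_pair_index(table, event$agent, event$recipient)
  bit <- 2^(config_index(table$space, event$result) - 1)
  member <- bitwAnd(table$masks[p, ], as.integer(bit)) != 0L
  d <- table$dsize[p, ]
  lik <- ifelse(member & d > 0L, 1 / pmax(d, 1L), 0)
  (1 - epsilon) * lik + epsilon / table$n_configs
}

# laws x candidates matrix of outcome probabilities P(r' = c | law, a, r)
# for the (agent, recipient) pair, over the full configuration space.
table_outcome_probs <- function(table, agent, recipient, epsilon = 0) {
  p <- table_pair_index(table, agent, recipient)
  nc <- table$n_configs
  bits <- as.integer(2^(seq_len(nc) - 1))
  m <- table$masks[p, ]
  member <- outer(m, bits, function(a, b) bitwAnd(a, b) != 0L)
  d <- table$dsize[p, ]
  probs <- member / pmax(d, 1L)
  probs[d == 0L, ] <- 0
  (1 - epsilon) * probs + epsilon / nc
}
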