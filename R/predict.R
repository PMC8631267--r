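# Posterior over laws and universal-law prediction.

#' Construct a choice distribution over a candidate panel
#'
#' @param panel Data.frame of candidate outcome stones (one per row), in the
#'   canonical order of the task's response panel.
#' @param prob Numeric probabilities, one per candidate; must sum to 1 up to
#'   numerical tolerance.
#' @return Object of class `choice_distribution`.
#' @export
choice_distribution <- function(panel, prob) {
  if (nrow(panel) != length(prob)) stop("panel and prob lengths differ")
  if (any(prob < -1e-12)) stop("negative probabilities")
  s <- sum(prob)
  if (abs(s - 1) > 1e-8) stop("probabilities must sum to 1")
  structure(list(panel = panel, prob = as.numeric(prob)),
            class = "choice_distribution")
}

#' @export
print.choice_distribution <- function(x, ...) {
  cat("<choice distribution over", nrow(x$panel), "candidates>\n")
  df <- cbind(x$panel, prob = round(x$prob, 4))
  print(utils::head(df[order(-x$prob), ], 5))
  invisible(x)
}

#' Modal choice of a choice distribution
#'
#' Deterministic argmax; ties are broken toward the lowest canonical
#' candidate index.
#'
#' @param dist A `choice_distribution`.
#' @return List with `index` (panel row) and `stone`.
#' @export
argmax_choice <- function(dist) {
  i <- which.max(dist$prob)   # which.max takes the first maximum: lowest index
  list(index = i,
       stone = as_stone(stats::setNames(as.character(dist$panel[i, ]),
                                        names(dist$panel))))
}

#' Posterior distribution over causal laws given observed events
#'
#' Bayes' rule over the enumerated law table: prior times the product of
#' per-event likelihoods, renormalized. If no law in the table explains the
#' data the posterior is degenerate; this is flagged explicitly rather than
#' silently renormalized.
#'
#' @param table A `law_table`.
#' @param events List of `causal_event`s with known results (an empty list
#'   returns the prior).
#' @param epsilon Soft-likelihood mixture weight (see [event_likelihood()]).
#' @return Object of class `law_posterior` with elements `posterior`,
#'   `evidence` (total marginal likelihood mass) and `degenerate`.
#' @export
posterior_over_laws <- function(table, events = list(), epsilon = 0) {
  if (inherits(events, "causal_event")) events <- list(events)
  w <- table$prior
  for (ev in events) {
    if (is.null(ev$result)) stop("all events must have known results")
    w <- w * table_event_likelihood(table, ev, epsilon = epsilon)
  }
  evid <- sum(w)
  degenerate <- evid <= 0
  if (degenerate) {
    warning("no law in the table explains the data: degenerate posterior")
    post <- rep(NA_real_, length(w))
  } else {
    post <- w / evid
  }
  structure(list(table = table, posterior = post, evidence = evid,
                 degenerate = degenerate, n_events = length(events)),
            class = "law_posterior")
}

#' @export
print.law_posterior <- function(x, ...) {
  if (x$degenerate) {
    cat("<degenerate law posterior: no law explains the data>\n")
    return(invisible(x))
  }
  cat(sprintf("Law posterior after %d event(s); support size %d\n",
              x$n_events, sum(x$posterior > 0)))
  top <- order(x$posterior, decreasing = TRUE)[seq_len(min(5, length(x$posterior)))]
  for (i in top)
    cat(sprintf("  %.4f  %s\n", x$posterior[i], x$table$strings[i]))
  invisible(x)
}

#' Export a law posterior as a data.frame
#'
#' @param x A `law_posterior`.
#' @param ... Unused.
#' @return Data.frame with law string, prior and posterior columns.
#' @export
as.data.frame.law_posterior <- function(x, ...) {
  data.frame(law = x$table$strings, prior = x$table$prior,
             posterior = x$posterior, stringsAsFactors = FALSE)
}

# Map panel rows to canonical configuration indices.
panel_config_indices <- function(space, panel) {
  vapply(seq_len(nrow(panel)), function(i)
    config_index(space, as_stone(stats::setNames(as.character(panel[i, ]),
                                                 names(panel)))),
    integer(1))
}

# Weighted predictive over a task's panel given per-law weights.
weighted_predictive <- function(table, weights, task, epsilon = 0,
                                normalize = TRUE, warn_loss = TRUE) {
  probs <- table_outcome_probs(table, task$agent, task$recipient, epsilon = epsilon)
  full <- as.numeric(weights %*% probs)          # over all configurations
  idx <- panel_config_indices(table$space, task$panel)
  p <- full[idx]
  total <- sum(full)
  if (warn_loss && total - sum(p) > 1e-8)
    warning(sprintf("candidate panel misses %.4f of the predictive mass; renormalizing",
                    total - sum(p)))
  if (normalize) {
    if (sum(p) <= 0) stop("no candidate in the panel has positive probability")
    p <- p / sum(p)
  }
  p
}

#' Universal-causal-laws prediction for a generalization task
#'
#' Marginalizes the posterior predictive over the law posterior: for each
#' candidate result the posterior mass of each law times the law's outcome
#' probability, renormalized over the candidate panel. This universal model
#' has no sequential state, so predictions are invariant to the order tasks
#' are evaluated in.
#'
#' @param posterior A `law_posterior` (must be nondegenerate).
#' @param task A `generalization_task`.
#' @param epsilon Soft-likelihood mixture weight.
#' @return A `choice_distribution` over the task's panel.
#' @export
uncala_predict <- function(posterior, task, epsilon = 0) {
  if (posterior$degenerate) stop("cannot predict from a degenerate posterior")
  p <- weighted_predictive(posterior$table, posterior$posterior, task,
                           epsilon = epsilon)
  choice_distribution(task$panel, p)
}

#' Prior-predictive distribution for a task (no learning data)
#'
#' @param table A `law_table`.
#' @param task A `generalization_task`.
#' @param epsilon Soft-likelihood mixture weight.
#' @return A `choice_distribution`.
#' @export
prior_predict <- function(table, task, epsilon = 0) {
  p <- weighted_predictive(table, table$prior, task, epsilon = epsilon,
                           warn_loss = FALSE)
  choice_distribution(task$panel, p)
}
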