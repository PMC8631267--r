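# Choice noise, likelihood/BIC model comparison, grid-search fitting, the
# uniform baseline, and the KR-21 inter-participant consistency statistic.

softmax_vec <- function(p, t, log_space = FALSE) {
  if (t < 0) stop("inverse temperature t must be >= 0")
  x <- if (log_space) t * log(pmax(p, .Machine$double.xmin)) else p * t
  e <- exp(x - max(x))
  e / sum(e)
}

#' Softmax a choice distribution
#'
#' Converts a model's predictive probabilities into choice probabilities
#' with an inverse temperature `t`: each candidate's probability is
#' exponentiated (`exp(p * t)`) and renormalized, exactly the printed form
#' in which the exponent acts on the probabilities themselves. `t = 0`
#' flattens toward uniform; large `t` approaches hard maximization. The
#' conventional log-space softmax (`p^t`, i.e. exponentiating
#' log-probabilities) is available behind `log_space = TRUE`.
#'
#' @param dist A `choice_distribution`.
#' @param t Inverse temperature (>= 0).
#' @param log_space Use the log-probability convention instead.
#' @return A `choice_distribution`.
#' @export
softmax_choice <- function(dist, t, log_space = FALSE) {
  choice_distribution(dist$panel, softmax_vec(dist$prob, t, log_space))
}

#' Uniform baseline choice model
#'
#' Predicts each of the `m` candidates with probability `1/m` on every
#' trial; has zero free parameters, and is a softmax fixed point (the
#' inverse temperature has no effect on it).
#'
#' @param panel_size Number of candidates (>= 2).
#' @return Numeric vector of length `panel_size` summing to 1.
#' @export
baseline_model <- function(panel_size) {
  if (panel_size < 2) stop("panel must have at least 2 candidates")
  rep(1 / panel_size, panel_size)
}

#' Log likelihood of observed choices under softmaxed model predictions
#'
#' @param predictions Matrix of model predictive probabilities (one row per
#'   trial, one column per candidate), or a single vector recycled across
#'   trials.
#' @param choices Integer vector of chosen candidate indices, one per trial.
#' @param t Inverse temperature applied to each row before scoring.
#' @param log_space Softmax convention (see [softmax_choice()]).
#' @return Sum of log choice probabilities.
#' @export
dataset_loglik <- function(predictions, choices, t, log_space = FALSE) {
  if (is.vector(predictions))
    predictions <- matrix(predictions, nrow = length(choices),
                          ncol = length(predictions), byrow = TRUE)
  if (nrow(predictions) != length(choices)) stop("one prediction row per choice required")
  if (any(choices < 1 | choices > ncol(predictions)))
    stop("chosen outcome absent from the candidate panel")
  ll <- 0
  for (i in seq_along(choices)) {
    s <- softmax_vec(predictions[i, ], t, log_space)
    ll <- ll + log(s[choices[i]])
  }
  ll
}

#' Bayesian information criterion
#'
#' @param loglik Maximized log likelihood.
#' @param k Number of free parameters.
#' @param n Number of choices.
#' @return `-2 * loglik + k * log(n)`.
#' @export
bic <- function(loglik, k, n) -2 * loglik + k * log(n)

#' Kuder-Richardson Formula 21 consistency
#'
#' Inter-participant consistency of a single generalization task:
#' `rho = k/(k-1) * (1 - k*p*(1-p) / var(X))` where `k` is the number of
#' participants, `p` the chance probability of an option, and `X` the
#' vector of aggregated selection counts per option (zeros included).
#' `var(X)` is the population variance by default; the sample-variance
#' convention is available behind a flag. A flat count vector (zero
#' variance) leaves the statistic undefined and is signaled with a warning
#' and `NA` rather than silently computed.
#'
#' @param X Integer vector of per-option selection counts; must sum to `k`.
#' @param k Number of participants (>= 2).
#' @param p Chance probability of picking one option (in (0, 1)).
#' @param variance `"population"` (default) or `"sample"`.
#' @return The consistency coefficient (1 for perfect agreement).
#' @export
kr21 <- function(X, k, p, variance = c("population", "sample")) {
  variance <- match.arg(variance)
  if (k < 2) stop("k must be at least 2")
  if (p <= 0 || p >= 1) stop("p must lie strictly between 0 and 1")
  if (abs(sum(X) - k) > 1e-9) stop("selection counts must sum to k")
  v <- mean((X - mean(X))^2)
  if (variance == "sample") v <- v * length(X) / (length(X) - 1)
  if (v == 0) {
    warning("zero variance in selection counts: consistency undefined")
    return(NA_real_)
  }
  k / (k - 1) * (1 - k * p * (1 - p) / v)
}

# --- dataset plumbing ------------------------------------------------------

dataset_feature_cols <- function(space, role) paste0(role, "_", space$features)

row_stone <- function(row, space, role) {
  v <- vapply(space$features, function(f) as.character(row[[paste0(role, "_", f)]]),
              character(1))
  as_stone(stats::setNames(v, space$features))
}

# Chosen-outcome config indices for every row.
dataset_choice_indices <- function(dataset, space) {
  vapply(seq_len(nrow(dataset)), function(i)
    config_index(space, row_stone(dataset[i, ], space, "choice")), integer(1))
}

dataset_pair_indices <- function(dataset, space) {
  nc <- n_configs(space)
  vapply(seq_len(nrow(dataset)), function(i) {
    a <- config_index(space, row_stone(dataset[i, ], space, "agent"))
    r <- config_index(space, row_stone(dataset[i, ], space, "recipient"))
    pair_id(nc, a, r)
  }, integer(1))
}

scored_rows <- function(dataset) {
  if ("is_catch" %in% names(dataset)) which(!as.logical(dataset$is_catch))
  else seq_len(nrow(dataset))
}

# --- model fitting ---------------------------------------------------------

optimize_t <- function(ll_fun, t_max = 200, n_starts = 5, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  starts <- c(1, 10, stats::runif(n_starts - 2, 0, t_max / 4))
  best <- list(value = -Inf, par = NA_real_)
  for (s in starts) {
    o <- stats::optim(s, function(t) -ll_fun(t), method = "L-BFGS-B",
                      lower = 0, upper = t_max)
    if (-o$value > best$value) best <- list(value = -o$value, par = o$par)
  }
  best
}

fit_result <- function(model, par, loglik, k, n, grid = NULL, seed = NULL) {
  structure(list(model = model, par = par, loglik = loglik, k = k, n = n,
                 bic = bic(loglik, k, n), grid = grid, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model fit: %s  LL = %.1f  BIC = %.1f  (k = %d, n = %d)\n",
              x$model, x$loglik, x$bic, x$k, x$n))
  if (length(x$par)) {
    cat("  parameters:",
        paste(sprintf("%s = %.4g", names(x$par), unlist(x$par)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# Predictive matrix (rows x panel) for the universal model, per row.
uncala_row_predictions <- function(dataset, space, table, learning_by_condition,
                                   epsilon = 0) {
  nc <- n_configs(space)
  out <- matrix(NA_real_, nrow(dataset), nc)
  for (cond in unique(dataset$condition)) {
    post <- posterior_over_laws(table, learning_by_condition[[cond]], epsilon)
    if (post$degenerate) stop("degenerate posterior for condition ", cond)
    rows <- which(dataset$condition == cond)
    pairs <- dataset_pair_indices(dataset[rows, , drop = FALSE], space)
    for (pu in unique(pairs)) {
      a <- (pu - 1) %/% nc + 1; r <- (pu - 1) %% nc + 1
      task <- generalization_task(index_config(space, a), index_config(space, r),
                                  space = space)
      p <- weighted_predictive(table, post$posterior, task, epsilon,
                               warn_loss = FALSE)
      out[rows[pairs == pu], ] <- matrix(p, sum(pairs == pu), nc, byrow = TRUE)
    }
  }
  out
}

# Analytic single-example local-law predictive per row, for given params.
locala_row_predictions <- function(dataset, space, table, learning_by_condition,
                                   params, epsilon = 0) {
  nc <- n_configs(space)
  out <- matrix(NA_real_, nrow(dataset), nc)
  for (cond in unique(dataset$condition)) {
    learning <- learning_by_condition[[cond]]
    if (length(learning) != 1L)
      stop("analytic local-law path requires exactly one learning event")
    rows <- which(dataset$condition == cond)
    pairs <- dataset_pair_indices(dataset[rows, , drop = FALSE], space)
    for (pu in unique(pairs)) {
      a <- (pu - 1) %/% nc + 1; r <- (pu - 1) %% nc + 1
      task <- generalization_task(index_config(space, a), index_config(space, r),
                                  space = space)
      p <- locala_single_example(learning[[1]], task, params, table, epsilon)$prob
      out[rows[pairs == pu], ] <- matrix(p, sum(pairs == pu), nc, byrow = TRUE)
    }
  }
  out
}

#' Fit a choice model to a behavioral-style dataset by maximum likelihood
#'
#' Implements the fitting protocol used for model comparison: the baseline
#' has no parameters; the universal-law model optimizes the softmax inverse
#' temperature `t`; the single-example local-law model jointly optimizes
#' `(alpha, beta, t)` along its analytic path (bounded quasi-Newton with 5
#' seeded multi-starts); the sequential process model is fit by grid search
#' over `(alpha, beta)` with simulation-estimated predicted proportions and
#' `t` optimized per cell. Catch trials (rows flagged `is_catch`) are
#' excluded from scoring.
#'
#' @param model `"baseline"`, `"uncala"`, `"locala"` or `"localapro"`.
#' @param dataset Trial data.frame in the package CSV schema (see
#'   [write_trials()]).
#' @param space The `feature_space` of the experiment.
#' @param table A `law_table`.
#' @param designs Named list mapping each condition label to an
#'   `experiment_design` (supplies the learning events; for the sequential
#'   model, task sequences are taken from the data rows themselves).
#' @param grid For grid-searched models: list with numeric vectors `alpha`
#'   and `beta`.
#' @param gamma Focus parameter (fixed during fitting; default 0.5).
#' @param n_runs Simulated runs per grid cell and task sequence for the
#'   sequential model (default 300).
#' @param t_max Upper bound for the inverse temperature.
#' @param seed Seed for multi-starts and simulation.
#' @param epsilon Soft-likelihood mixture weight.
#' @return A `fit_result` with parameters, log likelihood, BIC, and the
#'   evaluated grid (when applicable).
#' @export
fit_model <- function(model = c("baseline", "uncala", "locala", "localapro"),
                      dataset, space, table, designs = NULL,
                      grid = list(alpha = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 1, 2),
                                  beta = c(0, 0.5, 1, 2, 4)),
                      gamma = 0.5, n_runs = 300, t_max = 200, seed = 1,
                      epsilon = 0) {
  model <- match.arg(model)
  if (nrow(dataset) == 0L) stop("dataset is empty")
  keep <- scored_rows(dataset)
  data <- dataset[keep, , drop = FALSE]
  n <- nrow(data)
  m <- n_configs(space)
  choices <- dataset_choice_indices(data, space)
  learning_by_condition <- if (!is.null(designs))
    lapply(designs, function(d) d$learning)

  if (model == "baseline") {
    ll <- n * log(1 / m)
    return(fit_result("baseline", list(), ll, 0L, n, seed = seed))
  }

  if (model == "uncala") {
    P <- uncala_row_predictions(data, space, table, learning_by_condition, epsilon)
    ll_fun <- function(t) loglik_fast(P, choices, t)
    best <- optimize_t(ll_fun, t_max, seed = seed)
    return(fit_result("uncala", list(t = best$par), best$value, 1L, n, seed = seed))
  }

  if (model == "locala") {
    obj <- function(par) {
      prm <- dp_params(exp(par[1]), exp(par[2]), gamma)
      P <- locala_row_predictions(data, space, table, learning_by_condition,
                                  prm, epsilon)
      -loglik_fast(P, choices, max(par[3], 0))
    }
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    starts <- rbind(c(0, 0, 10),
                    matrix(c(stats::runif(4, -3, 2), stats::runif(4, -3, 3),
                             stats::runif(4, 1, 40)), ncol = 3))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      o <- try(stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                            lower = c(-12, -12, 0), upper = c(6, 8, t_max)),
               silent = TRUE)
      if (!inherits(o, "try-error") && (is.null(best) || o$value < best$value))
        best <- o
    }
    par <- list(alpha = exp(best$par[1]), beta = exp(best$par[2]),
                t = best$par[3])
    return(fit_result("locala", par, -best$value, 3L, n, seed = seed))
  }

  # sequential process model: grid over (alpha, beta), t optimized per cell
  seqs <- localapro_sequence_groups(data, space)
  cells <- expand.grid(alpha = grid$alpha, beta = grid$beta,
                       KEEP.OUT.ATTRS = FALSE)
  cells$t <- NA_real_; cells$loglik <- NA_real_
  best <- list(loglik = -Inf)
  for (ci in seq_len(nrow(cells))) {
    prm <- dp_params(cells$alpha[ci], cells$beta[ci], gamma)
    run_pred <- simulate_sequence_predictions(seqs, prm, table, space, designs,
                                              n_runs, seed, epsilon)
    ll_fun <- function(t) localapro_loglik(run_pred, seqs, choices, t)
    o <- stats::optimize(function(t) -ll_fun(t), c(0, t_max))
    cells$t[ci] <- o$minimum; cells$loglik[ci] <- -o$objective
    if (-o$objective > best$loglik)
      best <- list(loglik = -o$objective, alpha = cells$alpha[ci],
                   beta = cells$beta[ci], t = o$minimum)
  }
  par <- list(alpha = best$alpha, beta = best$beta, t = best$t)
  fit_result("localapro", par, best$loglik, 3L, n, grid = cells, seed = seed)
}

# Vectorized log likelihood over a prediction matrix.
loglik_fast <- function(P, choices, t, log_space = FALSE) {
  X <- if (log_space) t * log(pmax(P, .Machine$double.xmin)) else P * t
  E <- exp(X - apply(X, 1, max))
  sum(log(E[cbind(seq_along(choices), choices)] / rowSums(E)))
}

# Group rows into per-participant task sequences for the sequential model.
localapro_sequence_groups <- function(data, space) {
  key_cols <- intersect(c("participant_id", "condition", "transfer_order"),
                        names(data))
  pid <- do.call(paste, c(data[key_cols], sep = "|"))
  groups <- split(seq_len(nrow(data)), pid)
  out <- list()
  for (g in names(groups)) {
    rows <- groups[[g]][order(data$trial_index[groups[[g]]])]
    sig_rows <- data[rows, , drop = FALSE]
    pairs <- dataset_pair_indices(sig_rows, space)
    sig <- paste(sig_rows$condition[1], paste(pairs, collapse = ","))
    out[[g]] <- list(rows = rows, condition = sig_rows$condition[1],
                     pairs = pairs, signature = sig)
  }
  out
}

# Simulated per-run predictive arrays for each distinct task sequence.
simulate_sequence_predictions <- function(seqs, params, table, space, designs,
                                          n_runs, seed, epsilon) {
  sigs <- vapply(seqs, `[[`, character(1), "signature")
  out <- list()
  for (sig in unique(sigs)) {
    s <- seqs[[match(sig, sigs)]]
    design <- designs[[s$condition]]
    nc <- n_configs(space)
    tasks <- lapply(s$pairs, function(pu) {
      a <- (pu - 1) %/% nc + 1; r <- (pu - 1) %% nc + 1
      generalization_task(index_config(space, a), index_config(space, r),
                          space = space)
    })
    pseudo <- experiment_design(s$condition, space, design$learning, tasks,
                                "as_observed")
    cache <- design_cache(pseudo, table, epsilon)
    arr <- array(NA_real_, c(n_runs, length(tasks), nc))
    for (rn in seq_len(n_runs)) {
      run <- localapro_run(pseudo, params, table,
                           seed = derive_seed(seed, rn + 7 * match(sig, unique(sigs))),
                           epsilon = epsilon, cache = cache,
                           keep_distributions = FALSE)
      arr[rn, , ] <- run$pred_matrix
    }
    out[[sig]] <- arr
  }
  out
}

# Marginal choice log likelihood for the sequential model: the probability
# of a choice is the average over runs of its softmaxed probability.
# Marginal probabilities depend only on (sequence, trial), so they are
# computed once per t and looked up per participant row.
localapro_loglik <- function(run_pred, seqs, choices, t) {
  marg <- lapply(run_pred, function(arr) {
    nt <- dim(arr)[2]
    vapply(seq_len(nt), function(j) {
      E <- exp(t * arr[, j, , drop = TRUE])
      colMeans(E / rowSums(E))
    }, numeric(dim(arr)[3]))               # candidates x trials
  })
  ll <- 0
  for (s in seqs) {
    M <- marg[[s$signature]]
    ll <- ll + sum(log(M[cbind(choices[s$rows], seq_along(s$rows))]))
  }
  ll
}
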