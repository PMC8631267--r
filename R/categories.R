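# Causal categories: a Dirichlet-process mixture over agent-recipient pairs
# in which every category carries a mean feature profile (Dirichlet-smoothed
# value counts, weighted between agent and recipient by the focus parameter
# gamma) and one causal law drawn from the grammar.

#' Dirichlet-process categorization parameters
#'
#' @param alpha Concentration (> 0): larger values favor more categories.
#' @param beta Dirichlet smoothing (>= 0) added as pseudo-counts to the
#'   feature-value counts; larger values make categorization less sensitive
#'   to feature similarity.
#' @param gamma Focus (in `[0, 1]`): probability mass on agent features when
#'   building category profiles; 1 = agent-only, 0 = recipient-only,
#'   0.5 = both equally.
#' @param mu_norm How mean-feature profiles are normalized: `"feature"`
#'   (per-feature categorical, the Dirichlet-categorical posterior
#'   predictive; default) or `"pooled"` (counts normalized over all feature
#'   values jointly).
#' @return List of class `dp_params`.
#' @export
dp_params <- function(alpha, beta = 0, gamma = 0.5,
                      mu_norm = c("feature", "pooled")) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (!is.numeric(beta) || beta < 0) stop("beta must be >= 0")
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 mu_norm = match.arg(mu_norm)),
            class = "dp_params")
}

#' Chinese-restaurant-process assignment weights
#'
#' For the event at index `i`, the probability of joining each existing
#' category is its size among the other events over `n - 1 + alpha`; a new
#' category gets `alpha / (n - 1 + alpha)`, where `n - 1` counts the other
#' assigned events. The first observation joins the first category with
#' probability 1.
#'
#' @param partition Integer vector of category assignments (`NA` for
#'   unassigned events).
#' @param i Index of the event being (re)assigned; its own current
#'   assignment is ignored.
#' @param alpha Concentration parameter (> 0).
#' @return Named numeric vector: one weight per existing category plus
#'   `"new"`; sums to 1.
#' @export
crp_weights <- function(partition, i, alpha) {
  if (alpha <= 0) stop("alpha must be > 0")
  others <- partition[-i]
  others <- others[!is.na(others)]
  sizes <- table(others)
  n1 <- length(others)
  w <- c(as.numeric(sizes), alpha) / (n1 + alpha)
  names(w) <- c(names(sizes), "new")
  w
}

# --- mean feature profiles -------------------------------------------------

#' Mean feature profile of a category
#'
#' Per-feature value counts over the category's member pairs, with agent
#' values weighted `gamma` and recipient values `1 - gamma`, plus `beta`
#' pseudo-counts, normalized (per feature, or pooled over all values; see
#' [dp_params()]). An empty member list yields the uniform prior profile.
#'
#' @param members List of `causal_event`s (results are ignored; only agent
#'   and recipient features enter the profile).
#' @param params A `dp_params`.
#' @param space The `feature_space`.
#' @return Object of class `mu_profile`.
#' @export
category_mean <- function(members, params, space) {
  counts <- lapply(space$features, function(f) {
    cnt <- stats::setNames(rep(params$beta, length(space$values[[f]])),
                           space$values[[f]])
    for (ev in members) {
      cnt[[ev$agent[[f]]]] <- cnt[[ev$agent[[f]]]] + params$gamma
      cnt[[ev$recipient[[f]]]] <- cnt[[ev$recipient[[f]]]] + (1 - params$gamma)
    }
    cnt
  })
  names(counts) <- space$features
  mu <- if (params$mu_norm == "pooled") {
    tot <- sum(unlist(counts))
    if (tot <= 0) lapply(counts, function(c) rep(1 / sum(lengths(counts)), length(c)))
    else lapply(counts, function(c) c / tot)
  } else {
    lapply(counts, function(c) {
      if (sum(c) <= 0) rep(1 / length(c), length(c)) else c / sum(c)
    })
  }
  mu <- lapply(mu, as.numeric)
  for (f in space$features) names(mu[[f]]) <- space$values[[f]]
  structure(list(mu = mu, params = params, n_members = length(members)),
            class = "mu_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Feature-similarity likelihood of an agent-recipient pair under a profile
#'
#' Product over features of the profile probability of the pair's
#' role-selected values, interpolating between agent (`gamma = 1`) and
#' recipient (`gamma = 0`).
#'
#' @param agent,recipient Stones.
#' @param mu A `mu_profile` from [category_mean()].
#' @return Probability (not normalized across pairs).
#' @export
pair_feature_likelihood <- function(agent, recipient, mu) {
  g <- mu$params$gamma
  p <- 1
  for (f in names(mu$mu)) {
    m <- mu$mu[[f]]
    pa <- m[[agent[[f]]]]
    pr <- m[[recipient[[f]]]]
    if (is.null(pa) || is.null(pr)) stop("pair value outside the profile's space")
    p <- p * (g * pa + (1 - g) * pr)
  }
  p
}

null_profile <- function(params, space) category_mean(list(), params, space)

# --- analytic single-example model ----------------------------------------

#' Local-causal-laws prediction from a single learning example
#'
#' The analytic two-component case of the DP model: the learning event
#' defines category 1; a generalization task either joins it (probability
#' proportional to `1/(1+alpha)` times the feature-similarity of the task
#' pair to the category profile) and receives the posterior predictive of
#' the learned laws, or opens a new category (proportional to
#' `alpha/(1+alpha)` times the prior profile likelihood) and receives the
#' prior predictive. Each task is scored independently: this model has no
#' order effects. As `alpha` tends to 0 it reduces exactly to the universal
#' model; as `alpha` grows it reverts to the prior predictive.
#'
#' @param learning A single `causal_event` with known result.
#' @param task A `generalization_task`.
#' @param params A `dp_params`.
#' @param table A `law_table`.
#' @param epsilon Soft-likelihood mixture weight.
#' @return A `choice_distribution`; attribute `"p_same"` gives the
#'   probability the task joined the learning category.
#' @export
locala_single_example <- function(learning, task, params, table, epsilon = 0) {
  if (inherits(learning, "causal_event")) learning <- list(learning)
  if (length(learning) != 1L) stop("exactly one learning event required")
  space <- table$space
  post <- posterior_over_laws(table, learning, epsilon = epsilon)
  if (post$degenerate) stop("degenerate law posterior for the learning event")

  mu1 <- category_mean(learning, params, space)
  mu0 <- null_profile(params, space)
  w1 <- (1 / (1 + params$alpha)) * pair_feature_likelihood(task$agent, task$recipient, mu1)
  w0 <- (params$alpha / (1 + params$alpha)) * pair_feature_likelihood(task$agent, task$recipient, mu0)
  p_same <- w1 / (w1 + w0)

  p_post <- weighted_predictive(table, post$posterior, task, epsilon = epsilon,
                                warn_loss = FALSE)
  p_prior <- weighted_predictive(table, table$prior, task, epsilon = epsilon,
                                 warn_loss = FALSE)
  p <- p_same * p_post + (1 - p_same) * p_prior
  out <- choice_distribution(task$panel, p / sum(p))
  attr(out, "p_same") <- p_same
  out
}

# --- Gibbs sampler over latent partitions ----------------------------------

# Law posterior weights for a set of member events (unnormalized).
member_law_weights <- function(table, members, epsilon = 0) {
  w <- table$prior
  for (ev in members) w <- w * table_event_likelihood(table, ev, epsilon = epsilon)
  w
}

sample_law_index <- function(w) {
  if (sum(w) <= 0) stop("no law in the table explains a category's events")
  sample.int(length(w), 1L, prob = w)
}

#' Gibbs sampler for the latent-causal-category posterior
#'
#' Approximates the posterior over partitions of the events into causal
#' categories. Each sweep reassigns every event in random order: the
#' conditional for event `i` multiplies the CRP weight, the
#' feature-similarity of its pair to the category profile computed from the
#' other members, and the likelihood of its observed result under the
#' category's current law (for a new category, the prior-marginal
#' likelihood). After each reassignment the affected categories' laws are
#' resampled from their members' law posterior. Samples after burn-in are
#' retained.
#'
#' @param events List of `causal_event`s with known results.
#' @param params A `dp_params`.
#' @param table A `law_table`.
#' @param n_iter Total sweeps (default 500).
#' @param burn_in Sweeps discarded (default 100; must be < `n_iter`).
#' @param seed Integer seed.
#' @param epsilon Soft-likelihood mixture weight.
#' @return Object of class `gibbs_state` with retained `samples` (each a
#'   list with assignment vector `z` and per-category law indices `laws`),
#'   the final partition, and the inputs.
#' @export
gibbs_locala <- function(events, params, table, n_iter = 500, burn_in = 100,
                         seed = 1L, epsilon = 0) {
  if (length(events) < 1L) stop("at least one event required")
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  space <- table$space
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n <- length(events)
  z <- rep(1L, n)
  laws <- c(sample_law_index(member_law_weights(table, events, epsilon)))

  lik_cache <- vapply(events, function(ev)
    table_event_likelihood(table, ev, epsilon = epsilon), numeric(n_laws(table)))
  # lik_cache: laws x events
  prior_marg <- as.numeric(table$prior %*% lik_cache)  # per-event prior-marginal

  resample_cat_law <- function(k) {
    w <- table$prior
    for (j in which(z == k)) w <- w * lik_cache[, j]
    laws[k] <<- sample_law_index(w)
  }

  samples <- vector("list", n_iter - burn_in)
  for (it in seq_len(n_iter)) {
    for (i in sample.int(n)) {
      zi_old <- z[i]
      z[i] <- NA_integer_
      cats <- sort(unique(z[!is.na(z)]))
      wts <- numeric(length(cats) + 1L)
      for (ci in seq_along(cats)) {
        k <- cats[ci]
        members <- events[which(z == k)]
        muk <- category_mean(members, params, space)
        wts[ci] <- length(members) *
          pair_feature_likelihood(events[[i]]$agent, events[[i]]$recipient, muk) *
          lik_cache[laws[k], i]
      }
      mu0 <- null_profile(params, space)
      wts[length(wts)] <- params$alpha *
        pair_feature_likelihood(events[[i]]$agent, events[[i]]$recipient, mu0) *
        prior_marg[i]
      if (sum(wts) <= 0) stop("event ", i, " is unexplainable under the table")
      pick <- sample.int(length(wts), 1L, prob = wts)
      if (pick <= length(cats)) {
        z[i] <- cats[pick]
      } else {
        z[i] <- max(c(0L, z[!is.na(z)])) + 1L
        laws <- c(laws, 0L)
      }
      # relabel to compact 1..K and resample changed categories' laws
      uz <- sort(unique(z))
      z <- match(z, uz)
      laws <- laws[uz]
      resample_cat_law(z[i])
      if (!is.na(zi_old) && zi_old %in% uz) {
        k_old <- match(zi_old, uz)
        if (k_old != z[i]) resample_cat_law(k_old)
      }
    }
    if (it > burn_in)
      samples[[it - burn_in]] <- list(z = z, laws = laws)
  }
  structure(list(samples = samples, z = z, laws = laws, events = events,
                 params = params, table = table, epsilon = epsilon,
                 n_iter = n_iter, burn_in = burn_in, seed = seed),
            class = "gibbs_state")
}

#' @export
print.gibbs_state <- function(x, ...) {
  k <- vapply(x$samples, function(s) length(unique(s$z)), integer(1))
  cat(sprintf("Gibbs state: %d retained samples over %d events; mean #categories %.2f\n",
              length(x$samples), length(x$events), mean(k)))
  invisible(x)
}

#' Dump retained partition samples as JSON lines
#'
#' One line per retained sample: iteration number, assignment vector, and
#' the per-category law strings.
#'
#' @param state A `gibbs_state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gibbs_samples <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(state$samples)) {
    s <- state$samples[[i]]
    rec <- list(iteration = jsonlite::unbox(state$burn_in + i),
                assignments = s$z,
                laws = state$table$strings[s$laws])
    writeLines(as.character(jsonlite::toJSON(rec)), con)
  }
  invisible(path)
}

#' Posterior probability that two events share a category
#'
#' @param state A `gibbs_state`.
#' @param i,j Event indices.
#' @return Monte-Carlo estimate of the co-assignment probability.
#' @export
coassignment_prob <- function(state, i, j) {
  mean(vapply(state$samples, function(s) s$z[i] == s$z[j], logical(1)))
}

#' Local-causal-laws prediction from a Gibbs state
#'
#' Aggregates the posterior predictive over the retained partition samples.
#' Within each sample the task pair is assigned to each existing category
#' (CRP weight times feature similarity) or a new one; existing categories
#' predict through the law posterior of their members, a new category
#' through the prior predictive. Each generalization task is scored
#' independently against the learning partition.
#'
#' @param state A `gibbs_state`.
#' @param task A `generalization_task`.
#' @param params A `dp_params` (defaults to the state's).
#' @return A `choice_distribution`; use [argmax_choice()] for the discrete
#'   choice.
#' @export
locala_predict <- function(state, task, params = state$params) {
  if (length(state$samples) == 0L) stop("empty sample set")
  table <- state$table
  space <- table$space
  events <- state$events
  n <- length(events)
  mu0 <- null_profile(params, space)
  p0 <- weighted_predictive(table, table$prior, task, epsilon = state$epsilon,
                            warn_loss = FALSE)
  lik0 <- pair_feature_likelihood(task$agent, task$recipient, mu0)

  # cache per distinct partition (partitions repeat across samples)
  keys <- vapply(state$samples, function(s) paste(s$z, collapse = ","), character(1))
  acc <- numeric(nrow(task$panel))
  for (key in unique(keys)) {
    s <- state$samples[[match(key, keys)]]
    cats <- sort(unique(s$z))
    wts <- numeric(length(cats) + 1L)
    preds <- vector("list", length(cats))
    for (ci in seq_along(cats)) {
      members <- events[s$z == cats[ci]]
      muk <- category_mean(members, params, space)
      wts[ci] <- length(members) / (n + params$alpha) *
        pair_feature_likelihood(task$agent, task$recipient, muk)
      wlaw <- member_law_weights(table, members, state$epsilon)
      preds[[ci]] <- weighted_predictive(table, wlaw / sum(wlaw), task,
                                         epsilon = state$epsilon, warn_loss = FALSE)
    }
    wts[length(wts)] <- params$alpha / (n + params$alpha) * lik0
    wts <- wts / sum(wts)
    p <- wts[length(wts)] * p0
    for (ci in seq_along(cats)) p <- p + wts[ci] * preds[[ci]]
    acc <- acc + (p / sum(p)) * sum(keys == key)
  }
  acc <- acc / length(state$samples)
  choice_distribution(task$panel, acc / sum(acc))
}

# --- sequential process model ----------------------------------------------

# Precomputed quantities shared by every run over one design: per-task pair
# value indices, panel config indices, per-law outcome probabilities over the
# panel, and the learning events' law-posterior weights.
design_cache <- function(design, table, epsilon = 0) {
  space <- table$space
  tasks <- lapply(design$tasks, function(task) {
    panel_idx <- panel_config_indices(space, task$panel)
    probs <- table_outcome_probs(table, task$agent, task$recipient, epsilon)
    list(a_idx = value_index(space, task$agent),
         r_idx = value_index(space, task$recipient),
         panel_idx = panel_idx,
         probs = probs[, panel_idx, drop = FALSE])
  })
  learn <- lapply(design$learning, function(ev)
    list(a_idx = value_index(space, ev$agent),
         r_idx = value_index(space, ev$recipient)))
  list(tasks = tasks, learn = learn,
       law_w = member_law_weights(table, design$learning, epsilon),
       v_sizes = vapply(space$values, length, integer(1)))
}

# Count-based pair likelihood used by the fast sequential path; equivalent to
# pair_feature_likelihood(category_mean(...)) with per-feature normalization.
counts_pairlik <- function(cnt, m, a_idx, r_idx, params, v_sizes) {
  g <- params$gamma; b <- params$beta
  pooled <- params$mu_norm == "pooled"
  p <- 1
  for (f in seq_along(v_sizes)) {
    denom <- if (pooled) length(v_sizes) * m + b * sum(v_sizes) else m + b * v_sizes[f]
    if (denom <= 0) { p <- p / (if (pooled) sum(v_sizes) else v_sizes[f]); next }
    p <- p * (g * (cnt[[f]][a_idx[f]] + b) + (1 - g) * (cnt[[f]][r_idx[f]] + b)) / denom
  }
  p
}

#' Run the sequential commitment-based category process over a design
#'
#' The process model commits to its own categorization decisions: the
#' learning events seed category 1 with one causal law sampled from their
#' posterior; each generalization task is then assigned (sampled) to an
#' existing category (whose law is applied to predict the result) or to a
#' new category (whose law is sampled from the prior), and the assignment is
#' appended to the partition before the next task. Because assignments feed
#' back into the category sizes and profiles, predictions depend on task
#' order, producing generalization-order effects. A single run is one
#' stochastic trajectory; average many seeded runs to estimate predicted
#' proportions.
#'
#' @param design An `experiment_design`.
#' @param params A `dp_params`.
#' @param table A `law_table`.
#' @param seed Integer seed.
#' @param epsilon Soft-likelihood mixture weight.
#' @param cache Optional precomputed design cache (internal; built
#'   automatically when `NULL`).
#' @param keep_distributions If `FALSE`, return the per-trial probability
#'   rows as a plain matrix (`pred_matrix`) instead of
#'   `choice_distribution` objects (faster for large simulations).
#' @return List of class `localapro_run` with `predictions` (one
#'   `choice_distribution` per task, or a `pred_matrix`), `assignments`, and
#'   the per-category `laws` (law indices).
#' @export
localapro_run <- function(design, params, table, seed = 1L, epsilon = 0,
                          cache = NULL, keep_distributions = TRUE) {
  space <- table$space
  if (is.null(cache)) cache <- design_cache(design, table, epsilon)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  v_sizes <- cache$v_sizes
  nf <- length(v_sizes)
  laws <- c(sample_law_index(cache$law_w))
  # per-category feature-value counts (gamma-weighted) and sizes
  cnt1 <- lapply(v_sizes, function(V) numeric(V))
  for (le in cache$learn) {
    for (f in seq_len(nf)) {
      cnt1[[f]][le$a_idx[f]] <- cnt1[[f]][le$a_idx[f]] + params$gamma
      cnt1[[f]][le$r_idx[f]] <- cnt1[[f]][le$r_idx[f]] + (1 - params$gamma)
    }
  }
  cnts <- list(cnt1)
  sizes <- length(cache$learn)
  lik0 <- prod(1 / v_sizes)

  n_tasks <- length(cache$tasks)
  pred <- matrix(0, n_tasks, length(cache$tasks[[1]]$panel_idx))
  assignments <- integer(n_tasks)
  for (ti in seq_len(n_tasks)) {
    tk <- cache$tasks[[ti]]
    n_assigned <- sum(sizes)
    wts <- numeric(length(cnts) + 1L)
    for (k in seq_along(cnts))
      wts[k] <- sizes[k] * counts_pairlik(cnts[[k]], sizes[k], tk$a_idx, tk$r_idx,
                                          params, v_sizes)
    wts[length(wts)] <- params$alpha * lik0
    wts <- wts / (n_assigned + params$alpha)
    pick <- sample.int(length(wts), 1L, prob = wts)
    if (pick > length(cnts)) {
      cnts[[pick]] <- lapply(v_sizes, function(V) numeric(V))
      sizes[pick] <- 0L
      laws <- c(laws, sample_law_index(table$prior))
    }
    p <- tk$probs[laws[pick], ]
    if (sum(p) <= 0) p <- rep(1, length(p))   # inapplicable law: uninformative
    pred[ti, ] <- p / sum(p)
    assignments[ti] <- pick
    sizes[pick] <- sizes[pick] + 1L
    for (f in seq_len(nf)) {
      cnts[[pick]][[f]][tk$a_idx[f]] <- cnts[[pick]][[f]][tk$a_idx[f]] + params$gamma
      cnts[[pick]][[f]][tk$r_idx[f]] <- cnts[[pick]][[f]][tk$r_idx[f]] + (1 - params$gamma)
    }
  }
  predictions <- if (keep_distributions) {
    lapply(seq_len(n_tasks), function(ti)
      choice_distribution(design$tasks[[ti]]$panel, pred[ti, ]))
  } else NULL
  structure(list(predictions = predictions, pred_matrix = pred,
                 assignments = assignments, laws = laws, params = params,
                 seed = seed),
            class = "localapro_run")
}

#' @export
print.localapro_run <- function(x, ...) {
  cat(sprintf("Sequential-process run: %d tasks, %d categories (seed %d)\n",
              length(x$predictions), length(x$members), x$seed))
  invisible(x)
}
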