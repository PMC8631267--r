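# Synthetic participants: seeded end-to-end simulation of each choice
# model over an experiment design, dataset CSV I/O, per-task consistency
# summaries, and the order-effect harness.

# Participant-level seeds derive from the master seed through a fixed affine
# counter, so adding participants never perturbs existing ones.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + as.numeric(i) * 7919) %% 2147483629)
}

model_trial_predictions <- function(model, design, table, params, epsilon,
                                    gibbs_control) {
  nc <- n_configs(design$space)
  if (model == "baseline")
    return(matrix(1 / nc, length(design$tasks), nc))
  if (model == "uncala") {
    post <- posterior_over_laws(table, design$learning, epsilon)
    return(t(vapply(design$tasks, function(task)
      uncala_predict(post, task, epsilon)$prob, numeric(nc))))
  }
  if (model == "locala") {
    if (length(design$learning) == 1L) {
      return(t(vapply(design$tasks, function(task)
        locala_single_example(design$learning[[1]], task, params, table,
                              epsilon)$prob, numeric(nc))))
    }
    st <- gibbs_locala(design$learning, params, table,
                       n_iter = gibbs_control$n_iter,
                       burn_in = gibbs_control$burn_in,
                       seed = gibbs_control$seed, epsilon = epsilon)
    return(t(vapply(design$tasks, function(task)
      locala_predict(st, task)$prob, numeric(nc))))
  }
  stop("unknown model tag: ", model)
}

#' Simulate a population of participants from a choice model
#'
#' Each participant is an independent seeded run of the generating model
#' over the design's task sequence; per-trial choices are sampled from the
#' softmaxed predictive distribution. For the sequential process model each
#' participant is one fresh stochastic trajectory (its own category
#' commitments); the other models share one predictive per design.
#'
#' @param model `"baseline"`, `"uncala"`, `"locala"` or `"localapro"`.
#' @param design An `experiment_design`.
#' @param table A `law_table` (unused by the baseline).
#' @param n_participants Number of simulated participants.
#' @param t Softmax inverse temperature.
#' @param params A `dp_params` (required for the category models).
#' @param seed Master seed.
#' @param epsilon Soft-likelihood mixture weight.
#' @param gibbs_control List with `n_iter`, `burn_in`, `seed` for the
#'   multi-example local-law model.
#' @param id_offset Added to participant ids (for pooling conditions).
#' @return Data.frame in the trial CSV schema: `participant_id`,
#'   `condition`, `transfer_order`, `trial_index`, `is_catch`, then
#'   `agent_*`, `recipient_*`, `choice_*` feature columns.
#' @export
simulate_dataset <- function(model = c("baseline", "uncala", "locala", "localapro"),
                             design, table = NULL, n_participants = 100,
                             t = 10, params = NULL, seed = 1, epsilon = 0,
                             gibbs_control = list(n_iter = 400, burn_in = 100,
                                                  seed = 1),
                             id_offset = 0L) {
  model <- match.arg(model)
  if (model %in% c("locala", "localapro") && is.null(params))
    stop("model '", model, "' requires dp_params")
  if (model != "baseline" && is.null(table))
    stop("model '", model, "' requires a law table")
  space <- design$space
  nc <- n_configs(space)
  n_tasks <- length(design$tasks)
  cfg <- space_configs(space)

  shared <- if (model != "localapro")
    model_trial_predictions(model, design, table, params, epsilon, gibbs_control)
  cache <- if (model == "localapro") design_cache(design, table, epsilon)

  panel_idx <- lapply(design$tasks, function(task)
    panel_config_indices(space, task$panel))

  rows <- vector("list", n_participants)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (i in seq_len(n_participants)) {
    pseed <- derive_seed(seed, i)
    P <- if (model == "localapro") {
      localapro_run(design, params, table, seed = pseed, epsilon = epsilon,
                    cache = cache, keep_distributions = FALSE)$pred_matrix
    } else shared
    set.seed(derive_seed(pseed, 1))
    choice_cfg <- integer(n_tasks)
    for (ti in seq_len(n_tasks)) {
      pr <- softmax_vec(P[ti, if (model == "localapro") TRUE else panel_idx[[ti]]], t)
      pick <- sample.int(length(pr), 1L, prob = pr)
      choice_cfg[ti] <- panel_idx[[ti]][pick]
    }
    df <- data.frame(participant_id = i + id_offset,
                     condition = design$condition,
                     transfer_order = design$transfer_order,
                     trial_index = seq_len(n_tasks),
                     is_catch = vapply(design$tasks, `[[`, logical(1), "is_catch"),
                     stringsAsFactors = FALSE)
    for (f in space$features) {
      df[[paste0("agent_", f)]] <- vapply(design$tasks, function(tk) tk$agent[[f]], character(1))
      df[[paste0("recipient_", f)]] <- vapply(design$tasks, function(tk) tk$recipient[[f]], character(1))
      df[[paste0("choice_", f)]] <- cfg[[f]][choice_cfg]
    }
    rows[[i]] <- df
  }
  out <- do.call(rbind, rows)
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  out
}

#' Per-task inter-participant consistency of a dataset
#'
#' Aggregates selection counts per option for every
#' (condition, transfer order, trial) cell and computes the KR-21
#' coefficient with chance probability `1/m` over the `m`-option panel.
#' Catch trials are excluded.
#'
#' @param dataset Trial data.frame in the package schema.
#' @param space The experiment's `feature_space` (its configuration count is
#'   the panel size).
#' @param variance Variance convention passed to [kr21()].
#' @return Data.frame with columns `condition`, `transfer_order`,
#'   `trial_index`, `k`, `rho`.
#' @export
consistency_by_task <- function(dataset, space, variance = "population") {
  data <- dataset[scored_rows(dataset), , drop = FALSE]
  m <- n_configs(space)
  idx <- dataset_choice_indices(data, space)
  key <- interaction(data$condition, data$transfer_order, data$trial_index,
                     drop = TRUE)
  out <- list()
  for (g in levels(key)) {
    rows <- which(key == g)
    X <- tabulate(idx[rows], nbins = m)
    k <- length(rows)
    rho <- suppressWarnings(kr21(X, k, 1 / m, variance))
    out[[g]] <- data.frame(condition = data$condition[rows[1]],
                           transfer_order = data$transfer_order[rows[1]],
                           trial_index = data$trial_index[rows[1]],
                           k = k, rho = rho, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$condition, res$transfer_order, res$trial_index), ]
}

#' Order-effect simulation harness for the sequential process model
#'
#' Simulates near-first and far-first populations of sequential-process
#' participants for each requested condition and concentration value, and
#' summarizes mean per-task consistency plus the per-trial modal-choice
#' proportions. Small concentrations keep predictions close to the learning
#' posterior throughout and induce the near/far order effect; large
#' concentrations push every trial toward the prior predictive.
#'
#' @param table A `law_table` for the one-shot experiment space.
#' @param conditions Condition labels (default A1-A5).
#' @param alphas Concentration values to profile.
#' @param beta,gamma Remaining category parameters.
#' @param t Softmax inverse temperature for simulated choices.
#' @param n Participants per condition and order arm.
#' @param seed Master seed.
#' @return List with `summary` (condition x order x alpha mean consistency)
#'   and `proportions` (named list of trial-by-candidate modal-choice
#'   proportion matrices).
#' @export
order_effect_experiment <- function(table, conditions = paste0("A", 1:5),
                                    alphas = 0.38, beta = 1, gamma = 0.5,
                                    t = 10, n = 200, seed = 1) {
  space <- table$space
  summary <- list(); proportions <- list()
  for (alpha in alphas) {
    params <- dp_params(alpha, beta, gamma)
    for (cond in conditions) {
      for (ord in c("near_first", "far_first")) {
        design <- exp1_design(cond, ord, feature_order_seed = seed)
        ds <- simulate_dataset("localapro", design, table, n_participants = n,
                               t = t, params = params,
                               seed = derive_seed(seed, match(cond, conditions) * 2 +
                                                    (ord == "far_first")))
        cons <- consistency_by_task(ds, space)
        summary[[length(summary) + 1L]] <-
          data.frame(condition = cond, transfer_order = ord, alpha = alpha,
                     beta = beta, mean_rho = mean(cons$rho, na.rm = TRUE),
                     stringsAsFactors = FALSE)
        idx <- dataset_choice_indices(ds, space)
        prop <- matrix(0, length(design$tasks), n_configs(space))
        for (ti in seq_along(design$tasks)) {
          rows <- ds$trial_index == ti
          prop[ti, ] <- tabulate(idx[rows], nbins = n_configs(space)) / sum(rows)
        }
        proportions[[paste(cond, ord, alpha, sep = "_")]] <- prop
      }
    }
  }
  list(summary = do.call(rbind, summary), proportions = proportions)
}

#' Test per-condition choice consistency against random selection
#'
#' Thin delegation to [stats::fisher.test()] on the trial-by-option
#' contingency table of selection counts (Monte-Carlo p-value, since the
#' tables are larger than 2 x 2). Catch trials are excluded.
#'
#' @param dataset Trial data.frame in the package schema (one condition and
#'   order, or pool as desired).
#' @param space The experiment's `feature_space`.
#' @param B Monte-Carlo replicates for the p-value.
#' @return The `htest` object from [stats::fisher.test()].
#' @export
consistency_fisher_test <- function(dataset, space, B = 2000) {
  data <- dataset[scored_rows(dataset), , drop = FALSE]
  idx <- dataset_choice_indices(data, space)
  tabmat <- table(data$trial_index, idx)
  stats::fisher.test(tabmat, simulate.p.value = TRUE, B = B)
}

# --- CSV I/O ---------------------------------------------------------------

#' Write a trial dataset to CSV
#'
#' @param dataset Trial data.frame in the package schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial dataset from CSV, validating against a feature space
#'
#' Checks the column schema and that every agent/recipient/choice value is
#' admissible; violations are reported with row numbers and the admissible
#' values.
#'
#' @param path CSV path.
#' @param space The `feature_space` the trials must live in.
#' @return Validated data.frame.
#' @export
read_trials <- function(path, space) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$participant_id <- as.integer(df$participant_id)
  df$trial_index <- as.integer(df$trial_index)
  if ("is_catch" %in% names(df)) df$is_catch <- as.logical(df$is_catch)
  need <- c("participant_id", "condition", "trial_index",
            unlist(lapply(c("agent_", "recipient_", "choice_"),
                          paste0, space$features)))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  for (role in c("agent", "recipient", "choice")) {
    for (f in space$features) {
      col <- paste0(role, "_", f)
      bad <- which(!(df[[col]] %in% space$values[[f]]))
      if (length(bad))
        stop(sprintf("row %s: value '%s' in column %s is not admissible (admissible: %s)",
                     bad[1], df[[col]][bad[1]], col,
                     paste(space$values[[f]], collapse = ", ")))
    }
  }
  df
}
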