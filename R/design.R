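# Experiment designs: learning conditions, generalization-task grids,
# candidate panels, and the dissimilarity score.
#
# The task grids are shipped as data (inst/extdata/*.json) rather than code,
# so per-task feature assignments can be corrected without touching the
# generators.

design_config_env <- new.env(parent = emptyenv())

#' Read a design configuration file
#'
#' Design configs are JSON with keys `features`, `conditions`, `task_grid`
#' and `menu`; [write_design_config()] round-trips them bit-exactly.
#'
#' @param path Path to a JSON design config (defaults used by
#'   [exp1_design()]/[exp2_design()] ship with the package).
#' @return Parsed configuration list.
#' @export
read_design_config <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

#' Write a design configuration file
#'
#' @param config Configuration list as returned by [read_design_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

packaged_config <- function(name) {
  if (!exists(name, envir = design_config_env)) {
    path <- system.file("extdata", name, package = "localaws")
    if (!nzchar(path)) path <- file.path("inst", "extdata", name)
    assign(name, read_design_config(path), envir = design_config_env)
  }
  get(name, envir = design_config_env)
}

config_space <- function(config) {
  kind <- if (!is.null(config$kind)) unlist(config$kind)
  feature_space(config$features, kind = kind)
}

experiment_design <- function(condition, space, learning, tasks, transfer_order) {
  structure(list(condition = condition, space = space, learning = learning,
                 tasks = tasks, transfer_order = transfer_order),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("Design %s (%s): %d learning event(s), %d generalization task(s)\n",
              x$condition, x$transfer_order, length(x$learning), length(x$tasks)))
  invisible(x)
}

# "third" value: the value of a feature used by neither learning stone.
third_value <- function(space, f, agent, recipient) {
  v <- setdiff(space$values[[f]], c(agent[[f]], recipient[[f]]))
  if (length(v) != 1L)
    stop("no unique unused value for feature ", f)
  v
}

#' The Experiment 1 one-shot design
#'
#' One learning event (condition A1-A6) followed by 15 generalization tasks
#' built from the shipped task grid: tasks vary recipient features first,
#' then each agent feature crossed with the recipient variants, then both
#' agent features. Near-first transfer presents tasks 1 to 15 (most to least
#' similar to the learning example); far-first presents the exact reverse.
#' The seed counterbalances whether color or shape variants come first in
#' the later task pairs; the printed anchor (A1: red-square agent and
#' blue-circle recipient on task 1) is fixed for every seed.
#'
#' Conditions: A1 recipient takes the agent's shape; A2 a brand-new shape;
#' A3 takes the agent's color; A4 a brand-new color; A5 the agent's color
#' and shape; A6 a new color and shape.
#'
#' @param condition `"A1"` to `"A6"`.
#' @param transfer_order `"near_first"` or `"far_first"`.
#' @param feature_order_seed Integer seed for the color/shape
#'   counterbalancing.
#' @return An `experiment_design`.
#' @export
exp1_design <- function(condition, transfer_order = c("near_first", "far_first"),
                        feature_order_seed = 1L) {
  transfer_order <- match.arg(transfer_order)
  config <- packaged_config("exp1_design.json")
  if (!(condition %in% names(config$conditions)))
    stop("unknown condition: ", condition, " (expected ",
         paste(names(config$conditions), collapse = ", "), ")")
  space <- config_space(config)
  agent <- as_stone(unlist(config$learning_agent))
  recipient <- as_stone(unlist(config$learning_recipient))

  spec_ <- config$conditions[[condition]]
  result <- vapply(space$features, function(f) {
    switch(spec_[[f]],
           agent = agent[[f]],
           recipient = recipient[[f]],
           new = third_value(space, f, agent, recipient),
           stop("unknown effect spec: ", spec_[[f]]))
  }, character(1))
  learning <- causal_event(agent, recipient, as_stone(result))

  withr_seed <- function(code) {  # local RNG scope
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(feature_order_seed)
    code
  }
  flip <- withr_seed(stats::runif(1) < 0.5)

  varied <- function(st, vary) {   # vary = c(slot1, slot2) flags
    out <- unclass(st)
    for (j in 1:2) {
      f <- if (j == 1L) "color" else "shape"
      if (vary[[j]] == 1L) out[[f]] <- third_value(space, f, agent, recipient)
    }
    as_stone(out)
  }
  tasks <- vector("list", length(config$task_grid))
  for (i in seq_along(config$task_grid)) {
    cell <- config$task_grid[[i]]
    av <- unlist(cell$agent); rv <- unlist(cell$recipient)
    if (flip && i > 3L) { av <- rev(av); rv <- rev(rv) } # swap which feature slot 1 means
    tasks[[i]] <- generalization_task(varied(agent, av), varied(recipient, rv),
                                      space = space)
  }
  if (transfer_order == "far_first") tasks <- rev(tasks)
  experiment_design(condition, space, list(learning), tasks, transfer_order)
}

#' Apply a deterministic causal law to a pair of stones
#'
#' @param law A `causal_law` whose outcome domain for this pair is a single
#'   stone.
#' @param agent,recipient Stones.
#' @param space The `feature_space`.
#' @return The result stone.
#' @export
apply_law <- function(law, agent, recipient, space) {
  dom <- outcome_domain(law, agent, recipient, space)
  if (dom$size != 1L)
    stop("law is not deterministic for this pair (domain size ", dom$size, ")")
  as_stone(stats::setNames(as.character(dom$stones[1, ]), names(dom$stones)))
}

# Deterministic cycling pickers for novel/observed instance values.
make_cycler <- function(values, offset = 0L) {
  i <- offset %% length(values)
  function() {
    i <<- i %% length(values) + 1L
    values[[i]]
  }
}

#' The Experiment 2 few-shot design
#'
#' Six learning events consistent with the condition's ground-truth rule
#' (Rule 1 for B1/B2: the recipient gets one increment darker and takes the
#' agent's edge count plus one; Rule 2 for B3/B4 swaps the roles of shade
#' and edge), with the agent fixed in B1/B3 and the recipient fixed in
#' B2/B4. The 16 generalization tasks cross match/novel shade and edge
#' values for the fixed-role and varied-role objects per the shipped grid;
#' two catch trials re-present seed-chosen learning events with the result
#' hidden. The full 18-trial sequence is presented in seed-controlled random
#' order, and the response panel is the full 5-edge-by-4-shade menu
#' (20 options).
#'
#' @param condition `"B1"` to `"B4"`.
#' @param seed Integer seed controlling catch-trial selection, novel/observed
#'   instance cycling, and task order.
#' @return An `experiment_design` (tasks carry `is_catch` flags).
#' @export
exp2_design <- function(condition, seed = 1L) {
  config <- packaged_config("exp2_design.json")
  if (!(condition %in% names(config$conditions)))
    stop("unknown condition: ", condition, " (expected ",
         paste(names(config$conditions), collapse = ", "), ")")
  space <- config_space(config)
  cond <- config$conditions[[condition]]
  rule <- parse_law(config$rules[[cond$rule]])

  fixed <- as_stone(unlist(cond$fixed))
  varied_objs <- lapply(cond$varied, function(v) as_stone(unlist(v)))

  learning <- lapply(varied_objs, function(v) {
    agent <- if (cond$fixed_role == "agent") fixed else v
    recipient <- if (cond$fixed_role == "agent") v else fixed
    dom <- outcome_domain(rule, agent, recipient, space)
    if (dom$size != 1L)
      stop("rule application leaves the observed value range for a learning pair")
    causal_event(agent, recipient, apply_law(rule, agent, recipient, space))
  })

  # observed / novel values per feature, over every object shown in learning
  seen <- list()
  for (f in space$features) {
    vals <- unlist(lapply(learning, function(ev)
      c(ev$agent[[f]], ev$recipient[[f]], ev$result[[f]])))
    seen[[f]] <- intersect(space$values[[f]], unique(vals))
  }
  novel <- lapply(space$features, function(f) setdiff(space$values[[f]], seen[[f]]))
  names(novel) <- space$features
  if (any(vapply(novel, length, integer(1)) == 0L))
    stop("learning set leaves no novel value for some feature")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  offsets <- sample.int(10L, 4L)
  pick_obs <- list(); pick_nov <- list()
  for (f in space$features) {
    pick_obs[[f]] <- make_cycler(seen[[f]], offsets[[match(f, space$features)]])
    pick_nov[[f]] <- make_cycler(novel[[f]], offsets[[2L + match(f, space$features)]])
  }

  variant <- function(base, flags, use_base_on_match) {
    out <- character(0)
    for (j in seq_along(space$features)) {
      f <- space$features[[j]]
      out[[f]] <- if (flags[[j]] == 1L) pick_nov[[f]]()
                  else if (use_base_on_match) base[[f]] else pick_obs[[f]]()
    }
    as_stone(out)
  }

  tasks <- vector("list", length(config$task_grid))
  for (i in seq_along(config$task_grid)) {
    cell <- config$task_grid[[i]]
    fx <- variant(fixed, unlist(cell$fixed), use_base_on_match = TRUE)
    vr <- variant(NULL, unlist(cell$varied), use_base_on_match = FALSE)
    agent <- if (cond$fixed_role == "agent") fx else vr
    recipient <- if (cond$fixed_role == "agent") vr else fx
    tasks[[i]] <- generalization_task(agent, recipient, space = space)
  }

  catch_idx <- sort(sample.int(length(learning), 2L))
  for (ci in catch_idx) {
    ev <- learning[[ci]]
    tasks[[length(tasks) + 1L]] <- generalization_task(ev$agent, ev$recipient,
                                                       space = space,
                                                       is_catch = TRUE)
  }
  tasks <- tasks[sample.int(length(tasks))]
  experiment_design(condition, space, learning, tasks, "randomized")
}

#' Dissimilarity score of a generalization task
#'
#' Counts the feature values of the trial's agent and recipient that never
#' appeared on any object (agent, recipient or result) during learning:
#' `DS = |F_i \ F_L|` over feature-tagged values. Catch trials, being copies
#' of learning events, score 0.
#'
#' @param task A `generalization_task`.
#' @param learning Non-empty list of `causal_event`s.
#' @return List of class `dissimilarity_score` with `DS`, `F_i`, `F_L`.
#' @export
dissimilarity <- function(task, learning) {
  if (length(learning) == 0L) stop("learning set must be non-empty")
  tag <- function(st) paste(names(unclass(st)), unclass(st), sep = ":")
  f_l <- unique(unlist(lapply(learning, function(ev)
    c(tag(ev$agent), tag(ev$recipient), if (!is.null(ev$result)) tag(ev$result)))))
  f_i <- unique(c(tag(task$agent), tag(task$recipient)))
  structure(list(DS = length(setdiff(f_i, f_l)), F_i = f_i, F_L = f_l),
            class = "dissimilarity_score")
}

#' @export
print.dissimilarity_score <- function(x, ...) {
  cat("DS =", x$DS, " (novel:", paste(setdiff(x$F_i, x$F_L), collapse = ", "), ")\n")
  invisible(x)
}
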