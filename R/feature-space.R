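#' Define a feature space for stones
#'
#' A feature space declares the observable object features, the admissible
#' values of each, and whether a feature is categorical or ordinal. Ordinal
#' features are totally ordered by the listed value order, which is what the
#' increment (`+1`/`-1`) and inequality relations of the law grammar act on.
#'
#' @param values Named list; one entry per feature giving its admissible
#'   values (coerced to character). At least one feature, at least two values
#'   per feature, no duplicates.
#' @param kind Named character vector mapping features to `"categorical"` or
#'   `"ordinal"`. Unnamed features default to `"categorical"`.
#' @return An object of class `feature_space`.
#' @examples
#' feature_space(list(color = c("red", "yellow", "blue"),
#'                    shape = c("circle", "square", "diamond")))
#' @export
feature_space <- function(values, kind = NULL) {
  if (!is.list(values) || length(values) < 1)
    stop("'values' must be a non-empty named list")
  feats <- names(values)
  if (is.null(feats) || any(!nzchar(feats)) || anyDuplicated(feats))
    stop("features must have unique non-empty names")
  values <- lapply(values, as.character)
  for (f in feats) {
    v <- values[[f]]
    if (length(v) < 2)
      stop(sprintf("feature '%s' must have at least 2 values", f))
    if (anyDuplicated(v))
      stop(sprintf("feature '%s' has duplicate values", f))
  }
  k <- stats::setNames(rep("categorical", length(feats)), feats)
  if (!is.null(kind)) {
    if (is.null(names(kind))) names(kind) <- feats[seq_along(kind)]
    bad <- setdiff(names(kind), feats)
    if (length(bad)) stop("unknown features in 'kind': ", paste(bad, collapse = ", "))
    if (!all(kind %in% c("categorical", "ordinal")))
      stop("'kind' entries must be 'categorical' or 'ordinal'")
    k[names(kind)] <- kind
  }
  structure(list(features = feats, values = values, kind = k),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat("Feature space with", length(x$features), "features:\n")
  for (f in x$features)
    cat(sprintf("  %s (%s): %s\n", f, x$kind[[f]],
                paste(x$values[[f]], collapse = ", ")))
  cat(" ", n_configs(x), "object configurations\n")
  invisible(x)
}

#' Number of per-object configurations in a feature space
#'
#' @param space A `feature_space`.
#' @return Integer count of distinct objects, i.e. the product of the
#'   per-feature value counts.
#' @export
n_configs <- function(space) {
  stopifnot(inherits(space, "feature_space"))
  as.integer(prod(vapply(space$values, length, integer(1))))
}

#' Enumerate all object configurations of a feature space
#'
#' Configurations are listed in a fixed canonical order (first feature most
#' significant), which defines the canonical outcome index used for choice
#' panels and deterministic tie-breaking.
#'
#' @param space A `feature_space`.
#' @return A data.frame with one column per feature and one row per
#'   configuration.
#' @export
space_configs <- function(space) {
  stopifnot(inherits(space, "feature_space"))
  grids <- rev(space$values)
  df <- expand.grid(grids, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  df[, rev(names(df)), drop = FALSE]
}

#' Construct a stone (an object as a feature-value map)
#'
#' @param ... Named feature values, e.g. `stone(color = "red", shape = "square")`.
#' @return Named character vector of class `stone`.
#' @export
stone <- function(...) {
  v <- c(...)
  v <- stats::setNames(as.character(v), names(v))
  structure(v, class = "stone")
}

as_stone <- function(x) {
  structure(stats::setNames(as.character(x), names(x)), class = "stone")
}

#' @export
print.stone <- function(x, ...) {
  cat("<stone>", paste(sprintf("%s=%s", names(x), unclass(x)), collapse = " "), "\n")
  invisible(x)
}

#' @export
format.stone <- function(x, ...) paste(unclass(x)[order(names(x))], collapse = "-")

validate_stone <- function(space, x, what = "stone") {
  if (is.null(names(x)) || !setequal(names(x), space$features))
    stop(sprintf("%s must assign exactly the features: %s", what,
                 paste(space$features, collapse = ", ")))
  for (f in space$features) {
    if (!(x[[f]] %in% space$values[[f]]))
      stop(sprintf("%s: value '%s' is not admissible for feature '%s' (admissible: %s)",
                   what, x[[f]], f, paste(space$values[[f]], collapse = ", ")))
  }
  invisible(TRUE)
}

# Value index (position in the declared value order) per feature.
value_index <- function(space, x) {
  vapply(space$features, function(f) match(x[[f]], space$values[[f]]), integer(1))
}

#' Canonical configuration index of a stone
#'
#' @param space A `feature_space`.
#' @param x A stone (named vector of feature values).
#' @return Integer index into [space_configs()].
#' @export
config_index <- function(space, x) {
  idx <- value_index(space, x)
  if (anyNA(idx)) stop("stone has values outside the feature space")
  sizes <- vapply(space$values, length, integer(1))
  radix <- rev(cumprod(rev(c(sizes[-1], 1))))
  as.integer(sum((idx - 1) * radix) + 1L)
}

index_config <- function(space, i) {
  cfg <- space_configs(space)
  as_stone(stats::setNames(as.character(cfg[i, ]), names(cfg)))
}

#' Construct a causal event
#'
#' An event records one causal interaction: an agent stone acts on a
#' recipient stone, turning it into a result stone. The result may be
#' unknown (`NULL`), as in a generalization trial.
#'
#' @param agent,recipient Stones.
#' @param result Stone or `NULL` for an unobserved result.
#' @return Object of class `causal_event`.
#' @export
causal_event <- function(agent, recipient, result = NULL) {
  structure(list(agent = as_stone(agent), recipient = as_stone(recipient),
                 result = if (!is.null(result)) as_stone(result)),
            class = "causal_event")
}

#' @export
print.causal_event <- function(x, ...) {
  cat(sprintf("<event> agent %s -> recipient %s => %s\n",
              format(x$agent), format(x$recipient),
              if (is.null(x$result)) "?" else format(x$result)))
  invisible(x)
}

validate_event <- function(space, ev) {
  validate_stone(space, ev$agent, "agent")
  validate_stone(space, ev$recipient, "recipient")
  if (!is.null(ev$result)) validate_stone(space, ev$result, "result")
  invisible(TRUE)
}

#' Construct a generalization task
#'
#' @param agent,recipient Stones shown in the trial.
#' @param panel Data.frame of candidate outcome stones (one row each);
#'   defaults to the full configuration space when `space` is given.
#' @param space Optional `feature_space` used to build the default panel.
#' @param is_catch Logical; catch trials re-present a learning event with the
#'   result hidden.
#' @return Object of class `generalization_task`.
#' @export
generalization_task <- function(agent, recipient, panel = NULL, space = NULL,
                                is_catch = FALSE) {
  if (is.null(panel)) {
    if (is.null(space)) stop("either 'panel' or 'space' must be supplied")
    panel <- space_configs(space)
  }
  if (nrow(panel) < 1) stop("candidate panel must be non-empty")
  if (anyDuplicated(panel)) stop("candidate panel contains duplicates")
  structure(list(agent = as_stone(agent), recipient = as_stone(recipient),
                 panel = panel, is_catch = isTRUE(is_catch)),
            class = "generalization_task")
}

#' @export
print.generalization_task <- function(x, ...) {
  cat(sprintf("<task%s> agent %s, recipient %s, %d candidate outcomes\n",
              if (x$is_catch) " (catch)" else "", format(x$agent),
              format(x$recipient), nrow(x$panel)))
  invisible(x)
}

#' The Experiment 1 feature space
#'
#' Two categorical features: color (red, yellow, blue) and shape
#' (circle, square, diamond); 9 object configurations.
#' @return A `feature_space`.
#' @export
exp1_space <- function() {
  feature_space(list(color = c("red", "yellow", "blue"),
                     shape = c("circle", "square", "diamond")))
}

#' The Experiment 2 feature space
#'
#' Two ordinal features: shade of blue (1-4, light to very dark) and edge
#' count (3-7, triangle to heptagon); 20 object configurations, matching the
#' two response drop-down menus.
#'
#' @param observed_only If `TRUE`, restrict edges to 3-6, giving the 4 x 4
#'   observed-value object space (16 configurations).
#' @return A `feature_space`.
#' @export
exp2_space <- function(observed_only = FALSE) {
  edges <- if (observed_only) 3:6 else 3:7
  feature_space(list(shade = as.character(1:4), edge = as.character(edges)),
                kind = c(shade = "ordinal", edge = "ordinal"))
}
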