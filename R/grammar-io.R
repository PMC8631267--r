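# Grammar configuration files: a YAML (or JSON) mirror of the production
# table - feature supports, feature kinds, and the relation set per kind.

#' Read a grammar configuration file
#'
#' The config carries `features` (name -> value list), optional `kind`
#' (name -> categorical/ordinal) and `relations` (kind -> relation list).
#' YAML and JSON are both accepted.
#'
#' @param path Config path.
#' @return A `causal_grammar`.
#' @export
read_grammar_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML grammar configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  space <- feature_space(lapply(cfg$features, as.character),
                         kind = if (!is.null(cfg$kind)) unlist(cfg$kind))
  rel <- lapply(cfg$relations, unlist)
  causal_grammar(space, relations = rel)
}

#' Write a grammar configuration file
#'
#' @param grammar A `causal_grammar`.
#' @param path Output path (`.yaml`/`.yml` for YAML, anything else JSON).
#' @return `path`, invisibly.
#' @export
write_grammar_config <- function(grammar, path) {
  cfg <- list(features = grammar$space$values,
              kind = as.list(grammar$space$kind),
              relations = grammar$relations)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("writing YAML grammar configs requires the 'yaml' package")
    yaml::write_yaml(cfg, path)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Write a law table (or posterior) as a CSV dump
#'
#' @param x A `law_table` or `law_posterior`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_law_csv <- function(x, path) {
  df <- if (inherits(x, "law_posterior")) as.data.frame(x)
  else data.frame(law = x$strings, prior = x$prior, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
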