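#' Construct a single feature assertion
#'
#' An assertion constrains one feature of the result stone. The reference is
#' the same feature read off the agent, the recipient, or a constant value
#' (the lambda binding of the grammar ties reference and target to one
#' feature). Operators: `assign` (copy the reference value), `nassign`
#' (any admissible value except the reference), `plus1`/`minus1` (one step
#' along the ordinal value order), `gt`/`lt` (strictly greater/less than the
#' reference in ordinal order).
#'
#' @param feature Target feature of the result.
#' @param relation One of `"assign"`, `"nassign"`, `"plus1"`, `"minus1"`,
#'   `"gt"`, `"lt"`.
#' @param ref `"agent"`, `"recipient"`, or `"constant"`.
#' @param value Constant value (required when `ref = "constant"`).
#' @return A list of class `assertion`.
#' @export
assertion <- function(feature, relation, ref, value = NULL) {
  relation <- match.arg(relation, c("assign", "nassign", "plus1", "minus1", "gt", "lt"))
  ref <- match.arg(ref, c("agent", "recipient", "constant"))
  if (ref == "constant" && is.null(value))
    stop("constant reference requires a 'value'")
  if (ref != "constant") value <- NULL
  structure(list(feature = feature, relation = relation, ref = ref,
                 value = if (!is.null(value)) as.character(value)),
            class = "assertion")
}

#' Construct a causal law
#'
#' A causal law is a conjunction of assertions, each binding a distinct
#' feature of the result stone. Features not mentioned by the law keep the
#' recipient's value.
#'
#' @param ... `assertion` objects (or a single list of them).
#' @return A list of class `causal_law` with assertions sorted into a
#'   canonical (alphabetical-by-feature) order.
#' @export
causal_law <- function(...) {
  as_ <- list(...)
  if (length(as_) == 1L && !inherits(as_[[1]], "assertion")) as_ <- as_[[1]]
  if (!all(vapply(as_, inherits, logical(1), "assertion")))
    stop("all arguments must be assertions")
  feats <- vapply(as_, function(a) a$feature, character(1))
  if (anyDuplicated(feats))
    stop("a causal law binds each feature at most once")
  structure(list(assertions = as_[order(feats)]), class = "causal_law")
}

#' Number of conjoined assertions in a causal law
#' @param law A `causal_law`.
#' @return Integer.
#' @export
n_assertions <- function(law) length(law$assertions)

assertion_to_string <- function(a) {
  target <- sprintf("(%s R')", a$feature)
  refstr <- switch(a$ref,
                   agent = sprintf("(%s A)", a$feature),
                   recipient = sprintf("(%s R)", a$feature),
                   constant = a$value)
  sprintf("(%s %s %s)", a$relation, target, refstr)
}

#' Serialize a causal law to its canonical S-expression string
#'
#' @param law A `causal_law`.
#' @return A character scalar, e.g.
#'   `"(and (assign (color R') (color A)) (assign (shape R') square))"`.
#' @export
law_to_string <- function(law) {
  parts <- vapply(law$assertions, assertion_to_string, character(1))
  if (length(parts) == 1L) parts else sprintf("(and %s)", paste(parts, collapse = " "))
}

#' @export
print.causal_law <- function(x, ...) {
  cat("<causal law>", law_to_string(x), "\n")
  invisible(x)
}

#' @export
format.causal_law <- function(x, ...) law_to_string(x)

tokenize_sexpr <- function(s) {
  s <- gsub("([()])", " \\1 ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

parse_sexpr <- function(toks) {
  # returns list(node, rest)
  if (length(toks) == 0L) stop("unexpected end of law string")
  t1 <- toks[[1]]
  if (t1 == "(") {
    toks <- toks[-1]
    items <- list()
    while (length(toks) && toks[[1]] != ")") {
      res <- parse_sexpr(toks)
      items[[length(items) + 1L]] <- res$node
      toks <- res$rest
    }
    if (!length(toks)) stop("unbalanced parentheses in law string")
    list(node = items, rest = toks[-1])
  } else {
    list(node = t1, rest = toks[-1])
  }
}

sexpr_to_assertion <- function(node) {
  if (!is.list(node) || length(node) != 3L)
    stop("malformed assertion in law string")
  relation <- node[[1]]
  target <- node[[2]]
  if (!is.list(target) || length(target) != 2L || target[[2]] != "R'")
    stop("assertion target must be a result-feature reference like (color R')")
  feature <- target[[1]]
  refnode <- node[[3]]
  if (is.list(refnode)) {
    if (length(refnode) != 2L || refnode[[1]] != feature)
      stop("reference feature must match the target feature")
    role <- switch(refnode[[2]], "A" = "agent", "R" = "recipient",
                   stop("reference role must be A or R"))
    assertion(feature, relation, role)
  } else {
    assertion(feature, relation, "constant", refnode)
  }
}

#' Parse a causal law from its S-expression string
#'
#' Inverse of [law_to_string()]: `parse_law(law_to_string(x))` has identical
#' semantics and prior.
#'
#' @param s Law string.
#' @return A `causal_law`.
#' @export
parse_law <- function(s) {
  res <- parse_sexpr(tokenize_sexpr(s))
  if (length(res$rest)) stop("trailing content in law string")
  node <- res$node
  if (is.list(node) && length(node) && identical(node[[1]], "and")) {
    causal_law(lapply(node[-1], sexpr_to_assertion))
  } else {
    causal_law(sexpr_to_assertion(node))
  }
}
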