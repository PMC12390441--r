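# Gene-protein-reaction (GPR) boolean rules: parsing and evaluation.
#
# Grammar (case-insensitive keywords):
#   expr   := term ("or" term)*
#   term   := factor ("and" factor)*
#   factor := gene_id | "(" expr ")"
#
# Evaluation against expression values follows the enzymatic-capacity
# convention: AND (enzyme complex) takes the minimum of its operands, OR
# (isozymes) the sum.

gpr_tokenize <- function(gpr) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, gpr)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(gpr, gregexpr(pat, gpr))[[1]]
}

#' Parse a GPR rule into a nested boolean structure
#'
#' @param gpr GPR rule string such as `"(g1 and g2) or g3"`; `""` or `NA`
#'   yields `NULL` (no gene association).
#' @param context Optional reaction id used in error messages.
#' @return `NULL`, a gene id string (leaf), or a list
#'   `list(op = "and"|"or", args = list(...))`.
#' @export
parse_gpr <- function(gpr, context = NULL) {
  if (is.null(gpr) || is.na(gpr) || !nzchar(trimws(gpr))) return(NULL)
  tokens <- gpr_tokenize(gpr)
  pos <- 1L
  fail <- function(msg) {
    where <- if (is.null(context)) "" else paste0(" in reaction ", context)
    rlang::abort(paste0("malformed GPR", where, ": ", msg, " [", gpr, "]"))
  }
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() {
    tok <- peek()
    pos <<- pos + 1L
    tok
  }
  is_kw <- function(tok, kw) !is.na(tok) && tolower(tok) == kw

  parse_expr <- function() {
    args <- list(parse_term())
    while (is_kw(peek(), "or")) {
      advance()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_kw(peek(), "and")) {
      advance()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    tok <- advance()
    if (is.na(tok)) fail("unexpected end of rule")
    if (tok == "(") {
      inner <- parse_expr()
      if (!identical(advance(), ")")) fail("missing closing parenthesis")
      return(inner)
    }
    if (tok == ")" || is_kw(tok, "and") || is_kw(tok, "or")) {
      fail(paste0("unexpected token '", tok, "'"))
    }
    tok
  }

  out <- parse_expr()
  if (pos <= length(tokens)) fail(paste0("trailing token '", peek(), "'"))
  out
}

#' List the genes referenced by a GPR rule
#'
#' @param gpr GPR rule string.
#' @return Character vector of unique gene ids (empty if no rule).
#' @export
gpr_genes <- function(gpr) {
  node <- tryCatch(parse_gpr(gpr), error = function(e) NULL)
  collect <- function(n) {
    if (is.null(n)) return(character(0))
    if (is.character(n)) return(n)
    unlist(lapply(n$args, collect))
  }
  unique(collect(node))
}

#' Evaluate a GPR rule against gene expression values
#'
#' AND combines operands with `min` (complex limited by its scarcest
#' subunit); OR combines with `sum` (isozyme capacities add). A gene absent
#' from `values` contributes 0 to an OR and is ignored inside an AND unless
#' every operand is missing, in which case the whole (sub)rule is missing.
#'
#' @param gpr GPR rule string (or pre-parsed structure from [parse_gpr()]).
#' @param values Named numeric vector of gene expression on the linear scale.
#' @param context Optional reaction id for error messages.
#' @return Numeric value, or `NA` when the rule is empty or no referenced
#'   gene is measured.
#' @export
eval_gpr <- function(gpr, values, context = NULL) {
  node <- if (is.character(gpr) && length(gpr) == 1L && !is.list(gpr)) {
    parse_gpr(gpr, context = context)
  } else {
    gpr
  }
  if (is.null(node)) return(NA_real_)
  ev <- function(n) {
    if (is.character(n)) {
      if (!n %in% names(values)) return(NA_real_)
      return(unname(values[[n]]))
    }
    vals <- vapply(n$args, ev, numeric(1))
    if (n$op == "or") {
      if (all(is.na(vals))) return(NA_real_)
      return(sum(vals, na.rm = TRUE))  # missing isozyme contributes 0
    }
    if (all(is.na(vals))) return(NA_real_)
    min(vals, na.rm = TRUE)            # missing complex member ignored
  }
  ev(node)
}

# Render a parsed GPR structure back to a rule string (canonical spacing).
deparse_gpr <- function(node) {
  if (is.null(node)) return("")
  if (is.character(node)) return(node)
  parts <- vapply(node$args, function(a) {
    s <- deparse_gpr(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", node$op, " "))
}
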