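#' Parse a gene-protein-reaction rule string
#'
#' GPR rules are Boolean expressions over gene identifiers with `and` / `or`
#' connectives (case-insensitive; `&` and `|` accepted) and parentheses.
#' `and` binds tighter than `or`. Isoenzymes are expressed with `or`,
#' enzyme complexes with `and`.
#'
#' @param x a single rule string; `""` or `NA` yield `NULL` (empty rule).
#' @return an expression tree: a gene id (character scalar) at the leaves,
#'   internal nodes are `list(op = "and"|"or", args = list(...))`; `NULL`
#'   for the empty rule.
#' @examples
#' parseGPR("(g1 and g2) or g3")
#' @export
parseGPR <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x) || !nzchar(trimws(x))) {
    return(NULL)
  }
  x <- gsub("&&|&", " and ", x)
  x <- gsub("\\|\\||\\|", " or ", x)
  toks <- regmatches(x, gregexpr("\\(|\\)|[^()\\s]+", x, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- toks[pos]; pos <<- pos + 1L; t
  }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR parse error: unexpected end of rule in '", x, "'")
    if (t == "(") {
      advance()
      node <- parse_or()
      if (!identical(peek(), ")")) {
        stop("GPR parse error: missing ')' in '", x, "'")
      }
      advance()
      return(node)
    }
    if (t == ")" || is_kw(t, "and") || is_kw(t, "or")) {
      stop("GPR parse error: unexpected '", t, "' in '", x, "'")
    }
    advance()
  }
  parse_and <- function() {
    args <- list(parse_factor())
    while (is_kw(peek(), "and")) {
      advance()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (is_kw(peek(), "or")) {
      advance()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  tree <- parse_or()
  if (pos <= length(toks)) {
    stop("GPR parse error: trailing tokens in '", x, "'")
  }
  tree
}

#' Genes referenced by a GPR expression tree
#'
#' @param gpr a tree from [parseGPR()].
#' @return character vector of gene ids (empty for `NULL`).
#' @export
gprGenes <- function(gpr) {
  if (is.null(gpr)) return(character())
  if (is.character(gpr)) return(gpr)
  unique(unlist(lapply(gpr$args, gprGenes)))
}

#' Evaluate a GPR rule over trinary gene expression classes
#'
#' Propagates gene expression classes (low = -1, moderate = 0, high = +1)
#' through a GPR rule: `and` nodes (complexes) take the minimum of their
#' children, `or` nodes (isoenzymes) the maximum. Genes absent from
#' `geneValues` count as moderate (0), so they never push a reaction into
#' the highly or lowly expressed set on their own. The empty rule returns 0.
#'
#' @param gpr expression tree from [parseGPR()].
#' @param geneValues named numeric/integer vector with values in
#'   `c(-1, 0, 1)`.
#' @return a value in `c(-1, 0, 1)`.
#' @examples
#' evaluateGPR(parseGPR("g1 and g2"), c(g1 = 1, g2 = -1))  # -1
#' @export
evaluateGPR <- function(gpr, geneValues) {
  if (is.null(gpr)) return(0L)
  if (is.character(gpr)) {
    v <- geneValues[gpr]
    if (is.na(v)) 0L else as.integer(v)
  } else {
    vals <- vapply(gpr$args, evaluateGPR, integer(1), geneValues = geneValues)
    if (gpr$op == "and") min(vals) else max(vals)
  }
}

#' Render a GPR expression tree back to a rule string
#'
#' @param gpr expression tree from [parseGPR()].
#' @return a rule string, `""` for the empty rule.
#' @export
deparseGPR <- function(gpr) {
  if (is.null(gpr)) return("")
  if (is.character(gpr)) return(gpr)
  parts <- vapply(gpr$args, function(a) {
    s <- deparseGPR(a)
    if (!is.character(a) && a$op != gpr$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", gpr$op, " "))
}
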