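## Gene-protein-reaction association strings: boolean AND/OR trees over
## gene identifiers, e.g. "OsRBCS AND OsRBCL", "g1 AND (g2 OR g3)".
## AND binds tighter than OR; parentheses group.

gpr_tokens <- function(gpr) {
  gpr <- gsub("([()])", " \\1 ", gpr)
  toks <- strsplit(trimws(gpr), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a gene association string
#'
#' @param gpr Association string; `AND` binds tighter than `OR`,
#'   parentheses group. Case-insensitive keywords.
#' @return A nested list tree (`list(op = "AND"/"OR", args = ...)` or a
#'   gene id character), or `NULL` for an empty string.
#' @export
parse_gpr <- function(gpr) {
  if (is.null(gpr) || !nzchar(trimws(gpr))) return(NULL)
  toks <- gpr_tokens(gpr)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  perr <- function(...) stop("malformed gpr '", gpr, "': ", ...)

  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && toupper(peek()) == "OR") {
      take()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "OR", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && toupper(peek()) == "AND") {
      take()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "AND", args = args)
  }
  parse_atom <- function() {
    t <- take()
    if (is.na(t)) perr("unexpected end of expression")
    if (t == "(") {
      e <- parse_or()
      if (!identical(take(), ")")) perr("missing closing parenthesis")
      return(e)
    }
    if (t %in% c(")", "AND", "OR", "and", "or")) perr("unexpected token '", t, "'")
    t
  }
  tree <- parse_or()
  if (!is.na(peek())) perr("trailing tokens from '", peek(), "'")
  tree
}

#' Genes referenced by a gene association string
#' @param gpr Association string.
#' @return Character vector of gene ids (order of first mention).
#' @export
gpr_genes <- function(gpr) {
  tree <- parse_gpr(gpr)
  walk <- function(nd) {
    if (is.character(nd)) return(nd)
    unlist(lapply(nd$args, walk), use.names = FALSE)
  }
  if (is.null(tree)) character(0) else unique(walk(tree))
}

#' Evaluate a gene association with a set of knocked-out genes
#'
#' @param gpr Association string (or pre-parsed tree).
#' @param knocked Character vector of deleted gene ids (evaluated FALSE;
#'   all other genes TRUE).
#' @return Logical; `NA` for an empty association (no gene data).
#' @export
eval_gpr <- function(gpr, knocked = character(0)) {
  tree <- if (is.character(gpr) && length(gpr) == 1L) parse_gpr(gpr) else gpr
  if (is.null(tree)) return(NA)
  ev <- function(nd) {
    if (is.character(nd)) return(!(nd %in% knocked))
    vals <- vapply(nd$args, ev, NA)
    if (nd$op == "AND") all(vals) else any(vals)
  }
  ev(tree)
}
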