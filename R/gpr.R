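# Gene-protein-reaction (GPR) rule parsing.
#
# GPR rules are boolean expressions over gene/protein identifiers in which
# "or" separates isozymes (alternative catalysts) and "and" joins subunits
# of an enzyme complex. The parser produces a nested expression tree; for
# model construction the tree is normalised to a list of isozyme
# alternatives, each a character vector of complex subunits (disjunctive
# normal form).

#' Parse a GPR rule into an expression tree
#'
#' Accepts identifiers, parentheses and the (case-insensitive) operators
#' `and` / `or` (also `&` / `|`). Returns `NULL` for an empty rule.
#'
#' @param rule a single GPR string, e.g. `"(g1 and g2) or g3"`.
#' @return `NULL`, or a tree: either `list(op = "gene", gene = <id>)` or
#'   `list(op = "and"|"or", args = <list of trees>)`.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokens(rule)
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$pos <- 1L
  tree <- gpr_parse_or(env)
  if (env$pos <= length(env$toks))
    stop("malformed GPR rule (trailing input): ", rule)
  tree
}

gpr_tokens <- function(rule) {
  rule <- gsub("&&?", " and ", rule)
  rule <- gsub("\\|\\|?", " or ", rule)
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(env) {
  if (env$pos > length(env$toks)) "" else env$toks[[env$pos]]
}

gpr_parse_or <- function(env) {
  args <- list(gpr_parse_and(env))
  while (tolower(gpr_peek(env)) == "or") {
    env$pos <- env$pos + 1L
    args <- c(args, list(gpr_parse_and(env)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(env) {
  args <- list(gpr_parse_atom(env))
  while (tolower(gpr_peek(env)) == "and") {
    env$pos <- env$pos + 1L
    args <- c(args, list(gpr_parse_atom(env)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(env) {
  tok <- gpr_peek(env)
  if (tok == "") stop("malformed GPR rule (unexpected end of input)")
  if (tok == "(") {
    env$pos <- env$pos + 1L
    sub <- gpr_parse_or(env)
    if (gpr_peek(env) != ")") stop("malformed GPR rule (missing ')')")
    env$pos <- env$pos + 1L
    return(sub)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or"))
    stop("malformed GPR rule (unexpected token '", tok, "')")
  env$pos <- env$pos + 1L
  list(op = "gene", gene = tok)
}

#' Expand a GPR tree into isozyme alternatives
#'
#' Normalises the boolean expression to disjunctive normal form: a list of
#' isozyme alternatives, each alternative the character vector of subunits
#' that must all be present (an enzyme complex; length one for a single
#' enzyme).
#'
#' @param tree a tree from [parse_gpr()], or `NULL`.
#' @return A list of character vectors; `list()` for `NULL` input.
#' @export
gpr_isozymes <- function(tree) {
  if (is.null(tree)) return(list())
  alts <- gpr_dnf(tree)
  alts <- lapply(alts, function(a) sort(unique(a)))
  unique(alts)
}

gpr_dnf <- function(tree) {
  switch(tree$op,
    gene = list(tree$gene),
    or = do.call(c, lapply(tree$args, gpr_dnf)),
    and = Reduce(function(acc, sub) {
      alts <- gpr_dnf(sub)
      do.call(c, lapply(acc, function(a) lapply(alts, function(b) c(a, b))))
    }, tree$args, accumulate = FALSE, init = list(character(0))),
    stop("unknown GPR node type: ", tree$op)
  )
}

#' All genes mentioned in a GPR tree
#' @param tree a tree from [parse_gpr()], or `NULL`.
#' @return character vector (possibly empty).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  sort(unique(unlist(gpr_dnf(tree))))
}

#' Render a GPR tree back to a rule string
#' @param tree a tree from [parse_gpr()], or `NULL`.
#' @return a single string (`""` for `NULL`).
#' @export
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  rec <- function(t, parent_op = "") {
    if (t$op == "gene") return(t$gene)
    sep <- paste0(" ", t$op, " ")
    s <- paste(vapply(t$args, rec, "", parent_op = t$op), collapse = sep)
    if (parent_op != "" && parent_op != t$op) paste0("(", s, ")") else s
  }
  rec(tree)
}
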