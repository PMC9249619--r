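#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are Boolean expressions over gene identifiers: `or` joins
#' isozymes (either suffices), `and` joins complex subunits (all required).
#' Parentheses group; `and`/`or` are matched case-insensitively. The empty
#' string denotes "no gene association".
#'
#' @param rule character scalar, e.g. `"(b1263 and b1264) or b0123"`.
#' @return A GPR tree: `NULL` for the empty rule, otherwise a nested list
#'   with elements `op` (`"gene"`, `"and"`, `"or"`), and either `gene`
#'   (leaf) or `args` (list of subtrees).
#' @export
gpr_parse <- function(rule) {
  if (is.null(rule) || length(rule) == 0 || is.na(rule)) return(NULL)
  rule <- trimws(rule)
  if (!nzchar(rule)) return(NULL)
  toks <- gpr_tokenize(rule)
  st <- gpr_parse_or(toks, 1L)
  if (st$pos <= length(toks)) {
    stop("GPR parse error: trailing tokens at '", toks[st$pos], "' in rule: ", rule)
  }
  st$node
}

gpr_tokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(rule, "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gpr_parse_or <- function(toks, pos) {
  st <- gpr_parse_and(toks, pos)
  args <- list(st$node)
  pos <- st$pos
  while (pos <= length(toks) && tolower(toks[pos]) == "or") {
    st <- gpr_parse_and(toks, pos + 1L)
    args <- c(args, list(st$node))
    pos <- st$pos
  }
  node <- if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  list(node = node, pos = pos)
}

gpr_parse_and <- function(toks, pos) {
  st <- gpr_parse_atom(toks, pos)
  args <- list(st$node)
  pos <- st$pos
  while (pos <= length(toks) && tolower(toks[pos]) == "and") {
    st <- gpr_parse_atom(toks, pos + 1L)
    args <- c(args, list(st$node))
    pos <- st$pos
  }
  node <- if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  list(node = node, pos = pos)
}

gpr_parse_atom <- function(toks, pos) {
  if (pos > length(toks)) stop("GPR parse error: unexpected end of rule")
  tok <- toks[pos]
  if (tok == "(") {
    st <- gpr_parse_or(toks, pos + 1L)
    if (st$pos > length(toks) || toks[st$pos] != ")") {
      stop("GPR parse error: unbalanced parenthesis")
    }
    st$pos <- st$pos + 1L
    return(st)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop("GPR parse error: unexpected token '", tok, "'")
  }
  list(node = list(op = "gene", gene = tok), pos = pos + 1L)
}

#' Genes referenced by a GPR tree
#' @param tree a tree from [gpr_parse()].
#' @return character vector of distinct gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (tree$op == "gene") return(tree$gene)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Evaluate a GPR tree under a gene truth assignment
#'
#' @param tree a tree from [gpr_parse()].
#' @param active named logical vector; genes absent from it default to
#'   `default`.
#' @param default truth value for unmentioned genes (`TRUE`: present).
#' @return logical: is the reaction catalytically available. The empty tree
#'   (no gene association) evaluates `TRUE`.
#' @export
gpr_eval <- function(tree, active, default = TRUE) {
  if (is.null(tree)) return(TRUE)
  switch(tree$op,
    gene = {
      v <- active[tree$gene]
      if (is.na(v)) default else unname(v)
    },
    and = all(vapply(tree$args, gpr_eval, logical(1), active = active, default = default)),
    or  = any(vapply(tree$args, gpr_eval, logical(1), active = active, default = default)),
    stop("bad GPR node")
  )
}

#' Deparse a GPR tree back to rule text
#' @param tree a tree from [gpr_parse()].
#' @return character scalar (empty string for `NULL`).
#' @export
gpr_deparse <- function(tree) {
  if (is.null(tree)) return("")
  rec <- function(nd, parent_op) {
    if (nd$op == "gene") return(nd$gene)
    sep <- paste0(" ", nd$op, " ")
    s <- paste(vapply(nd$args, rec, character(1), parent_op = nd$op), collapse = sep)
    if (!is.null(parent_op) && parent_op != nd$op) paste0("(", s, ")") else s
  }
  rec(tree, NULL)
}

# All minimal gene sets G such that knocking out exactly G (others active)
# flips the rule to FALSE.  Exhaustive over subsets by increasing size, so
# guarded to small rules -- intervention reactions have a handful of genes.
gpr_minimal_falsifying_sets <- function(tree, max_genes = 16L) {
  gpr_minimal_sets(tree, target = FALSE, max_genes = max_genes)
}

# All minimal gene sets G such that having exactly G active (others knocked
# out) keeps the rule TRUE: the minimal sufficient complements/isozymes.
gpr_minimal_satisfying_sets <- function(tree, max_genes = 16L) {
  gpr_minimal_sets(tree, target = TRUE, max_genes = max_genes)
}

gpr_minimal_sets <- function(tree, target, max_genes) {
  genes <- sort(gpr_genes(tree))
  if (length(genes) == 0L) stop("no gene association")
  if (length(genes) > max_genes) {
    stop("GPR has ", length(genes), " genes; minimal-set enumeration is guarded at ", max_genes)
  }
  found <- list()
  covered_by_found <- function(idx) {
    any(vapply(found, function(f) all(f %in% idx), logical(1)))
  }
  for (k in seq_len(length(genes))) {
    combs <- utils::combn(length(genes), k, simplify = FALSE)
    for (idx in combs) {
      if (covered_by_found(idx)) next
      if (target) {
        # exactly genes[idx] active
        act <- stats::setNames(seq_along(genes) %in% idx, genes)
      } else {
        # exactly genes[idx] knocked out
        act <- stats::setNames(!(seq_along(genes) %in% idx), genes)
      }
      if (gpr_eval(tree, act) == target) found <- c(found, list(idx))
    }
    # supersets of found sets are skipped via covered_by_found(); other
    # larger combinations may still be minimal, so keep scanning.
  }
  sets <- lapply(found, function(idx) genes[idx])
  # order by size, then lexicographically
  ord <- order(lengths(sets), vapply(sets, function(s) paste(s, collapse = ","), character(1)))
  sets[ord]
}
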