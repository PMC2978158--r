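#' Gene-protein-reaction (GPR) boolean rules
#'
#' A GPR rule states which gene combinations enable a reaction: `or` joins
#' isozymes (either suffices), `and` joins subunits of a complex (all are
#' required). Rules are parsed into a boolean tree whose leaves are gene ids;
#' an empty rule marks a non-gene-associated reaction, which is always
#' enabled.
#'
#' The grammar accepts gene ids (any token without whitespace or
#' parentheses), parentheses, and the case-insensitive connectives
#' `and` / `or`; `and` binds tighter than `or`. Internal trees are nested
#' lists: a leaf is `list(op = "gene", gene = <id>)`, an internal node is
#' `list(op = "and"|"or", args = <list of subtrees>)`, and the empty rule is
#' `NULL`.
#'
#' @param text a GPR rule string; `""`, `NA` and whitespace-only all denote
#'   the empty rule.
#' @return `parse_gpr()` returns a GPR tree (or `NULL`); `gpr_to_string()`
#'   its canonical serialization (fully parenthesized, lower-case
#'   connectives); `gpr_genes()` the sorted unique gene ids in the rule.
#' @examples
#' g <- parse_gpr("(g1 and g2) or g3")
#' gpr_to_string(g)
#' evaluate_gpr(g, present = "g3")
#' @export
parse_gpr <- function(text) {
  if (length(text) != 1L || is.na(text)) text <- ""
  text <- trimws(as.character(text))
  if (!nzchar(text)) return(NULL)
  toks <- gpr_tokenize(text)
  st <- list(pos = 1L, toks = toks$token, at = toks$at, text = text)
  res <- gpr_parse_or(st)
  st <- res$state
  if (st$pos <= length(st$toks)) {
    stop(sprintf("GPR parse error at position %d: unexpected token '%s' in \"%s\"",
                 st$at[st$pos], st$toks[st$pos], st$text), call. = FALSE)
  }
  res$node
}

# lexer: parentheses and whitespace-delimited tokens, with character offsets
gpr_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  token <- character(0)
  at <- integer(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch %in% c("(", ")")) {
      token <- c(token, ch)
      at <- c(at, i)
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !grepl("^\\s$", chars[j]) && !chars[j] %in% c("(", ")")) j <- j + 1L
      token <- c(token, paste(chars[i:(j - 1L)], collapse = ""))
      at <- c(at, i)
      i <- j
    }
  }
  list(token = token, at = at)
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_fail <- function(st, msg) {
  pos <- if (st$pos <= length(st$at)) st$at[st$pos] else nchar(st$text) + 1L
  stop(sprintf("GPR parse error at position %d: %s in \"%s\"", pos, msg, st$text),
       call. = FALSE)
}

gpr_parse_or <- function(st) {
  res <- gpr_parse_and(st)
  st <- res$state
  args <- list(res$node)
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    res <- gpr_parse_and(st)
    st <- res$state
    args <- c(args, list(res$node))
  }
  node <- if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  list(node = node, state = st)
}

gpr_parse_and <- function(st) {
  res <- gpr_parse_atom(st)
  st <- res$state
  args <- list(res$node)
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    res <- gpr_parse_atom(st)
    st <- res$state
    args <- c(args, list(res$node))
  }
  node <- if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  list(node = node, state = st)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) gpr_fail(st, "missing operand")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    res <- gpr_parse_or(st)
    st <- res$state
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") gpr_fail(st, "unbalanced parentheses")
    st$pos <- st$pos + 1L
    return(list(node = res$node, state = st))
  }
  if (tk == ")") gpr_fail(st, "unbalanced parentheses")
  if (tolower(tk) %in% c("and", "or")) gpr_fail(st, sprintf("empty operand before '%s'", tk))
  st$pos <- st$pos + 1L
  list(node = list(op = "gene", gene = tk), state = st)
}

#' @rdname parse_gpr
#' @param gpr a GPR tree as returned by [parse_gpr()].
#' @export
gpr_to_string <- function(gpr) {
  if (is.null(gpr)) return("")
  if (gpr$op == "gene") return(gpr$gene)
  parts <- vapply(gpr$args, function(a) {
    s <- gpr_to_string(a)
    if (!is.null(a$op) && a$op != "gene") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", gpr$op, " "))
}

#' @rdname parse_gpr
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (gpr$op == "gene") return(gpr$gene)
  sort(unique(unlist(lapply(gpr$args, gpr_genes))))
}

#' Evaluate a GPR rule against a set of present genes
#'
#' Standard boolean semantics: a leaf is true iff its gene is in `present`,
#' `and`/`or` combine children, and the empty rule (`NULL`) is true — a
#' reaction without gene association is not gene-controlled and survives any
#' gene loss.
#'
#' @param gpr a GPR tree ([parse_gpr()]) or a rule string.
#' @param present character vector of gene ids considered present.
#' @return logical scalar.
#' @export
evaluate_gpr <- function(gpr, present) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) return(TRUE)
  switch(gpr$op,
    gene = gpr$gene %in% present,
    and = all(vapply(gpr$args, evaluate_gpr, logical(1), present = present)),
    or = any(vapply(gpr$args, evaluate_gpr, logical(1), present = present)),
    stop("malformed GPR node: ", gpr$op)
  )
}

#' Translate a GPR rule into a target-species gene namespace
#'
#' Each source-gene leaf is replaced by an `or` over its target homologs;
#' a leaf with no homolog becomes constant-false and is simplified away
#' (false absorbs an `and`, disappears from an `or`). The translated rule
#' therefore has the same truth table as the original evaluated through the
#' homology mapping. A rule whose every path requires an unmapped gene
#' collapses to constant false, returned as the sentinel `gpr_false()`.
#'
#' @param gpr GPR tree or rule string in the source namespace.
#' @param homology a [homology_table()] (or a named list mapping source gene
#'   id to a character vector of target gene ids).
#' @return GPR tree in the target namespace, `NULL` (empty rule), or
#'   `gpr_false()` when no gene combination can enable the reaction.
#' @export
translate_gpr <- function(gpr, homology) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  map <- if (inherits(homology, "homology_table")) homology$map else homology
  translate_node(gpr, map)
}

#' @rdname translate_gpr
#' @export
gpr_false <- function() structure(list(op = "false"), class = "gpr_false")

#' @rdname translate_gpr
#' @param x object to test.
#' @export
is_gpr_false <- function(x) !is.null(x) && identical(x$op, "false")

translate_node <- function(gpr, map) {
  if (is.null(gpr)) return(NULL)
  if (gpr$op == "gene") {
    targets <- map[[gpr$gene]]
    if (is.null(targets) || length(targets) == 0L) return(gpr_false())
    if (length(targets) == 1L) return(list(op = "gene", gene = targets))
    return(list(op = "or", args = lapply(sort(targets), function(t) list(op = "gene", gene = t))))
  }
  kids <- lapply(gpr$args, translate_node, map = map)
  dead <- vapply(kids, is_gpr_false, logical(1))
  if (gpr$op == "and") {
    if (any(dead)) return(gpr_false())
    args <- kids
  } else { # or
    args <- kids[!dead]
    if (length(args) == 0L) return(gpr_false())
  }
  if (length(args) == 1L) args[[1]] else list(op = gpr$op, args = args)
}
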