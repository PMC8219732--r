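#' Transpile a motif to a Cypher query
#'
#' Emits the Neo4j Cypher text equivalent to a motif query: one `MATCH`
#' relationship pattern per required edge, one negated pattern predicate per
#' forbidden edge, one `WHERE` predicate per attribute constraint, pairwise
#' node-distinctness predicates enforcing injectivity, and — when `dedup` —
#' `id(A) < id(B)` ordering predicates mirroring [break_symmetry()] so that
#' duplicate motif automorphisms are not reported. Text generation only; no
#' database connection is made.
#'
#' @param m a [motif()].
#' @param edge_label relationship type used in patterns (configurable for
#'   the target schema; e.g. neuPrint-style "ConnectsTo").
#' @param node_label optional node label applied to all aliases.
#' @param dedup include symmetry-breaking ordering predicates.
#' @return object of class `cypher_query`: list with `text` and
#'   `parameter_notes` (clause provenance per motif element).
#' @examples
#' cat(to_cypher(parse_motif("A -> B\nA.size > 50"))$text)
#' @export
to_cypher <- function(m, edge_label = "ConnectsTo", node_label = NULL,
                      dedup = TRUE) {
  if (isTRUE(m$ignore_direction)) {
    stop("unsupported feature for Cypher output: direction-ignoring motifs")
  }
  lab <- if (is.null(node_label)) "" else paste0(":", node_label)
  notes <- list()
  note <- function(elem, clause) notes[[elem]] <<- clause

  pats <- character()
  for (i in seq_len(nrow(m$edges))) {
    f <- m$edges[i, 1]; t <- m$edges[i, 2]
    alias <- paste0(f, "_", t)
    pats <- c(pats, sprintf("(%s%s)-[%s:%s]->(%s%s)", f, lab, alias,
                            edge_label, t, lab))
    note(edge_key(f, t), "MATCH pattern")
  }
  loose <- setdiff(m$nodes, unique(c(t(m$edges))))
  for (v in loose) {
    pats <- c(pats, sprintf("(%s%s)", v, lab))
    note(v, "MATCH pattern (unconnected alias)")
  }

  preds <- character()
  for (i in seq_len(nrow(m$forbidden))) {
    f <- m$forbidden[i, 1]; t <- m$forbidden[i, 2]
    preds <- c(preds, sprintf("NOT (%s)-[:%s]->(%s)", f, edge_label, t))
    note(paste0(f, " !> ", t), "WHERE negated pattern")
  }
  for (cst in m$node_constraints) {
    preds <- c(preds, cypher_predicate(paste0(cst$subject, ".", cst$attribute), cst))
    note(constraint_string(cst), "WHERE predicate")
  }
  for (key in names(m$edge_constraints)) {
    ft <- strsplit(key, "->", fixed = TRUE)[[1]]
    alias <- paste0(ft[1], "_", ft[2])
    for (cst in m$edge_constraints[[key]]) {
      preds <- c(preds, cypher_predicate(paste0(alias, ".", cst$attribute), cst))
      note(constraint_string(cst), "WHERE predicate")
    }
  }
  k <- length(m$nodes)
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) {
        preds <- c(preds, sprintf("%s <> %s", m$nodes[i], m$nodes[j]))
      }
    }
    note("injectivity", "WHERE pairwise distinctness")
  }
  if (dedup) {
    mm <- if (is.null(m$symmetry_perms)) break_symmetry(m) else m
    for (p in mm$ordering) {
      preds <- c(preds, sprintf("id(%s) < id(%s)", p[1], p[2]))
      note(paste0(p[1], " === ", p[2]), "WHERE symmetry-breaking order")
    }
  }

  text <- paste0(
    "MATCH ", paste(pats, collapse = ",\n      "), "\n",
    "WHERE ", if (length(preds)) paste(preds, collapse = "\n  AND ") else "true", "\n",
    "RETURN DISTINCT ", paste(m$nodes, collapse = ", "))
  structure(list(text = text, parameter_notes = notes), class = "cypher_query")
}

cypher_predicate <- function(lhs, cst) {
  op <- switch(cst$op,
               "=" = "=", "!=" = "<>", "<" = "<", "<=" = "<=",
               ">" = ">", ">=" = ">=", "in" = "IN", "contains" = "CONTAINS",
               stop("unsupported operator for Cypher: ", cst$op))
  rhs <- if (!is.null(cst$rhs_ref)) {
    paste0(cst$rhs_ref[1], ".", cst$rhs_ref[2])
  } else {
    cypher_literal(cst$rhs)
  }
  paste(lhs, op, rhs)
}

cypher_literal <- function(v) {
  if (is.list(v)) {
    return(paste0("[", paste(vapply(v, cypher_literal, ""), collapse = ", "), "]"))
  }
  if (is.character(v)) paste0("'", gsub("'", "\\\\'", v), "'")
  else if (is.logical(v)) tolower(as.character(v))
  else format(v, digits = 15)
}

#' @export
print.cypher_query <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}
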