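#' Attribute constraint on a motif node or edge
#'
#' A predicate of the form `subject.attribute <op> rhs`. The right-hand side
#' is either a literal (number, string, or list of those) or a reference to
#' another node's attribute, enabling inter-node comparisons such as
#' "A.radius > B.radius".
#'
#' @param subject a node name (length 1) or an ordered edge as c(from, to).
#' @param attribute attribute name (case-sensitive).
#' @param op one of `=`, `!=`, `<`, `<=`, `>`, `>=`, `in`, `contains`.
#' @param rhs literal value, or NULL when `rhs_ref` is given.
#' @param rhs_ref optional c(node_name, attribute) reference.
#' @return an object of class `motif_constraint`.
#' @export
constraint <- function(subject, attribute, op, rhs = NULL, rhs_ref = NULL) {
  if (!op %in% CONSTRAINT_OPS) {
    stop("unknown constraint operator: ", op,
         " (supported: ", paste(CONSTRAINT_OPS, collapse = " "), ")")
  }
  if (!length(subject) %in% 1:2) stop("constraint subject must be a node or an edge")
  if (is.null(rhs) && is.null(rhs_ref)) stop("constraint needs a rhs or rhs_ref")
  if (!is.null(rhs) && !is.null(rhs_ref)) stop("constraint rhs and rhs_ref are exclusive")
  if (!is.null(rhs_ref) && length(rhs_ref) != 2) {
    stop("rhs_ref must be c(node_name, attribute)")
  }
  structure(list(subject = as.character(subject),
                 attribute = as.character(attribute),
                 op = op,
                 rhs = rhs,
                 rhs_ref = if (!is.null(rhs_ref)) as.character(rhs_ref)),
            class = "motif_constraint")
}

CONSTRAINT_OPS <- c("=", "!=", "<", "<=", ">", ">=", "in", "contains")

#' Evaluate a constraint operator on concrete values
#'
#' Comparisons between mismatched types (e.g. a number against a string) are
#' constraint failures (`FALSE`), never errors, so that queries have
#' predictable matching semantics on heterogeneous attribute data. A missing
#' (`NULL`) operand also fails the constraint.
#'
#' @param op operator string (see [constraint()]).
#' @param lhs,rhs operand values.
#' @return logical scalar.
#' @export
eval_op <- function(op, lhs, rhs) {
  if (is.null(lhs) || is.null(rhs)) return(FALSE)
  if (op == "in") {
    if (length(lhs) != 1) return(FALSE)
    return(any(vapply(as.list(rhs), function(v) same_value(lhs, v), logical(1))))
  }
  if (op == "contains") {
    if (is.character(lhs) && length(lhs) == 1 && is.character(rhs) &&
        length(rhs) == 1) {
      return(grepl(rhs, lhs, fixed = TRUE))
    }
    return(any(vapply(as.list(lhs), function(v) same_value(v, rhs), logical(1))))
  }
  if (length(lhs) != 1 || length(rhs) != 1) return(FALSE)
  if (op == "=") return(same_value(lhs, rhs))
  if (op == "!=") return(!same_value(lhs, rhs))
  # order comparisons: numeric with numeric, string with string
  if (is.numeric(lhs) && is.numeric(rhs)) {
    return(switch(op, "<" = lhs < rhs, "<=" = lhs <= rhs,
                  ">" = lhs > rhs, ">=" = lhs >= rhs))
  }
  if (is.character(lhs) && is.character(rhs)) {
    return(switch(op, "<" = lhs < rhs, "<=" = lhs <= rhs,
                  ">" = lhs > rhs, ">=" = lhs >= rhs))
  }
  FALSE
}

same_value <- function(a, b) {
  if (is.numeric(a) && is.numeric(b)) return(isTRUE(a == b))
  if (is.character(a) && is.character(b)) return(isTRUE(a == b))
  if (is.logical(a) && is.logical(b)) return(isTRUE(a == b))
  FALSE
}

#' Construct a motif query graph
#'
#' A motif is a small named query graph: required directed edges, forbidden
#' edges (host pairs that must *not* be connected), node and edge attribute
#' constraints, declared interchangeable node pairs, and match-mode flags.
#' Usually built by [parse_motif()]; this constructor is the programmatic
#' interface and enforces the structural invariants.
#'
#' @param edges two-column character matrix of required directed edges.
#' @param forbidden two-column character matrix of forbidden edges.
#' @param nodes optional character vector fixing node order; defaults to
#'   order of first appearance in edges/constraints.
#' @param node_constraints list of [constraint()] objects on nodes.
#' @param edge_constraints named list keyed "from->to" of constraint lists.
#' @param interchangeable list of length-2 character vectors of node names
#'   the user asserts to be symmetric.
#' @param exact_match search for node-induced isomorphisms instead of
#'   monomorphisms.
#' @param ignore_direction treat all edges as undirected at match time.
#' @param provenance named list of free-text metadata (author, date, ...).
#' @return object of class `motif`.
#' @examples
#' m <- motif(rbind(c("A", "B"), c("B", "A")))
#' @export
motif <- function(edges, forbidden = NULL, nodes = NULL,
                  node_constraints = list(), edge_constraints = list(),
                  interchangeable = list(), exact_match = FALSE,
                  ignore_direction = FALSE, provenance = list()) {
  edges <- as_edge_matrix(edges)
  forbidden <- as_edge_matrix(forbidden)
  if (any(edges[, 1] == edges[, 2]) || any(forbidden[, 1] == forbidden[, 2])) {
    stop("motif edges may not be self-loops")
  }
  edges <- unique(edges)
  forbidden <- unique(forbidden)
  cn <- unlist(lapply(node_constraints, function(cst) {
    c(cst$subject, if (!is.null(cst$rhs_ref)) cst$rhs_ref[1])
  }))
  seen <- unique(c(t(edges), t(forbidden), cn, unlist(interchangeable)))
  if (is.null(nodes)) nodes <- seen
  nodes <- as.character(nodes)
  if (!all(seen %in% nodes)) {
    stop("names used in edges/constraints missing from node set: ",
         paste(setdiff(seen, nodes), collapse = ", "))
  }
  for (key in names(edge_constraints)) {
    ft <- strsplit(key, "->", fixed = TRUE)[[1]]
    if (length(ft) != 2 || !all(ft %in% nodes)) {
      stop("edge_constraints key does not name motif nodes: ", key)
    }
  }
  for (p in interchangeable) {
    if (length(p) != 2 || p[1] == p[2] || !all(p %in% nodes)) {
      stop("interchangeable pairs must name two distinct motif nodes")
    }
  }
  structure(list(nodes = nodes,
                 edges = edges,
                 forbidden = forbidden,
                 node_constraints = node_constraints,
                 edge_constraints = edge_constraints,
                 interchangeable = interchangeable,
                 exact_match = isTRUE(exact_match),
                 ignore_direction = isTRUE(ignore_direction),
                 provenance = provenance,
                 ordering = list(),      # filled by break_symmetry()
                 symmetry_perms = NULL), # filled by break_symmetry()
            class = "motif")
}

as_edge_matrix <- function(x) {
  if (is.null(x)) return(matrix(character(), 0, 2))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.character(x) && is.null(dim(x)) && length(x) == 2) x <- rbind(x)
  if (!is.matrix(x) || ncol(x) != 2) stop("edges must be a two-column matrix")
  matrix(as.character(x), ncol = 2,
         dimnames = list(NULL, c("from", "to")))
}

edge_key <- function(from, to) paste0(from, "->", to)

#' @export
print.motif <- function(x, ...) {
  cat("Motif:", length(x$nodes), "nodes,", nrow(x$edges), "required edges,",
      nrow(x$forbidden), "forbidden edges\n")
  cat("  mode:", if (x$exact_match) "isomorphism (exact)" else "monomorphism",
      if (x$ignore_direction) "[direction ignored]" else "", "\n")
  if (nrow(x$edges)) {
    cat("  edges:", paste(edge_key(x$edges[, 1], x$edges[, 2]), collapse = ", "), "\n")
  }
  if (nrow(x$forbidden)) {
    cat("  non-edges:", paste(paste0(x$forbidden[, 1], " !> ", x$forbidden[, 2]),
                              collapse = ", "), "\n")
  }
  ncst <- length(x$node_constraints) + sum(lengths(x$edge_constraints))
  if (ncst) cat("  constraints:", ncst, "\n")
  if (length(x$interchangeable)) {
    cat("  interchangeable:",
        paste(vapply(x$interchangeable, paste, "", collapse = " === "),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# All constraints attached to a given node (excluding rhs_ref mentions).
node_constraints_of <- function(m, node) {
  Filter(function(cst) length(cst$subject) == 1 && cst$subject == node,
         m$node_constraints)
}

constraints_of_edge <- function(m, from, to) {
  cs <- m$edge_constraints[[edge_key(from, to)]]
  if (is.null(cs)) list() else cs
}

# Stable one-line serialization of a constraint, used for structural
# comparison and automorphism signatures.
constraint_string <- function(cst) {
  rhs <- if (!is.null(cst$rhs_ref)) {
    paste0("@", cst$rhs_ref[1], ".", cst$rhs_ref[2])
  } else {
    paste(vapply(as.list(cst$rhs), format_value, ""), collapse = ",")
  }
  paste0(paste(cst$subject, collapse = "->"), ".", cst$attribute,
         " ", cst$op, " ", rhs)
}

format_value <- function(v) {
  if (is.character(v)) paste0("\"", v, "\"") else format(v, digits = 15)
}

#' Structural equality of two motifs
#'
#' Compares node sets, required/forbidden edge sets, constraint multisets,
#' interchangeability declarations and match-mode flags, ignoring statement
#' order and provenance. Used to verify parse/serialize round-trips.
#'
#' @param a,b motif objects.
#' @return logical scalar.
#' @export
motif_identical <- function(a, b) {
  canon <- function(m) {
    list(nodes = sort(m$nodes),
         edges = sort(edge_key(m$edges[, 1], m$edges[, 2])),
         forbidden = sort(edge_key(m$forbidden[, 1], m$forbidden[, 2])),
         ncst = sort(vapply(m$node_constraints, constraint_string, "")),
         ecst = sort(unlist(lapply(names(m$edge_constraints), function(k) {
           vapply(m$edge_constraints[[k]], constraint_string, "")
         }))),
         inter = sort(vapply(m$interchangeable,
                             function(p) paste(sort(p), collapse = "==="), "")),
         flags = c(m$exact_match, m$ignore_direction))
  }
  identical(canon(a), canon(b))
}
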