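#' Simplify a motif's constraint sets
#'
#' Removes redundant constraints before search: duplicate edges, non-edges
#' and constraints are deduplicated, and numeric bound constraints on the
#' same subject/attribute are collapsed to the tightest bound (e.g.
#' `x > 5 AND x > 3` becomes `x > 5`). The match set on any host graph is
#' unchanged.
#'
#' @param m a [motif()].
#' @return a semantically equivalent motif.
#' @export
simplify_constraints <- function(m) {
  m$node_constraints <- simplify_cset(m$node_constraints)
  # group node constraints by subject+attribute for bound collapsing
  m$node_constraints <- collapse_bounds(m$node_constraints)
  for (k in names(m$edge_constraints)) {
    m$edge_constraints[[k]] <- collapse_bounds(simplify_cset(m$edge_constraints[[k]]))
  }
  m
}

simplify_cset <- function(csts) {
  if (!length(csts)) return(csts)
  csts[!duplicated(vapply(csts, constraint_string, ""))]
}

collapse_bounds <- function(csts) {
  if (length(csts) < 2) return(csts)
  is_bound <- vapply(csts, function(cst) {
    cst$op %in% c("<", "<=", ">", ">=") && is.null(cst$rhs_ref) &&
      is.numeric(cst$rhs) && length(cst$rhs) == 1
  }, logical(1))
  bounds <- csts[is_bound]
  rest <- csts[!is_bound]
  keys <- vapply(bounds, function(cst) {
    paste(paste(cst$subject, collapse = "->"), cst$attribute)
  }, "")
  out <- rest
  for (key in unique(keys)) {
    grp <- bounds[keys == key]
    lower <- Filter(function(cst) cst$op %in% c(">", ">="), grp)
    upper <- Filter(function(cst) cst$op %in% c("<", "<="), grp)
    pick <- function(set, best) {
      if (!length(set)) return(NULL)
      vals <- vapply(set, function(cst) cst$rhs, 0)
      strict <- vapply(set, function(cst) cst$op %in% c(">", "<"), logical(1))
      i <- order(if (best == "max") -vals else vals, !strict)[1]
      set[[i]]
    }
    out <- c(out, Filter(Negate(is.null), list(pick(lower, "max"), pick(upper, "min"))))
  }
  out
}

#' Detect the automorphism group of a motif
#'
#' An automorphism is a permutation of the motif's nodes that maps required
#' edges onto required edges, forbidden edges onto forbidden edges, and
#' preserves the full constraint multiset under renaming — i.e. both the
#' syntactic structure and the attribute semantics are preserved, so two
#' nodes are interchangeable only if their constraints agree. Found by
#' exhaustive backtracking over node bijections with degree/constraint
#' partition pruning; exact for the small query graphs this package targets.
#'
#' User-declared interchangeable pairs are verified against the detected
#' group: declaring a pair that is not actually an automorphism is an error.
#'
#' @param m a [motif()].
#' @param max_nodes guard on motif size for the exhaustive search.
#' @return object of class `automorphism_group` with elements
#'   `permutations` (integer matrix, one row per group element, identity
#'   included), `nodes`, `orbits` (list of node-name vectors),
#'   `generating_pairs` (unordered node pairs whose transposition is in the
#'   group; sufficient to break all pairwise symmetry), and `order`.
#' @examples
#' find_automorphisms(parse_motif("A -> B\nB -> A"))$order
#' @export
find_automorphisms <- function(m, max_nodes = 10) {
  k <- length(m$nodes)
  if (k > max_nodes) {
    stop("automorphism search is exhaustive and limited to ", max_nodes,
         " motif nodes (got ", k, "); raise max_nodes to override")
  }
  nidx <- stats::setNames(seq_len(k), m$nodes)
  R <- matrix(FALSE, k, k)
  if (nrow(m$edges)) R[cbind(nidx[m$edges[, 1]], nidx[m$edges[, 2]])] <- TRUE
  Fb <- matrix(FALSE, k, k)
  if (nrow(m$forbidden)) Fb[cbind(nidx[m$forbidden[, 1]], nidx[m$forbidden[, 2]])] <- TRUE
  if (isTRUE(m$ignore_direction)) {
    R <- R | t(R)
    Fb <- Fb | t(Fb)
  }

  cst_strings <- function(map) {
    # full constraint multiset under node renaming `map` (orig idx -> idx)
    rename <- function(x) m$nodes[map[nidx[x]]]
    out <- character()
    for (cst in m$node_constraints) {
      c2 <- cst
      c2$subject <- rename(cst$subject)
      if (!is.null(cst$rhs_ref)) c2$rhs_ref[1] <- rename(cst$rhs_ref[1])
      out <- c(out, constraint_string(c2))
    }
    for (key in names(m$edge_constraints)) {
      ft <- strsplit(key, "->", fixed = TRUE)[[1]]
      for (cst in m$edge_constraints[[key]]) {
        c2 <- cst
        c2$subject <- rename(ft)
        if (isTRUE(m$ignore_direction)) c2$subject <- sort(c2$subject)
        if (!is.null(cst$rhs_ref)) c2$rhs_ref[1] <- rename(cst$rhs_ref[1])
        out <- c(out, constraint_string(c2))
      }
    }
    sort(out)
  }
  base_csts <- cst_strings(seq_len(k))

  # pruning signature: degrees plus local literal-constraint fingerprint
  local_sig <- vapply(seq_len(k), function(u) {
    lits <- Filter(function(cst) is.null(cst$rhs_ref),
                   node_constraints_of(m, m$nodes[u]))
    strs <- sort(vapply(lits, function(cst) {
      paste(cst$attribute, cst$op, serialize_value(cst))
    }, ""))
    paste(sum(R[u, ]), sum(R[, u]), sum(Fb[u, ]), sum(Fb[, u]),
          paste(strs, collapse = ";"))
  }, "")

  perms <- list()
  img <- integer(k)
  used <- logical(k)
  recurse <- function(d) {
    if (d > k) {
      if (identical(cst_strings(img), base_csts)) {
        perms[[length(perms) + 1L]] <<- img
      }
      return(invisible(NULL))
    }
    for (v in seq_len(k)) {
      if (used[v] || local_sig[v] != local_sig[d]) next
      ok <- TRUE
      for (u in seq_len(d - 1L)) {
        if (R[img[u], v] != R[u, d] || R[v, img[u]] != R[d, u] ||
            Fb[img[u], v] != Fb[u, d] || Fb[v, img[u]] != Fb[d, u]) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      img[d] <<- v; used[v] <<- TRUE
      recurse(d + 1L)
      used[v] <<- FALSE
    }
  }
  recurse(1L)
  P <- do.call(rbind, perms)

  in_group <- function(perm) any(apply(P, 1, identical, y = perm))
  for (pair in m$interchangeable) {
    tr <- seq_len(k)
    tr[nidx[pair]] <- nidx[rev(pair)]
    if (!in_group(as.integer(tr))) {
      stop("declared interchangeable pair ", pair[1], " === ", pair[2],
           " is not an automorphism of the motif")
    }
  }

  # orbits: union-find over all permutations
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (r in seq_len(nrow(P))) {
    for (u in seq_len(k)) {
      a <- find(u); b <- find(P[r, u])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  orbits <- lapply(unique(roots), function(r) m$nodes[roots == r])

  gen_pairs <- list()
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) {
        tr <- seq_len(k); tr[c(i, j)] <- c(j, i)
        if (in_group(as.integer(tr))) {
          gen_pairs[[length(gen_pairs) + 1L]] <- m$nodes[c(i, j)]
        }
      }
    }
  }

  structure(list(permutations = P, nodes = m$nodes, orbits = orbits,
                 generating_pairs = gen_pairs, order = nrow(P)),
            class = "automorphism_group")
}

#' @export
print.automorphism_group <- function(x, ...) {
  cat("Automorphism group of order", x$order, "on",
      length(x$nodes), "nodes\n")
  cat("  orbits:", paste(vapply(x$orbits, function(o) {
    paste0("{", paste(o, collapse = ","), "}")
  }, ""), collapse = " "), "\n")
  invisible(x)
}

#' Enrich a motif with symmetry-breaking constraints
#'
#' Ensures the search returns exactly one representative per
#' automorphism-equivalence class of matches. Two complementary mechanisms
#' are attached to the motif: (a) internal host-node ordering constraints
#' (`id(A) < id(B)`) for every node pair whose transposition is in the
#' group — these prune the search early and are always sound; (b) a
#' lexicographic-minimum orbit filter under the full group, applied to
#' completed mappings — this is exact for every group, including cyclic
#' symmetries that pairwise orderings alone cannot break. For an asymmetric
#' motif (trivial group) the match set is unchanged.
#'
#' @param m a [motif()].
#' @param group an [find_automorphisms()] result; computed if missing.
#' @return the motif with `ordering` pairs and the symmetry group attached.
#' @export
break_symmetry <- function(m, group = NULL) {
  if (is.null(group)) group <- find_automorphisms(m)
  nidx <- stats::setNames(seq_along(m$nodes), m$nodes)
  m$ordering <- lapply(group$generating_pairs, function(p) {
    p[order(nidx[p])]  # orient along motif node order: earlier node smaller
  })
  m$symmetry_perms <- group$permutations
  m
}
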