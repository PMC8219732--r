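# Independent brute-force oracle for subgraph matching: enumerates every
# injective tuple of host nodes and filters it directly against the match
# definition. Shares no code with the package's queue search (its own
# operator evaluator, its own automorphism enumeration), so agreement is
# meaningful.

ov_eval <- function(op, lhs, rhs) {
  if (is.null(lhs) || is.null(rhs)) return(FALSE)
  if (length(lhs) == 1 && is.atomic(lhs) && is.na(lhs)) return(FALSE)
  scalar_eq <- function(a, b) {
    (is.numeric(a) && is.numeric(b) && isTRUE(a == b)) ||
      (is.character(a) && is.character(b) && isTRUE(a == b)) ||
      (is.logical(a) && is.logical(b) && isTRUE(a == b))
  }
  if (op == "in") return(any(sapply(as.list(rhs), scalar_eq, a = lhs)))
  if (op == "contains") {
    if (is.character(lhs) && length(lhs) == 1 && is.character(rhs)) {
      return(grepl(rhs, lhs, fixed = TRUE))
    }
    return(any(sapply(as.list(lhs), scalar_eq, b = rhs)))
  }
  if (op == "=") return(scalar_eq(lhs, rhs))
  if (op == "!=") return(!scalar_eq(lhs, rhs))
  if ((is.numeric(lhs) && is.numeric(rhs)) ||
      (is.character(lhs) && is.character(rhs))) {
    return(isTRUE(switch(op, "<" = lhs < rhs, "<=" = lhs <= rhs,
                         ">" = lhs > rhs, ">=" = lhs >= rhs)))
  }
  FALSE
}

# All injective k-tuples over 1..n as a matrix (rows).
injective_tuples <- function(n, k) {
  tu <- as.matrix(expand.grid(rep(list(seq_len(n)), k)))
  dimnames(tu) <- NULL
  if (k > 1) {
    ok <- rep(TRUE, nrow(tu))
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) ok <- ok & tu[, i] != tu[, j]
    }
    tu <- tu[ok, , drop = FALSE]
  }
  tu
}

oracle_matches <- function(m, host, mode = "monomorphism") {
  nm <- igraph::V(host)$name
  n <- length(nm)
  k <- length(m$nodes)
  empty <- matrix(character(), 0, k, dimnames = list(NULL, m$nodes))
  if (n < k) return(empty)
  A <- matrix(FALSE, n, n)
  eid <- matrix(0L, n, n)
  if (igraph::ecount(host) > 0) {
    ends <- igraph::ends(host, igraph::E(host), names = FALSE)
    A[ends] <- TRUE
    eid[ends] <- seq_len(nrow(ends))
    if (!igraph::is_directed(host)) {
      A[ends[, 2:1, drop = FALSE]] <- TRUE
      eid[ends[, 2:1, drop = FALSE]] <- seq_len(nrow(ends))
    }
  }
  S <- A | t(A)
  eid_s <- pmax(eid, t(eid))
  Adj <- if (isTRUE(m$ignore_direction)) S else A
  Eid <- if (isTRUE(m$ignore_direction)) eid_s else eid
  idx <- setNames(seq_len(k), m$nodes)
  tu <- injective_tuples(n, k)

  keep <- rep(TRUE, nrow(tu))
  for (i in seq_len(nrow(m$edges))) {
    u <- idx[m$edges[i, 1]]; v <- idx[m$edges[i, 2]]
    keep <- keep & Adj[cbind(tu[, u], tu[, v])]
  }
  for (i in seq_len(nrow(m$forbidden))) {
    u <- idx[m$forbidden[i, 1]]; v <- idx[m$forbidden[i, 2]]
    keep <- keep & !Adj[cbind(tu[, u], tu[, v])]
  }
  if (mode == "isomorphism" && k > 1) {
    req <- matrix(FALSE, k, k)
    for (i in seq_len(nrow(m$edges))) {
      req[idx[m$edges[i, 1]], idx[m$edges[i, 2]]] <- TRUE
    }
    if (isTRUE(m$ignore_direction)) req <- req | t(req)
    for (u in seq_len(k)) {
      for (v in seq_len(k)) {
        if (u == v || req[u, v]) next
        keep <- keep & !Adj[cbind(tu[, u], tu[, v])]
      }
    }
  }
  tu <- tu[keep, , drop = FALSE]
  if (!nrow(tu)) return(empty)

  vattrs <- igraph::vertex_attr(host)
  eattrs <- igraph::edge_attr(host)
  vval <- function(i, attr) {
    col <- vattrs[[attr]]
    if (is.null(col)) NULL else if (is.list(col)) col[[i]] else col[i]
  }
  eval_one <- function(row) {
    for (cst in m$node_constraints) {
      lhs <- vval(row[idx[cst$subject]], cst$attribute)
      rhs <- if (!is.null(cst$rhs_ref)) {
        vval(row[idx[cst$rhs_ref[1]]], cst$rhs_ref[2])
      } else cst$rhs
      if (!ov_eval(cst$op, lhs, rhs)) return(FALSE)
    }
    for (key in names(m$edge_constraints)) {
      ft <- strsplit(key, "->", fixed = TRUE)[[1]]
      e <- Eid[row[idx[ft[1]]], row[idx[ft[2]]]]
      for (cst in m$edge_constraints[[key]]) {
        col <- eattrs[[cst$attribute]]
        lhs <- if (e == 0 || is.null(col)) NULL else
          if (is.list(col)) col[[e]] else col[e]
        rhs <- if (!is.null(cst$rhs_ref)) {
          vval(row[idx[cst$rhs_ref[1]]], cst$rhs_ref[2])
        } else cst$rhs
        if (!ov_eval(cst$op, lhs, rhs)) return(FALSE)
      }
    }
    TRUE
  }
  if (length(m$node_constraints) || length(m$edge_constraints)) {
    tu <- tu[apply(tu, 1, eval_one), , drop = FALSE]
  }
  if (!nrow(tu)) return(empty)
  out <- matrix(nm[tu], ncol = k, dimnames = list(NULL, m$nodes))
  out[order(apply(out, 1, paste, collapse = "\r")), , drop = FALSE]
}

# Automorphisms of a motif by direct permutation filtering (independent of
# the package's backtracking search).
oracle_automorphisms <- function(m) {
  k <- length(m$nodes)
  perm_list <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_list(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  edge_set <- function(ed, map) {
    if (!nrow(ed)) return(character())
    s <- paste(map[ed[, 1]], map[ed[, 2]])
    if (isTRUE(m$ignore_direction)) {
      # direction-ignoring motifs: an edge listed in both directions is one
      # undirected requirement, so compare sets, not multisets
      s <- unique(apply(cbind(map[ed[, 1]], map[ed[, 2]]), 1,
                        function(r) paste(sort(r), collapse = " ")))
    }
    sort(unname(s))
  }
  cst_set <- function(map) {
    out <- character()
    for (cst in m$node_constraints) {
      rhs <- if (!is.null(cst$rhs_ref)) {
        paste0("@", map[cst$rhs_ref[1]], ".", cst$rhs_ref[2])
      } else paste(deparse(cst$rhs), collapse = "")
      out <- c(out, paste(map[cst$subject], cst$attribute, cst$op, rhs))
    }
    for (key in names(m$edge_constraints)) {
      ft <- strsplit(key, "->", fixed = TRUE)[[1]]
      ftm <- map[ft]
      if (isTRUE(m$ignore_direction)) ftm <- sort(ftm)
      for (cst in m$edge_constraints[[key]]) {
        rhs <- if (!is.null(cst$rhs_ref)) {
          paste0("@", map[cst$rhs_ref[1]], ".", cst$rhs_ref[2])
        } else paste(deparse(cst$rhs), collapse = "")
        out <- c(out, paste(paste(ftm, collapse = ">"), cst$attribute,
                            cst$op, rhs))
      }
    }
    sort(out)
  }
  id <- setNames(m$nodes, m$nodes)
  base <- list(edge_set(m$edges, id), edge_set(m$forbidden, id), cst_set(id))
  keep <- list()
  for (p in perm_list(m$nodes)) {
    map <- setNames(p, m$nodes)
    cand <- list(edge_set(m$edges, map), edge_set(m$forbidden, map),
                 cst_set(map))
    if (identical(cand, base)) keep[[length(keep) + 1]] <- map
  }
  keep
}

# Deduplicate oracle matches by automorphism orbit (one representative per
# equivalence class).
oracle_dedup <- function(matches, m) {
  if (!nrow(matches)) return(matches)
  auts <- oracle_automorphisms(m)
  keys <- apply(matches, 1, function(row) {
    imgs <- vapply(auts, function(map) {
      paste(row[map[colnames(matches)]], collapse = "\r")
    }, "")
    min(imgs)
  })
  matches[!duplicated(keys), , drop = FALSE]
}

# ---- randomized fixtures ---------------------------------------------------

random_host <- function(n, seed, p = 0.25, directed = TRUE) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p, directed = directed)
  igraph::V(g)$name <- paste0("h", seq_len(n))
  igraph::V(g)$weight <- round(runif(n, 0, 20), 1)
  igraph::V(g)$kind <- sample(c("exc", "inh", "mod"), n, replace = TRUE)
  if (igraph::ecount(g)) {
    igraph::E(g)$weight <- round(runif(igraph::ecount(g), 0, 20), 1)
    igraph::E(g)$type <- sample(c("GABA", "glutamate"), igraph::ecount(g),
                                replace = TRUE)
  }
  g
}

random_motif <- function(seed, max_nodes = 4, constrained = TRUE) {
  set.seed(seed)
  k <- sample(2:max_nodes, 1)
  nodes <- LETTERS[seq_len(k)]
  pairs <- which(!diag(k) > 0, arr.ind = TRUE)
  n_edges <- sample(seq_len(min(4, nrow(pairs))), 1)
  sel <- sample(nrow(pairs), n_edges)
  edges <- matrix(nodes[pairs[sel, , drop = FALSE]], ncol = 2)
  forb <- NULL
  rest <- setdiff(seq_len(nrow(pairs)), sel)
  if (length(rest) && runif(1) < 0.4) {
    forb <- matrix(nodes[pairs[sample(rest, 1), , drop = FALSE]], ncol = 2)
  }
  ncst <- list()
  ecst <- list()
  used <- unique(c(edges, forb))  # constrain only nodes that sit on an edge
  if (constrained) {
    if (runif(1) < 0.6) {
      op <- sample(c(">", "<=", "=", "!=", ">="), 1)
      rhs <- if (op %in% c("=", "!=") && runif(1) < 0.5) {
        sample(c("exc", "inh"), 1)
      } else round(runif(1, 0, 20))
      attr <- if (is.character(rhs)) "kind" else "weight"
      ncst <- list(motifquery::constraint(sample(used, 1), attr, op, rhs))
    }
    if (runif(1) < 0.5) {
      i <- sample(n_edges, 1)
      key <- paste0(edges[i, 1], "->", edges[i, 2])
      op <- sample(c(">", "<", ">="), 1)
      ecst[[key]] <- list(motifquery::constraint(edges[i, ], "weight", op,
                                                 round(runif(1, 0, 20))))
    }
    if (runif(1) < 0.25 && length(used) >= 2) {
      ab <- sample(used, 2)
      ncst <- c(ncst, list(motifquery::constraint(
        ab[1], "weight", sample(c(">", "<="), 1), rhs_ref = c(ab[2], "weight"))))
    }
  }
  motifquery::motif(edges, forbidden = forb,
                    node_constraints = ncst, edge_constraints = ecst,
                    ignore_direction = runif(1) < 0.2)
}

# Satisfiability check by explicit assignment search over a small value
# domain (used to verify that the validator passes satisfiable motifs).
assignment_satisfiable <- function(m) {
  domain <- list(0, 1, 5, 10, 100, "GABA", "glutamate", "a", "b")
  groups <- list()
  for (cst in m$node_constraints) {
    if (!is.null(cst$rhs_ref)) next
    key <- paste0(cst$subject, ".", cst$attribute)
    groups[[key]] <- c(groups[[key]], list(cst))
  }
  for (k in names(m$edge_constraints)) {
    for (cst in m$edge_constraints[[k]]) {
      if (!is.null(cst$rhs_ref)) next
      key <- paste0(k, ".", cst$attribute)
      groups[[key]] <- c(groups[[key]], list(cst))
    }
  }
  for (key in names(groups)) {
    csts <- groups[[key]]
    vals <- c(domain, lapply(csts, function(cst) if (!is.list(cst$rhs)) cst$rhs))
    ok <- any(vapply(vals, function(v) {
      if (is.null(v)) return(FALSE)
      all(vapply(csts, function(cst) ov_eval(cst$op, v, cst$rhs), logical(1)))
    }, logical(1)))
    if (!ok) return(FALSE)
  }
  TRUE
}
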