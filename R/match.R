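#' Find all matches of a motif in a host graph
#'
#' Enumerates injective mappings of motif nodes onto host nodes such that
#' every required motif edge maps onto a host edge (direction respected
#' unless the motif ignores direction), every forbidden edge maps onto a
#' host non-edge, and all node/edge attribute constraints hold. In
#' `"monomorphism"` mode (the default) extra host edges among mapped nodes
#' are allowed; in `"isomorphism"` mode the match must be a node-induced
#' subgraph, i.e. host edges between mapped pairs not required by the motif
#' are disallowed.
#'
#' The search maintains its state space in a one-dimensional queue of
#' partial mappings; dead partial states are never enqueued. The queue
#' discipline (`"fifo"` or `"lifo"`) affects traversal order only, never the
#' result set.
#'
#' With `dedup = TRUE` (the default, as symmetric motifs otherwise
#' over-count), one representative per motif-automorphism equivalence class
#' is returned: the automorphism group is detected with
#' [find_automorphisms()], the query is enriched with symmetry-breaking
#' ordering constraints via [break_symmetry()], and completed mappings are
#' kept only if lexicographically minimal within their orbit.
#'
#' @param m a [motif()].
#' @param host an igraph host graph.
#' @param mode `"monomorphism"` or `"isomorphism"`; default follows the
#'   motif's `exact_match` flag.
#' @param dedup return one representative per automorphism class.
#' @param queue queue discipline, `"fifo"` (default) or `"lifo"`.
#' @return character matrix, one row per match, columns named by motif
#'   nodes, values host node names; rows sorted lexicographically.
#' @examples
#' host <- host_graph(rbind(c("x", "y"), c("y", "z"), c("z", "x")))
#' find_matches(parse_motif("A -> B"), host)
#' @export
find_matches <- function(m, host, mode = NULL, dedup = TRUE,
                         queue = c("fifo", "lifo")) {
  res <- run_search(m, host, mode, dedup, match.arg(queue), collect = TRUE)
  out <- res$matches
  if (length(out) == 0) {
    return(matrix(character(), 0, length(m$nodes), dimnames = list(NULL, m$nodes)))
  }
  mat <- do.call(rbind, out)
  mat <- matrix(res$host_names[mat], ncol = length(m$nodes),
                dimnames = list(NULL, m$nodes))
  mat[order(apply(mat, 1, paste, collapse = "\r")), , drop = FALSE]
}

#' Count matches without materializing them
#'
#' Streaming counterpart of [find_matches()]: identical semantics, but
#' completed mappings are only counted, bounding memory on motif-rich hosts.
#'
#' @inheritParams find_matches
#' @return non-negative integer.
#' @export
count_matches <- function(m, host, mode = NULL, dedup = TRUE,
                          queue = c("fifo", "lifo")) {
  run_search(m, host, mode, dedup, match.arg(queue), collect = FALSE)$count
}

#' Expand a partial mapping by one motif node
#'
#' The child-generation step of the queue search, exposed for inspection:
#' given a consistent partial mapping, returns one child per candidate host
#' node for the next unassigned motif node such that the extended mapping
#' remains injective and satisfies every edge, non-edge and constraint
#' restricted to assigned nodes.
#'
#' @param partial named character vector mapping already-assigned motif
#'   nodes to host node names (may be empty: `character()`).
#' @inheritParams find_matches
#' @return list of named character vectors, each one node larger.
#' @export
extend_mapping <- function(partial, m, host, mode = NULL) {
  mode <- resolve_mode(m, mode)
  assigned <- names(partial)
  if (!all(assigned %in% m$nodes)) stop("partial mapping names unknown motif nodes")
  order_hint <- c(assigned, setdiff(m$nodes, assigned))
  cq <- compile_query(m, host, mode, order_hint = order_hint)
  k <- length(m$nodes)
  p <- length(assigned)
  if (p >= k) stop("partial mapping is already complete")
  state <- match(partial, cq$hx$names)
  if (anyNA(state)) stop("partial mapping names unknown host nodes")
  kids <- child_states(cq, as.integer(state), p)
  lapply(kids, function(st) {
    stats::setNames(cq$hx$names[st], cq$order_names[seq_len(p + 1)])
  })
}

resolve_mode <- function(m, mode) {
  if (is.null(mode)) {
    return(if (isTRUE(m$exact_match)) "isomorphism" else "monomorphism")
  }
  match.arg(mode, c("monomorphism", "isomorphism"))
}

# ---- query compilation ---------------------------------------------------

# Compiles a motif against a host into a positional check plan: motif nodes
# get a static assignment order (most-constrained-first: constraint count
# plus degree into the already-ordered set, ties by node order), and every
# edge/non-edge/constraint/ordering check is attached to the first position
# at which all of its participants are assigned.
compile_query <- function(m, host, mode, order_hint = NULL) {
  hx <- host_index(host)
  k <- length(m$nodes)
  if (k == 0) stop("motif has no nodes")
  nidx <- stats::setNames(seq_len(k), m$nodes)

  n_cst <- integer(k)
  for (cst in m$node_constraints) n_cst[nidx[cst$subject]] <- n_cst[nidx[cst$subject]] + 1L
  deg <- integer(k)
  all_pairs <- rbind(m$edges, m$forbidden)
  for (i in seq_len(nrow(all_pairs))) {
    deg[nidx[all_pairs[i, 1]]] <- deg[nidx[all_pairs[i, 1]]] + 1L
    deg[nidx[all_pairs[i, 2]]] <- deg[nidx[all_pairs[i, 2]]] + 1L
  }

  if (is.null(order_hint)) {
    ord <- integer(0)
    remaining <- seq_len(k)
    adj <- matrix(FALSE, k, k)
    if (nrow(m$edges)) {
      adj[cbind(nidx[m$edges[, 1]], nidx[m$edges[, 2]])] <- TRUE
    }
    adj <- adj | t(adj)
    while (length(remaining)) {
      into <- vapply(remaining, function(u) sum(adj[u, ord]), 0L)
      score <- n_cst[remaining] + deg[remaining] + 2L * into
      pick <- remaining[order(-score, remaining)[1]]
      ord <- c(ord, pick)
      remaining <- setdiff(remaining, pick)
    }
  } else {
    ord <- unname(nidx[order_hint])
  }
  pos <- integer(k); pos[ord] <- seq_len(k)  # original index -> position

  checks <- vector("list", k)
  add <- function(at, chk) checks[[at]][[length(checks[[at]]) + 1L]] <<- chk

  sym <- isTRUE(m$ignore_direction)
  req <- matrix(0L, 0, 2)
  if (nrow(m$edges)) {
    req <- cbind(unname(nidx[m$edges[, 1]]), unname(nidx[m$edges[, 2]]))
  }
  for (i in seq_len(nrow(req))) {
    at <- max(pos[req[i, ]])
    add(at, list(type = "edge", u = pos[req[i, 1]], v = pos[req[i, 2]]))
  }
  if (nrow(m$forbidden)) {
    forb <- cbind(unname(nidx[m$forbidden[, 1]]), unname(nidx[m$forbidden[, 2]]))
    for (i in seq_len(nrow(forb))) {
      add(max(pos[forb[i, ]]),
          list(type = "nonedge", u = pos[forb[i, 1]], v = pos[forb[i, 2]]))
    }
  }
  if (mode == "isomorphism") {
    has_req <- matrix(FALSE, k, k)
    if (nrow(req)) has_req[req] <- TRUE
    if (sym) has_req <- has_req | t(has_req)
    for (u in seq_len(k)) {
      for (v in seq_len(k)) {
        if (u == v || has_req[u, v]) next
        if (sym && u > v) next
        add(max(pos[u], pos[v]),
            list(type = "nonedge", u = pos[u], v = pos[v]))
      }
    }
  }
  for (cst in m$node_constraints) {
    su <- nidx[cst$subject]
    rp <- if (!is.null(cst$rhs_ref)) nidx[cst$rhs_ref[1]] else NA_integer_
    at <- max(pos[su], if (!is.na(rp)) pos[rp] else 0L)
    add(at, list(type = "nodecst", s = pos[su], cst = cst,
                 r = if (is.na(rp)) NA_integer_ else pos[rp]))
  }
  for (key in names(m$edge_constraints)) {
    ft <- strsplit(key, "->", fixed = TRUE)[[1]]
    for (cst in m$edge_constraints[[key]]) {
      rp <- if (!is.null(cst$rhs_ref)) nidx[cst$rhs_ref[1]] else NA_integer_
      at <- max(pos[nidx[ft[1]]], pos[nidx[ft[2]]],
                if (!is.na(rp)) pos[rp] else 0L)
      add(at, list(type = "edgecst", u = pos[nidx[ft[1]]], v = pos[nidx[ft[2]]],
                   cst = cst, r = if (is.na(rp)) NA_integer_ else pos[rp]))
    }
  }
  for (pair in m$ordering) {
    add(max(pos[nidx[pair]]),
        list(type = "order", lo = pos[nidx[pair[1]]], hi = pos[nidx[pair[2]]]))
  }

  perms <- NULL
  if (!is.null(m$symmetry_perms) && nrow(m$symmetry_perms) > 1) {
    perms <- m$symmetry_perms  # rows: permutations over original node indices
  }
  list(hx = hx, k = k, order = ord, order_names = m$nodes[ord], pos = pos,
       checks = checks, sym = sym, perms = perms)
}

# Evaluate every check attached to position p for candidate `cand`.
check_position <- function(cq, a, p, cand) {
  a[p] <- cand
  hx <- cq$hx
  A <- if (cq$sym) hx$Asym else hx$A
  for (chk in cq$checks[[p]]) {
    ok <- switch(chk$type,
      edge = A[a[chk$u], a[chk$v]],
      nonedge = !A[a[chk$u], a[chk$v]],
      nodecst = {
        cst <- chk$cst
        lhs <- host_node_attr(hx, a[chk$s], cst$attribute)
        rhs <- if (!is.na(chk$r)) {
          host_node_attr(hx, a[chk$r], cst$rhs_ref[2])
        } else cst$rhs
        eval_op(cst$op, lhs, rhs)
      },
      edgecst = {
        cst <- chk$cst
        lhs <- host_edge_attr(hx, a[chk$u], a[chk$v], cst$attribute,
                              symmetric = cq$sym)
        rhs <- if (!is.na(chk$r)) {
          host_node_attr(hx, a[chk$r], cst$rhs_ref[2])
        } else cst$rhs
        eval_op(cst$op, lhs, rhs)
      },
      order = a[chk$lo] < a[chk$hi])
    if (!isTRUE(ok)) return(FALSE)
  }
  TRUE
}

# All consistent one-node extensions of a state with p assigned positions.
child_states <- function(cq, a, p) {
  used <- a[seq_len(p)]
  kids <- list()
  for (cand in seq_len(cq$hx$n)) {
    if (cand %in% used) next
    if (check_position(cq, a, p + 1L, cand)) {
      child <- a
      child[p + 1L] <- cand
      kids[[length(kids) + 1L]] <- child
    }
  }
  kids
}

# Keep a completed mapping only if it is the lexicographically minimal
# member of its automorphism orbit (host indices in original node order).
is_orbit_representative <- function(morig, perms) {
  for (r in seq_len(nrow(perms))) {
    img <- morig[perms[r, ]]
    for (i in seq_along(morig)) {
      if (img[i] < morig[i]) return(FALSE)
      if (img[i] > morig[i]) break
    }
  }
  TRUE
}

run_search <- function(m, host, mode, dedup, queue, collect) {
  mode <- resolve_mode(m, mode)
  if (dedup && is.null(m$symmetry_perms)) {
    grp <- find_automorphisms(m)
    m <- break_symmetry(m, grp)
  }
  cq <- compile_query(m, host, mode)
  k <- cq$k
  n <- cq$hx$n
  count <- 0L
  matches <- list()
  if (n < k) return(list(count = 0L, matches = list(), host_names = cq$hx$names))

  init <- rep(NA_integer_, k)
  qenv <- list(init)   # queue of (state, depth) pairs; depth tracked in slot k+1
  depths <- 0L
  head <- 1L
  while (head <= length(qenv)) {
    if (queue == "fifo") {
      st <- qenv[[head]]; p <- depths[head]; head <- head + 1L
    } else {
      last <- length(qenv)
      st <- qenv[[last]]; p <- depths[last]
      qenv[[last]] <- NULL; depths <- depths[-last]
    }
    kids <- child_states(cq, st, p)
    for (child in kids) {
      if (p + 1L == k) {
        morig <- child[cq$pos]  # original node order
        if (is.null(cq$perms) || !dedup || is_orbit_representative(morig, cq$perms)) {
          count <- count + 1L
          if (collect) matches[[length(matches) + 1L]] <- morig
        }
      } else {
        qenv[[length(qenv) + 1L]] <- child
        depths <- c(depths, p + 1L)
      }
    }
    if (head > 4096L) { # drop the consumed queue prefix to bound memory
      qenv <- qenv[seq.int(head, length(qenv))]
      depths <- depths[seq.int(head, length(depths))]
      head <- 1L
    }
  }
  list(count = count, matches = matches, host_names = cq$hx$names)
}
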