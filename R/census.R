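# Exhaustive enumeration of small-graph isomorphism classes via bitmask
# canonical forms: a graph on n labelled nodes is a bitmask over edge slots
# (unordered pairs when undirected, ordered pairs when directed); the
# canonical form of a mask is the minimum over all n! node permutations of
# the permuted mask. Vectorized over all 2^S masks at once.

# All permutations of 1..n as a matrix (n! rows).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, p + (p >= k))
  }))
}

# Edge slots: ordered (i, j) pairs for directed graphs, i < j pairs for
# undirected; returned in row-major order so slot indices are stable.
edge_slots <- function(n, directed) {
  idx <- which(if (directed) !diag(n) > 0 else upper.tri(matrix(0, n, n)),
               arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# Canonical mask of every graph on n nodes; returns the canonical value for
# each of the 2^S masks (index = mask + 1).
canonical_masks <- function(n, directed) {
  sl <- edge_slots(n, directed)
  S <- nrow(sl)
  key <- matrix(0L, n, n)
  for (i in seq_len(S)) {
    key[sl[i, 1], sl[i, 2]] <- i
    if (!directed) key[sl[i, 2], sl[i, 1]] <- i
  }
  P <- all_perms(n)
  masks <- 0:(2^S - 1)
  bits <- lapply(seq_len(S), function(s) {
    bitwAnd(masks, bitwShiftL(1L, s - 1L)) != 0L
  })
  canon <- rep(Inf, length(masks))
  for (pi in seq_len(nrow(P))) {
    pr <- P[pi, ]
    slotmap <- vapply(seq_len(S), function(s) key[pr[sl[s, 1]], pr[sl[s, 2]]],
                      integer(1))
    pm <- numeric(length(masks))
    for (s in seq_len(S)) pm <- pm + bits[[s]] * 2^(slotmap[s] - 1)
    canon <- pmin(canon, pm)
  }
  canon
}

mask_to_edges <- function(mask, slots) {
  on <- which(floor(mask / 2^(seq_len(nrow(slots)) - 1)) %% 2 == 1)
  slots[on, , drop = FALSE]
}

# Is the (possibly directed) edge set connected over all n nodes, ignoring
# direction (weak connectivity)?
edges_connected <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(edges))) {
    a <- find(edges[i, 1]); b <- find(edges[i, 2])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1
}

# Automorphism count of a labelled graph given as a mask.
mask_aut_order <- function(mask, n, directed) {
  sl <- edge_slots(n, directed)
  S <- nrow(sl)
  key <- matrix(0L, n, n)
  for (i in seq_len(S)) {
    key[sl[i, 1], sl[i, 2]] <- i
    if (!directed) key[sl[i, 2], sl[i, 1]] <- i
  }
  P <- all_perms(n)
  cnt <- 0L
  for (pi in seq_len(nrow(P))) {
    pr <- P[pi, ]
    pm <- 0
    for (s in seq_len(S)) {
      if (floor(mask / 2^(s - 1)) %% 2 == 1) {
        pm <- pm + 2^(key[pr[sl[s, 1]], pr[sl[s, 2]]] - 1)
      }
    }
    if (pm == mask) cnt <- cnt + 1L
  }
  cnt
}

#' Enumerate small undirected graphs in atlas order
#'
#' Generates one representative per isomorphism class of undirected graphs
#' on up to `max_n` nodes by exhaustive edge-subset enumeration with bitmask
#' canonicalization, ordered and numbered in the convention of the standard
#' graph atlas: ascending node count, then ascending edge count, then
#' ascending lexicographic sorted degree sequence, then descending
#' automorphism-group order. Numbering starts at 1 for the single-node
#' graph; anchors: id 7 is the triangle, id 16 the 4-cycle, id 208 the
#' complete graph K6.
#'
#' @param max_n largest node count (2..6).
#' @param connected_only keep only connected graphs (the usual motif set;
#'   ids are still assigned within the full atlas, so gaps remain).
#' @return data.frame with columns `atlas_id`, `n`, `m`, and list-column
#'   `edges` (two-column integer matrices on nodes 1..n).
#' @examples
#' atlas_graphs(3)
#' @export
atlas_graphs <- function(max_n, connected_only = TRUE) {
  if (max_n < 2 || max_n > 6) stop("max_n must be between 2 and 6")
  rows <- list()
  next_id <- 1L
  for (n in 1:max_n) {
    sl <- edge_slots(n, directed = FALSE)
    canon <- canonical_masks(n, directed = FALSE)
    reps <- sort(unique(canon))
    info <- lapply(reps, function(mask) {
      ed <- mask_to_edges(mask, sl)
      degs <- tabulate(c(ed[, 1], ed[, 2]), nbins = n)
      list(mask = mask, edges = ed, m = nrow(ed),
           degseq = sort(degs),
           aut = mask_aut_order(mask, n, directed = FALSE),
           connected = edges_connected(ed, n))
    })
    m_vec <- vapply(info, `[[`, 0L, "m")
    deg_key <- vapply(info, function(x) {
      paste(sprintf("%02d", x$degseq), collapse = ",")
    }, "")
    aut_vec <- vapply(info, `[[`, 0L, "aut")
    ord <- order(m_vec, deg_key, -aut_vec)
    for (i in ord) {
      x <- info[[i]]
      rows[[length(rows) + 1]] <- list(atlas_id = next_id, n = n, m = x$m,
                                       edges = x$edges,
                                       connected = x$connected)
      next_id <- next_id + 1L
    }
  }
  df <- data.frame(
    atlas_id = vapply(rows, `[[`, 0L, "atlas_id"),
    n = vapply(rows, `[[`, 0L, "n"),
    m = vapply(rows, `[[`, 0L, "m"),
    connected = vapply(rows, `[[`, TRUE, "connected"))
  df$edges <- lapply(rows, `[[`, "edges")
  if (connected_only) df <- df[df$connected, , drop = FALSE]
  df$connected <- NULL
  rownames(df) <- NULL
  df
}

#' Enumerate weakly connected directed graphs up to isomorphism
#'
#' Exhaustively enumerates all 2^(n(n-1)) arc sets on n labelled nodes,
#' canonicalizes each under all n! node permutations (bitmask canonical
#' forms), and keeps one representative per class whose underlying
#' undirected graph is connected. Class counts: 2 (n=2), 13 (n=3),
#' 199 (n=4), 9364 (n=5).
#'
#' @param n node count (2..5; the 6-node enumeration exceeds desk scale).
#' @return list of two-column integer edge matrices, one per class.
#' @examples
#' length(connected_digraphs(3))
#' @export
connected_digraphs <- function(n) {
  if (n < 2 || n > 5) {
    stop("directed enumeration is supported for 2 <= n <= 5 ",
         "(the 6-node class count exceeds 1.5 million)")
  }
  sl <- edge_slots(n, directed = TRUE)
  canon <- canonical_masks(n, directed = TRUE)
  reps <- sort(unique(canon))
  out <- list()
  for (mask in reps) {
    ed <- mask_to_edges(mask, sl)
    if (nrow(ed) && edges_connected(ed, n)) out[[length(out) + 1]] <- ed
  }
  out
}

#' Build a motif from an enumerated edge matrix
#'
#' Converts an entry of [atlas_graphs()] or [connected_digraphs()] (a
#' two-column integer edge matrix on nodes 1..n) into a [motif()] with nodes
#' named M1..Mn, e.g. for export as a `.motif` file via [serialize_motif()].
#'
#' @param edges two-column integer edge matrix.
#' @param n node count (isolated trailing nodes included).
#' @param ignore_direction match edges regardless of direction (set for
#'   atlas/undirected entries).
#' @return a [motif()].
#' @export
motif_from_edges <- function(edges, n, ignore_direction = FALSE) {
  nm <- paste0("M", seq_len(n))
  motif(matrix(nm[edges], ncol = 2), nodes = nm,
        ignore_direction = ignore_direction)
}

#' Count a set of motifs in a host graph
#'
#' Runs a deduplicated monomorphism census: each motif is counted with
#' [count_matches()] (one representative per automorphism class). With
#' `ignore_direction = TRUE` motifs are matched against the symmetrized
#' host, the convention for undirected atlas censuses of a directed
#' connectome.
#'
#' @param host an igraph host graph.
#' @param motifs a motif set: the result of [atlas_graphs()], a list of
#'   edge matrices from [connected_digraphs()], or a named list of
#'   [motif()] objects.
#' @param ignore_direction match edges regardless of direction.
#' @return data.frame of class `census_result` with columns `motif_id`,
#'   `n`, `m`, `count` (motifs with no occurrence report 0, not omitted).
#' @examples
#' host <- host_graph(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
#' motif_census(host, atlas_graphs(3), ignore_direction = TRUE)
#' @export
motif_census <- function(host, motifs, ignore_direction = FALSE) {
  set <- as_motif_set(motifs, ignore_direction)
  counts <- vapply(set, function(m) count_matches(m, host, dedup = TRUE), 0L)
  out <- data.frame(
    motif_id = names(set),
    n = vapply(set, function(m) length(m$nodes), 0L),
    m = vapply(set, function(m) nrow(m$edges), 0L),
    count = counts,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("census_result", class(out))
  out
}

as_motif_set <- function(motifs, ignore_direction) {
  if (is.data.frame(motifs)) {  # atlas_graphs() output
    set <- lapply(seq_len(nrow(motifs)), function(i) {
      motif_from_edges(motifs$edges[[i]], motifs$n[i],
                       ignore_direction = TRUE)
    })
    names(set) <- as.character(motifs$atlas_id)
    return(set)
  }
  if (!is.list(motifs)) stop("unsupported motif set")
  if (length(motifs) && inherits(motifs[[1]], "motif")) {
    if (is.null(names(motifs))) names(motifs) <- paste0("motif", seq_along(motifs))
    return(motifs)
  }
  # list of integer edge matrices (directed enumeration)
  set <- lapply(motifs, function(ed) {
    motif_from_edges(ed, max(ed), ignore_direction = ignore_direction)
  })
  names(set) <- paste0("d", vapply(motifs, max, 0L), "_", seq_along(motifs))
  set
}

#' Motif census under random-graph null models
#'
#' Samples each null model repeatedly, runs [motif_census()] on every
#' sample, and summarizes the per-motif count distribution (mean, standard
#' deviation, min, max). X-swap models resample randomizations of their
#' source graph, so their single-edge counts match the host exactly.
#'
#' @param host host graph (used for motif sets that need symmetrization
#'   only; models carry their own parameters).
#' @param models named list of [model_spec()] objects.
#' @param motifs motif set as in [motif_census()].
#' @param n_samples samples per model.
#' @param seed integer; sample i of model j uses seed `seed + i` offset by
#'   the model index, so runs are reproducible.
#' @param ignore_direction forwarded to [motif_census()].
#' @return data.frame with columns model, motif_id, n, m, mean, sd, min,
#'   max, n_samples.
#' @export
null_model_census <- function(host, models, motifs, n_samples = 20,
                              seed = 1, ignore_direction = FALSE) {
  if (is.null(names(models))) {
    names(models) <- vapply(models, function(s) s$model, "")
  }
  out <- list()
  for (j in seq_along(models)) {
    per_sample <- lapply(seq_len(n_samples), function(i) {
      g <- sample_model(models[[j]], seed = seed + 7919L * (j - 1L) + i)
      motif_census(g, motifs, ignore_direction = ignore_direction)
    })
    counts <- do.call(cbind, lapply(per_sample, `[[`, "count"))
    template <- per_sample[[1]]
    out[[j]] <- data.frame(
      model = names(models)[j],
      motif_id = template$motif_id,
      n = template$n, m = template$m,
      mean = apply(counts, 1, mean),
      sd = apply(counts, 1, stats::sd),
      min = apply(counts, 1, min),
      max = apply(counts, 1, max),
      n_samples = n_samples,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
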