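#' Construct an attributed host graph
#'
#' A host graph is the network being searched: a simple graph (at most one
#' edge per ordered node pair, no self-loops unless `allow_loops = TRUE`)
#' whose nodes and edges may carry arbitrary string/numeric attributes.
#' Host graphs are plain \pkg{igraph} objects with a `name` vertex attribute;
#' every function in this package accepts any such igraph object.
#'
#' @param edges two-column character matrix or data.frame of (from, to) node
#'   identifiers; extra data.frame columns become edge attributes.
#' @param nodes optional character vector of node identifiers (to include
#'   isolated nodes); defaults to the set of edge endpoints.
#' @param directed logical; directed edges (the default, as in connectomes).
#' @param node_attrs optional data.frame with a `name` column plus one column
#'   per node attribute.
#' @param allow_loops permit self-loops (disallowed by default).
#' @return an igraph object.
#' @examples
#' g <- host_graph(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
#' graph_density(g)
#' @export
host_graph <- function(edges, nodes = NULL, directed = TRUE,
                       node_attrs = NULL, allow_loops = FALSE) {
  if (is.matrix(edges)) {
    edges <- data.frame(from = as.character(edges[, 1]),
                        to = as.character(edges[, 2]),
                        stringsAsFactors = FALSE)
  } else if (is.data.frame(edges)) {
    if (ncol(edges) < 2) stop("`edges` needs at least two columns (from, to)")
    edges[[1]] <- as.character(edges[[1]])
    edges[[2]] <- as.character(edges[[2]])
    names(edges)[1:2] <- c("from", "to")
  } else if (is.null(edges) || nrow2(edges) == 0) {
    edges <- data.frame(from = character(), to = character())
  } else {
    stop("`edges` must be a two-column matrix or a data.frame")
  }
  ids <- unique(c(edges$from, edges$to, as.character(nodes)))
  if (!is.null(node_attrs)) {
    if (!"name" %in% names(node_attrs)) {
      stop("`node_attrs` must have a `name` column")
    }
    node_attrs$name <- as.character(node_attrs$name)
    ids <- unique(c(ids, node_attrs$name))
  }
  verts <- data.frame(name = ids, stringsAsFactors = FALSE)
  if (!is.null(node_attrs)) {
    idx <- match(verts$name, node_attrs$name)
    for (col in setdiff(names(node_attrs), "name")) {
      verts[[col]] <- node_attrs[[col]][idx]
    }
  }
  g <- igraph::graph_from_data_frame(edges, directed = directed,
                                     vertices = verts)
  check_host(g, allow_loops = allow_loops)
  g
}

#' Validate host-graph invariants
#'
#' Checks that a graph is a legal host: an igraph object with named nodes,
#' no parallel edges, and (by default) no self-loops.
#'
#' @param graph an igraph object.
#' @param allow_loops permit self-loops.
#' @return the graph, invisibly; errors describe the violated invariant.
#' @export
check_host <- function(graph, allow_loops = FALSE) {
  if (!igraph::is_igraph(graph)) stop("host graph must be an igraph object")
  if (igraph::vcount(graph) > 0 && is.null(igraph::V(graph)$name)) {
    stop("host graph nodes must be named (character `name` attribute)")
  }
  if (anyDuplicated(igraph::V(graph)$name)) {
    stop("host graph node names must be unique")
  }
  if (igraph::any_multiple(graph)) {
    stop("host graph has parallel edges; at most one edge per ordered pair")
  }
  if (!allow_loops && any(igraph::which_loop(graph))) {
    stop("host graph has self-loops (set allow_loops = TRUE to permit)")
  }
  invisible(graph)
}

nrow2 <- function(x) if (is.null(dim(x))) 0L else nrow(x)

#' Graph density
#'
#' Density of a host graph. The undirected convention counts unordered
#' adjacent pairs: D = 2|E| / (|V| (|V| - 1)). The directed convention
#' counts ordered pairs: D = |E| / (|V| (|V| - 1)). For a directed graph
#' with `treat_as_undirected = TRUE`, mutual edges collapse to a single
#' adjacent pair before counting.
#'
#' @param graph an igraph host graph with at least two nodes.
#' @param treat_as_undirected use the undirected pair-counting convention.
#' @return density in [0, 1].
#' @export
graph_density <- function(graph, treat_as_undirected = !igraph::is_directed(graph)) {
  check_host(graph, allow_loops = TRUE)
  n <- igraph::vcount(graph)
  if (n < 2) stop("density is undefined for graphs with fewer than 2 nodes")
  if (treat_as_undirected) {
    u <- igraph::as_undirected(graph, mode = "collapse")
    2 * igraph::ecount(u) / (n * (n - 1))
  } else {
    if (!igraph::is_directed(graph)) {
      2 * igraph::ecount(graph) / (n * (n - 1))
    } else {
      igraph::ecount(graph) / (n * (n - 1))
    }
  }
}

#' In- and out-degree sequences
#'
#' @param graph an igraph host graph.
#' @return list with named integer vectors `in_degree` and `out_degree`
#'   (equal for undirected graphs). Both sum to |E| on directed graphs.
#' @export
degree_sequences <- function(graph) {
  check_host(graph, allow_loops = TRUE)
  list(in_degree = igraph::degree(graph, mode = "in"),
       out_degree = igraph::degree(graph, mode = "out"))
}

# Internal indexed view of a host graph used by the match engine: dense
# adjacency, edge-id lookup by ordered index pair, per-element attribute lists.
host_index <- function(graph, ignore_direction = FALSE) {
  check_host(graph, allow_loops = TRUE)
  n <- igraph::vcount(graph)
  nm <- igraph::V(graph)$name
  A <- matrix(FALSE, n, n)
  eid <- matrix(0L, n, n)
  if (igraph::ecount(graph) > 0) {
    ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
    A[ends] <- TRUE
    eid[ends] <- seq_len(nrow(ends))
    if (!igraph::is_directed(graph)) {
      A[ends[, 2:1, drop = FALSE]] <- TRUE
      eid[ends[, 2:1, drop = FALSE]] <- seq_len(nrow(ends))
    }
  }
  Asym <- A | t(A)
  vattrs <- igraph::vertex_attr(graph)
  vattrs$name <- NULL
  eattrs <- igraph::edge_attr(graph)
  list(n = n, names = nm, A = A, Asym = Asym, eid = eid,
       eid_sym = pmax(eid, t(eid)),
       vattrs = vattrs, eattrs = eattrs,
       ignore_direction = ignore_direction)
}

# Attribute of host node i (NULL if absent).
host_node_attr <- function(hx, i, attribute) {
  col <- hx$vattrs[[attribute]]
  if (is.null(col)) return(NULL)
  v <- if (is.list(col)) col[[i]] else col[i]
  if (is.null(v) || (length(v) == 1 && is.atomic(v) && is.na(v))) NULL else v
}

# Attribute of the host edge i -> j (directed lookup unless symmetric).
host_edge_attr <- function(hx, i, j, attribute, symmetric = FALSE) {
  e <- if (symmetric) hx$eid_sym[i, j] else hx$eid[i, j]
  if (e == 0L) return(NULL)
  col <- hx$eattrs[[attribute]]
  if (is.null(col)) return(NULL)
  v <- if (is.list(col)) col[[e]] else col[e]
  if (is.null(v) || (length(v) == 1 && is.atomic(v) && is.na(v))) NULL else v
}
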