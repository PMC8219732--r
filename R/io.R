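#' Read a host graph from a file
#'
#' Supported formats:
#' * `edgelist` — CSV whose first two columns are source and target node
#'   identifiers (header optional; recognized header names include
#'   source/target, from/to, pre/post); any further columns become edge
#'   attributes. Node attributes may be supplied in a sidecar CSV via
#'   `node_attrs` with a `name` column.
#' * `graphml` — GraphML with node and edge attributes preserved.
#' * `adjacency` — dense adjacency-matrix text (whitespace or comma
#'   separated); nonzero entries are edges, no attributes. Nodes are named
#'   "1".."n" unless the file has a header row of names.
#'
#' Node identifiers are always read as strings: connectome body IDs
#' routinely exceed integer range.
#'
#' @param path file to read.
#' @param format one of "auto", "edgelist", "graphml", "adjacency";
#'   "auto" guesses from the file extension.
#' @param directed build a directed graph (edgelist/adjacency).
#' @param node_attrs optional path to a node-attribute sidecar CSV.
#' @return an igraph host graph.
#' @export
read_host <- function(path, format = c("auto", "edgelist", "graphml", "adjacency"),
                      directed = TRUE, node_attrs = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     graphml = "graphml",
                     csv = "edgelist",
                     edgelist = "edgelist",
                     adj = "adjacency",
                     txt = "adjacency",
                     mat = "adjacency",
                     stop("cannot guess graph format from extension '.", ext,
                          "'; pass `format` explicitly"))
  }
  g <- switch(format,
              edgelist = read_edgelist_csv(path, directed),
              graphml = read_graphml(path),
              adjacency = read_adjacency(path, directed))
  if (!is.null(node_attrs)) {
    na <- utils::read.csv(node_attrs, stringsAsFactors = FALSE,
                          colClasses = c(name = "character"))
    if (!"name" %in% names(na)) stop("node attribute sidecar needs a `name` column")
    idx <- match(igraph::V(g)$name, na$name)
    for (col in setdiff(names(na), "name")) {
      g <- igraph::set_vertex_attr(g, col, value = na[[col]][idx])
    }
  }
  check_host(g, allow_loops = TRUE)
  g
}

HEADER_NAMES <- c("source", "target", "from", "to", "pre", "post",
                  "presynaptic", "postsynaptic")

read_edgelist_csv <- function(path, directed) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (!length(first) || !nzchar(trimws(first))) {
    stop("malformed edgelist CSV (", path, "): file is empty")
  }
  fields <- tolower(trimws(strsplit(first, ",")[[1]]))
  has_header <- length(fields) >= 2 && all(fields[1:2] %in% HEADER_NAMES)
  df <- tryCatch(
    utils::read.csv(path, header = has_header, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("malformed edgelist CSV (", path, "): ",
                             conditionMessage(e)))
  if (ncol(df) < 2) stop("malformed edgelist CSV (", path,
                         "): need at least source,target columns")
  if (!has_header) {
    names(df)[1:2] <- c("source", "target")
    if (ncol(df) > 2) names(df)[-(1:2)] <- paste0("attr", seq_len(ncol(df) - 2))
  }
  # numeric-looking attribute columns become numeric edge attributes
  for (col in names(df)[-(1:2)]) {
    v <- df[[col]]
    if (all(grepl("^\\s*[-+]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][-+]?[0-9]+)?\\s*$",
                  v) | v == "")) {
      df[[col]] <- as.numeric(v)
    }
  }
  host_graph(df, directed = directed, allow_loops = TRUE)
}

read_graphml <- function(path) {
  g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                error = function(e) stop("malformed GraphML (", path, "): ",
                                         conditionMessage(e)))
  if (is.null(igraph::V(g)$name)) {
    id <- igraph::vertex_attr(g, "id")
    igraph::V(g)$name <- if (!is.null(id)) as.character(id) else
      as.character(seq_len(igraph::vcount(g)))
  }
  g
}

read_adjacency <- function(path, directed) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  if (!length(txt)) stop("malformed adjacency matrix (", path, "): file is empty")
  sep <- if (grepl(",", txt[1], fixed = TRUE)) "," else ""
  parse_row <- function(ln) {
    parts <- if (sep == ",") trimws(strsplit(ln, ",")[[1]]) else
      strsplit(trimws(ln), "\\s+")[[1]]
    parts[nzchar(parts)]
  }
  rows <- lapply(txt, parse_row)
  names_row <- suppressWarnings(any(is.na(as.numeric(rows[[1]]))))
  node_names <- NULL
  if (names_row) {
    node_names <- rows[[1]]
    rows <- rows[-1]
  }
  M <- do.call(rbind, lapply(seq_along(rows), function(i) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(v)) stop("malformed adjacency matrix (", path, "): line ",
                       i + names_row, " contains a non-numeric entry")
    v
  }))
  if (nrow(M) != ncol(M)) {
    stop("malformed adjacency matrix (", path, "): ", nrow(M), " rows x ",
         ncol(M), " columns")
  }
  if (is.null(node_names)) node_names <- as.character(seq_len(nrow(M)))
  ed <- which(M != 0, arr.ind = TRUE)
  if (!directed) ed <- ed[ed[, 1] <= ed[, 2], , drop = FALSE]
  host_graph(matrix(node_names[ed], ncol = 2), nodes = node_names,
             directed = directed, allow_loops = TRUE)
}

#' Write a host graph to a file
#'
#' Deterministic (stable edge ordering) counterparts of [read_host()].
#' GraphML preserves node and edge attributes; the edgelist CSV carries edge
#' attributes as extra columns and node attributes in an optional sidecar;
#' adjacency output is structure-only.
#'
#' @param graph host graph.
#' @param path output file.
#' @param format "edgelist", "graphml", or "adjacency".
#' @param node_attrs optional sidecar CSV path for node attributes
#'   (edgelist format only).
#' @return `path`, invisibly.
#' @export
write_host <- function(graph, path,
                       format = c("edgelist", "graphml", "adjacency"),
                       node_attrs = NULL) {
  format <- match.arg(format)
  check_host(graph, allow_loops = TRUE)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else if (format == "edgelist") {
    el <- igraph::as_data_frame(graph, what = "edges")
    el <- el[order(el$from, el$to), , drop = FALSE]
    names(el)[1:2] <- c("source", "target")
    utils::write.csv(el, path, row.names = FALSE, quote = FALSE)
    if (!is.null(node_attrs)) {
      nv <- igraph::as_data_frame(graph, what = "vertices")
      nv <- nv[order(nv$name), , drop = FALSE]
      utils::write.csv(nv, node_attrs, row.names = FALSE, quote = FALSE)
    }
  } else {
    M <- as.matrix(igraph::as_adjacency_matrix(graph))
    utils::write.table(M, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Specify a synthetic attributed fixture graph
#'
#' Describes a connectome-like test graph: an Erdős–Rényi directed
#' background at a given density over nodes carrying cell-type and radius
#' attributes, with edges carrying neurotransmitter-type and weight
#' attributes, plus an optional list of planted motifs. Planted motifs are
#' embedded on disjoint fresh nodes (no background edges touch them), so
#' their stated multiplicities are guaranteed minimum counts.
#'
#' @param n background node count.
#' @param density background edge density (directed convention).
#' @param cell_types categorical node attribute values for `cell_type`.
#' @param edge_types categorical edge attribute values for `type`.
#' @param planted list of `list(motif = <motif>, times = <int>)` entries.
#' @param seed integer seed.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n, density, cell_types = c("pyramidal", "basket",
                                                    "martinotti"),
                         edge_types = c("GABA", "glutamate", "acetylcholine"),
                         planted = list(), seed = 1) {
  if (n < 0 || density < 0 || density > 1) stop("invalid fixture spec")
  for (p in planted) {
    if (!inherits(p$motif, "motif") || is.null(p$times) || p$times < 1) {
      stop("planted entries must be list(motif = <motif>, times = <count>)")
    }
  }
  if (n < 2 && density > 0) {
    stop("density infeasible: a positive background density needs n >= 2")
  }
  structure(list(n = as.integer(n), density = density,
                 cell_types = cell_types, edge_types = edge_types,
                 planted = planted, seed = seed),
            class = "fixture_spec")
}

#' Generate a synthetic attributed host graph
#'
#' Seed-deterministic realization of a [fixture_spec()]: background nodes
#' "n1".."nN" with directed Erdős–Rényi edges at the stated density, node
#' attributes `cell_type` (categorical) and `radius` (lognormal, positive),
#' edge attributes `type` (categorical) and `weight` (positive). Planted
#' motifs get fresh nodes "p<i>_<name>"; their edge/node attributes are
#' chosen to satisfy the motif's equality and bound constraints.
#'
#' @param spec a [fixture_spec()].
#' @return an igraph host graph.
#' @examples
#' g <- generate_fixture(fixture_spec(n = 30, density = 0.05, seed = 7))
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, function() {
    nodes <- if (spec$n) paste0("n", seq_len(spec$n)) else character()
    edges <- matrix(character(), 0, 2)
    if (spec$n >= 2 && spec$density > 0) {
      pairs <- which(!diag(spec$n) > 0, arr.ind = TRUE)
      on <- stats::runif(nrow(pairs)) < spec$density
      edges <- matrix(nodes[pairs[on, , drop = FALSE]], ncol = 2)
    }
    planted_nodes <- character()
    for (i in seq_along(spec$planted)) {
      p <- spec$planted[[i]]
      for (rep in seq_len(p$times)) {
        rename <- stats::setNames(
          paste0("p", i, "r", rep, "_", p$motif$nodes), p$motif$nodes)
        planted_nodes <- c(planted_nodes, unname(rename))
        if (nrow(p$motif$edges)) {
          edges <- rbind(edges, matrix(rename[p$motif$edges], ncol = 2))
        }
      }
    }
    all_nodes <- c(nodes, planted_nodes)
    g <- host_graph(edges, nodes = all_nodes)
    nv <- igraph::vcount(g)
    g <- igraph::set_vertex_attr(g, "cell_type",
                                 value = sample(spec$cell_types, nv, TRUE))
    g <- igraph::set_vertex_attr(g, "radius",
                                 value = round(stats::rlnorm(nv, log(8), 0.5), 3))
    ne <- igraph::ecount(g)
    if (ne) {
      g <- igraph::set_edge_attr(g, "type",
                                 value = sample(spec$edge_types, ne, TRUE))
      g <- igraph::set_edge_attr(g, "weight",
                                 value = round(stats::rlnorm(ne, log(5), 0.8), 3))
    }
    # overwrite attributes on planted elements so their constraints hold
    for (i in seq_along(spec$planted)) {
      p <- spec$planted[[i]]
      for (rep in seq_len(p$times)) {
        prefix <- paste0("p", i, "r", rep, "_")
        for (cst in p$motif$node_constraints) {
          if (!is.null(cst$rhs_ref)) next
          v <- satisfying_value(cst)
          if (is.null(v)) next
          g <- igraph::set_vertex_attr(g, cst$attribute,
                                       index = paste0(prefix, cst$subject),
                                       value = v)
        }
        for (key in names(p$motif$edge_constraints)) {
          ft <- paste0(prefix, strsplit(key, "->", fixed = TRUE)[[1]])
          eid <- igraph::get_edge_ids(g, ft)
          if (eid == 0) next
          for (cst in p$motif$edge_constraints[[key]]) {
            if (!is.null(cst$rhs_ref)) next
            v <- satisfying_value(cst)
            if (!is.null(v)) g <- igraph::set_edge_attr(g, cst$attribute,
                                                        index = eid, value = v)
          }
        }
      }
    }
    g
  })
}

# A concrete value satisfying a single literal constraint (NULL if the
# operator does not pin one down usefully).
satisfying_value <- function(cst) {
  switch(cst$op,
         "=" = if (!is.list(cst$rhs)) cst$rhs,
         ">=" = cst$rhs,
         "<=" = cst$rhs,
         ">" = if (is.numeric(cst$rhs)) cst$rhs + 1,
         "<" = if (is.numeric(cst$rhs)) cst$rhs - 1,
         "in" = cst$rhs[[1]],
         NULL)
}
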