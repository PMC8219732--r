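#' Specify a random-graph null model
#'
#' Null models used to contextualize motif counts: a motif is interesting
#' when its observed frequency departs from its expected frequency under a
#' random model calibrated to the connectome. Five models are supported:
#'
#' * `"er"` — Erdős–Rényi G(n, p): each pair connected independently with
#'   probability `p` (`directed = TRUE` samples each ordered pair).
#' * `"geometric"` — random geometric graph: nodes uniform in the unit
#'   square, edge iff Euclidean distance ≤ `r`.
#' * `"watts_strogatz"` — ring lattice of `k` nearest neighbours, each edge
#'   rewired with probability `rewire`.
#' * `"barabasi_albert"` — preferential attachment adding `m` edges per new
#'   node (power-law degree distribution).
#' * `"xswap"` — degree-preserving randomization of a `source` graph by
#'   repeated edge swaps (see [xswap_randomize()]).
#'
#' @param model one of "er", "geometric", "watts_strogatz",
#'   "barabasi_albert", "xswap".
#' @param n node count (ignored for "xswap", which takes it from `source`).
#' @param p edge probability (er).
#' @param r connection radius (geometric).
#' @param k even lattice degree (watts_strogatz).
#' @param rewire rewiring probability (watts_strogatz; default 0.1).
#' @param m edges added per new node (barabasi_albert).
#' @param source source host graph (xswap).
#' @param n_swaps accepted swaps (xswap; default 10 |E|).
#' @param directed sample each ordered pair independently (er only).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(model = c("er", "geometric", "watts_strogatz",
                                 "barabasi_albert", "xswap"),
                       n = NULL, p = NULL, r = NULL, k = NULL, rewire = NULL,
                       m = NULL, source = NULL, n_swaps = NULL,
                       directed = NULL) {
  model <- match.arg(model)
  params <- list(p = p, r = r, k = k, rewire = rewire, m = m,
                 source = source, n_swaps = n_swaps, directed = directed)
  params <- params[!vapply(params, is.null, logical(1))]
  if (model == "xswap") {
    if (is.null(params$source)) stop("xswap model needs a `source` graph")
    n <- igraph::vcount(params$source)
  } else {
    if (is.null(n) || n < 1) stop("model needs a node count n >= 1")
  }
  if (model == "er") {
    p <- params$p
    if (is.null(p) || p < 0 || p > 1) stop("er model needs 0 <= p <= 1")
  }
  if (model == "geometric") {
    if (is.null(params$r) || params$r < 0) stop("geometric model needs r >= 0")
  }
  if (model == "watts_strogatz") {
    k <- params$k
    if (is.null(k) || k %% 2 != 0 || k < 2 || k >= n) {
      stop("watts_strogatz model needs an even k with 2 <= k < n")
    }
    if (is.null(params$rewire)) params$rewire <- 0.1
    if (params$rewire < 0 || params$rewire > 1) stop("rewire probability must be in [0,1]")
  }
  if (model == "barabasi_albert") {
    m <- params$m
    if (is.null(m) || m < 1 || m >= n) stop("barabasi_albert model needs 1 <= m < n")
  }
  structure(list(model = model, n = as.integer(n), params = params),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  shown <- x$params[setdiff(names(x$params), "source")]
  cat("Random graph model:", x$model, " n =", x$n, "\n")
  if (length(shown)) {
    cat(" ", paste(names(shown), unlist(lapply(shown, format)),
                   sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

# Run fn under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, fn) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  fn()
}

#' Sample a graph from a null model
#'
#' Seed-deterministic: the same spec and seed always return the identical
#' edge set. Nodes are named "n1".."nN" ("xswap" keeps the source names).
#'
#' @param spec a [model_spec()].
#' @param seed integer seed (NULL uses the current RNG stream).
#' @return an igraph host graph.
#' @examples
#' g <- sample_model(model_spec("er", n = 20, p = 0.2), seed = 1)
#' @export
sample_model <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  with_seed(seed, function() {
    g <- switch(spec$model,
      er = igraph::sample_gnp(spec$n, spec$params$p,
                              directed = isTRUE(spec$params$directed)),
      geometric = igraph::sample_grg(spec$n, spec$params$r),
      watts_strogatz = igraph::simplify(igraph::sample_smallworld(
        1, spec$n, spec$params$k / 2, spec$params$rewire)),
      barabasi_albert = igraph::sample_pa(spec$n, m = spec$params$m,
                                          directed = FALSE),
      xswap = return(xswap_randomize(spec$params$source,
                                     n_swaps = spec$params$n_swaps)))
    igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
    g
  })
}

#' Calibrate a null model to a target density
#'
#' Chooses model parameters so that sampled graphs match a target graph
#' density D = 2|E| / (|V| (|V| - 1)), the calibration characteristic used
#' when comparing motif counts across connectomes and models:
#'
#' * er: `p = target_density` exactly (density in expectation).
#' * geometric: radius `r` found by bisection on a Monte-Carlo estimate of
#'   expected density (tolerance ±0.005).
#' * watts_strogatz: `k` is the nearest valid even integer to
#'   `target_density * (n - 1)`; density is fixed by `k`, so the rewiring
#'   probability remains a free parameter (`rewire`, default 0.1) to be
#'   swept.
#' * barabasi_albert: `m = round(target_density * (n - 1) / 2)`; closest
#'   achievable density.
#'
#' @param model model name (see [model_spec()]); "xswap" needs no
#'   calibration (it inherits the source graph's density exactly).
#' @param n node count.
#' @param target_density desired density in (0, 1).
#' @param ... extra parameters passed through (e.g. `rewire`, `directed`).
#' @param mc_samples Monte-Carlo replicates per bisection step (geometric).
#' @param seed seed for the Monte-Carlo calibration.
#' @return a calibrated [model_spec()].
#' @examples
#' calibrate_model("er", n = 296, target_density = 0.06)$params$p
#' @export
calibrate_model <- function(model, n, target_density, ...,
                            mc_samples = 20, seed = 1) {
  if (target_density <= 0 || target_density >= 1) {
    stop("target density must lie strictly between 0 and 1")
  }
  extra <- list(...)
  if (model == "er") {
    return(do.call(model_spec, c(list("er", n = n, p = target_density), extra)))
  }
  if (model == "geometric") {
    est <- function(r) {
      if (r <= 0) return(0)
      with_seed(seed, function() {
        mean(vapply(seq_len(mc_samples), function(i) {
          x <- stats::runif(n); y <- stats::runif(n)
          d2 <- (outer(x, x, "-"))^2 + (outer(y, y, "-"))^2
          sum(d2[upper.tri(d2)] <= r^2) / choose(n, 2)
        }, 0))
      })
    }
    lo <- 0; hi <- sqrt(2)
    if (est(hi) < target_density) {
      stop("calibration error: geometric model cannot reach density ",
           target_density)
    }
    repeat {
      mid <- (lo + hi) / 2
      d <- est(mid)
      if (abs(d - target_density) <= 0.005 || (hi - lo) < 1e-6) break
      if (d < target_density) lo <- mid else hi <- mid
    }
    return(do.call(model_spec, c(list("geometric", n = n, r = mid), extra)))
  }
  if (model == "watts_strogatz") {
    k <- max(2, 2 * round(target_density * (n - 1) / 2))
    if (k >= n) {
      stop("calibration error: watts_strogatz needs k < n; achievable density < ",
           round((n - 2) / (n - 1), 3))
    }
    return(do.call(model_spec, c(list("watts_strogatz", n = n, k = k), extra)))
  }
  if (model == "barabasi_albert") {
    m <- round(target_density * (n - 1) / 2)
    if (m < 1) {
      stop("calibration error: barabasi_albert needs m >= 1; minimum achievable ",
           "density at this n is about ", round(2 / (n - 1), 4))
    }
    return(do.call(model_spec, c(list("barabasi_albert", n = n, m = m), extra)))
  }
  if (model == "xswap") {
    stop("xswap inherits density from its source graph; no calibration needed")
  }
  stop("unknown model: ", model)
}

#' Degree-preserving X-swap randomization
#'
#' Repeatedly picks two random edges \{u1, v1\} and \{u2, v2\} and rewires
#' them to \{u1, v2\} and \{u2, v1\}. Every node's in-degree and out-degree
#' are exactly preserved, so single-edge motif counts are invariant while
#' higher-order structure randomizes. Proposed swaps that would introduce a
#' self-loop or duplicate edge are rejected and resampled; a graph with no
#' valid swap is returned unchanged.
#'
#' @param graph host graph (directed or undirected).
#' @param n_swaps accepted swaps to perform (default 10 |E|, a common
#'   mixing heuristic).
#' @param seed integer seed.
#' @param max_tries attempt budget before giving up on reaching `n_swaps`.
#' @return randomized graph with identical degree sequences; node
#'   attributes are preserved, edge attributes are dropped (edges lose
#'   their identity under swapping).
#' @export
xswap_randomize <- function(graph, n_swaps = NULL,
                            seed = NULL, max_tries = NULL) {
  check_host(graph)
  ne <- igraph::ecount(graph)
  if (is.null(n_swaps)) n_swaps <- 10L * ne
  if (n_swaps < 0) stop("n_swaps must be >= 0")
  if (ne < 2 || n_swaps == 0) return(graph)
  if (is.null(max_tries)) max_tries <- 100L * n_swaps + 1000L
  directed <- igraph::is_directed(graph)
  n <- igraph::vcount(graph)
  el <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  A <- matrix(FALSE, n, n)
  A[el] <- TRUE
  if (!directed) A[el[, 2:1, drop = FALSE]] <- TRUE

  with_seed(seed, function() {
    accepted <- 0L
    tries <- 0L
    while (accepted < n_swaps && tries < max_tries) {
      tries <- tries + 1L
      ij <- sample.int(ne, 2)
      u1 <- el[ij[1], 1]; v1 <- el[ij[1], 2]
      u2 <- el[ij[2], 1]; v2 <- el[ij[2], 2]
      if (u1 == v2 || u2 == v1) next            # self-loop
      if (A[u1, v2] || A[u2, v1]) next          # duplicate edge
      A[u1, v1] <<- FALSE; A[u2, v2] <<- FALSE
      A[u1, v2] <<- TRUE;  A[u2, v1] <<- TRUE
      if (!directed) {
        A[v1, u1] <<- FALSE; A[v2, u2] <<- FALSE
        A[v2, u1] <<- TRUE;  A[v1, u2] <<- TRUE
      }
      el[ij[1], 2] <<- v2
      el[ij[2], 2] <<- v1
      accepted <- accepted + 1L
    }
    nm <- igraph::V(graph)$name
    out <- igraph::graph_from_edgelist(
      matrix(nm[el], ncol = 2), directed = directed)
    missing <- setdiff(nm, igraph::V(out)$name)
    if (length(missing)) out <- igraph::add_vertices(out, length(missing),
                                                     name = missing)
    out <- igraph::permute(out, match(igraph::V(out)$name, nm))
    for (attr in setdiff(names(igraph::vertex_attr(graph)), "name")) {
      out <- igraph::set_vertex_attr(out, attr,
                                     value = igraph::vertex_attr(graph, attr))
    }
    out
  })
}
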