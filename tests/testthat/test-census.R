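test_that("atlas enumeration hits its anchors and class counts", {
  at <- atlas_graphs(4)
  expect_equal(sum(at$n == 3), 2)
  expect_equal(sum(at$n == 4), 6)

  tri <- at[at$atlas_id == 7, ]
  expect_equal(tri$n, 3)
  expect_equal(tri$m, 3)

  rect <- at[at$atlas_id == 16, ]
  expect_equal(rect$n, 4)
  expect_equal(rect$m, 4)
  degs <- tabulate(c(rect$edges[[1]]), nbins = 4)
  expect_equal(sort(degs), c(2, 2, 2, 2))  # the 4-cycle, not the paw

  expect_error(atlas_graphs(7), "between 2 and 6")
  expect_error(atlas_graphs(1), "between 2 and 6")

  # entries are pairwise non-isomorphic (independent igraph oracle)
  gs <- lapply(seq_len(nrow(at)), function(i) {
    igraph::graph_from_edgelist(at$edges[[i]], directed = FALSE) |>
      (\(g) igraph::add_vertices(g, at$n[i] - igraph::vcount(g)))()
  })
  for (i in seq_along(gs)) {
    for (j in seq_along(gs)) {
      if (i < j && at$n[i] == at$n[j]) {
        expect_false(igraph::isomorphic(gs[[i]], gs[[j]]))
      }
    }
  }
})

test_that("directed enumeration matches printed class counts for small n", {
  expect_length(connected_digraphs(2), 2)   # single arc; mutual pair
  d3 <- connected_digraphs(3)
  expect_length(d3, 13)
  expect_error(connected_digraphs(6), "2 <= n <= 5")

  # pairwise non-isomorphic by the igraph oracle
  gs <- lapply(d3, function(ed) {
    g <- igraph::graph_from_edgelist(ed, directed = TRUE)
    igraph::add_vertices(g, 3 - igraph::vcount(g))
  })
  for (i in 1:12) {
    for (j in (i + 1):13) {
      expect_false(igraph::isomorphic(gs[[i]], gs[[j]], method = "vf2"))
    }
  }
})

test_that("census counts the planted structure and nothing else", {
  cyc <- host_graph(rbind(c("x", "y"), c("y", "z"), c("z", "x")))
  cen <- motif_census(cyc, atlas_graphs(3), ignore_direction = TRUE)
  expect_equal(cen$count[cen$motif_id == "7"], 1)   # one triangle
  expect_equal(cen$count[cen$motif_id == "6"], 3)   # three 2-paths
  expect_true(all(c("1", "3", "6", "7") %in% cen$motif_id))

  # fan-out host: exactly one directed 3-node class occurs
  fan <- host_graph(rbind(c("hub", "a"), c("hub", "b")))
  dcen <- motif_census(fan, connected_digraphs(3))
  expect_equal(sum(dcen$count > 0), 1)
  expect_equal(sum(dcen$count), 1)
  hit <- dcen[dcen$count > 0, ]
  expect_equal(hit$m, 2)
})

test_that("triangle census equals the closed-form triple-count oracle", {
  tri_via_triples <- function(host) {
    A <- as.matrix(igraph::as_adjacency_matrix(host)) > 0
    A <- A | t(A)
    n <- nrow(A)
    cnt <- 0L
    for (a in seq_len(n - 2)) {
      for (b in seq.int(a + 1, n - 1)) {
        if (!A[a, b]) next
        for (c in seq.int(b + 1, n)) {
          if (A[a, c] && A[b, c]) cnt <- cnt + 1L
        }
      }
    }
    cnt
  }
  for (s in 1:4) {
    host <- sample_model(model_spec("er", n = 30, p = 0.2, directed = TRUE),
                         seed = 60 + s)
    cen <- motif_census(host, atlas_graphs(3), ignore_direction = TRUE)
    expect_equal(cen$count[cen$motif_id == "7"], tri_via_triples(host))
  }
})

test_that("census is invariant under relabeling and edge reversal", {
  host <- sample_model(model_spec("er", n = 20, p = 0.15, directed = TRUE),
                       seed = 77)
  cen <- motif_census(host, atlas_graphs(4), ignore_direction = TRUE)

  set.seed(1)
  relabeled <- igraph::permute(host, sample(igraph::vcount(host)))
  expect_equal(motif_census(relabeled, atlas_graphs(4),
                            ignore_direction = TRUE)$count, cen$count)

  reversed <- igraph::reverse_edges(host)
  expect_equal(motif_census(reversed, atlas_graphs(4),
                            ignore_direction = TRUE)$count, cen$count)
})

test_that("null-model census summarizes count distributions", {
  host <- sample_model(model_spec("er", n = 25, p = 0.12, directed = TRUE),
                       seed = 5)
  edge_motif <- list(edge = parse_motif("A -> B"))
  models <- list(
    xswap = model_spec("xswap", source = host),
    er0 = model_spec("er", n = 25, p = 0, directed = TRUE))
  res <- null_model_census(host, models, edge_motif, n_samples = 5, seed = 2)

  # degree preservation: single-edge count invariant under X-swap
  xs <- res[res$model == "xswap", ]
  expect_equal(xs$mean, igraph::ecount(host))
  expect_equal(xs$sd, 0)
  # empty model: all counts zero
  expect_equal(res[res$model == "er0", ]$max, 0)
})

test_that("clustered null models beat ER on triangles (census-level)", {
  tri_set <- atlas_graphs(3)
  tri_set <- tri_set[tri_set$atlas_id == 7, ]
  models <- list(
    ws = model_spec("watts_strogatz", n = 40, k = 4, rewire = 0.05),
    er = calibrate_model("er", n = 40, target_density = 4 / 39))
  res <- null_model_census(NULL, models, tri_set, n_samples = 20, seed = 3,
                           ignore_direction = TRUE)
  expect_gt(res$mean[res$model == "ws"], res$mean[res$model == "er"])
})
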