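test_that("model boundary cases sample as expected", {
  expect_equal(igraph::ecount(sample_model(model_spec("er", n = 10, p = 0), 1)), 0)
  g1 <- sample_model(model_spec("er", n = 10, p = 1), 1)
  expect_equal(graph_density(g1), 1.0)
  gg <- sample_model(model_spec("geometric", n = 50, r = sqrt(2)), 1)
  expect_equal(graph_density(gg), 1.0)  # max distance in the unit square
  expect_error(model_spec("er", n = 10, p = 1.5), "p")
  expect_error(model_spec("watts_strogatz", n = 10, k = 3), "even")
  expect_error(model_spec("barabasi_albert", n = 10, m = 0), "m")
})

test_that("samplers are seed-deterministic", {
  specs <- list(model_spec("er", n = 30, p = 0.2, directed = TRUE),
                model_spec("geometric", n = 30, r = 0.3),
                model_spec("watts_strogatz", n = 30, k = 4, rewire = 0.2),
                model_spec("barabasi_albert", n = 30, m = 2))
  for (spec in specs) {
    a <- sample_model(spec, seed = 99)
    b <- sample_model(spec, seed = 99)
    expect_identical(igraph::as_edgelist(a), igraph::as_edgelist(b))
    c <- sample_model(spec, seed = 100)
    expect_false(identical(igraph::as_edgelist(a), igraph::as_edgelist(c)))
  }
  src <- sample_model(model_spec("er", n = 40, p = 0.1, directed = TRUE), 3)
  expect_identical(igraph::as_edgelist(xswap_randomize(src, seed = 7)),
                   igraph::as_edgelist(xswap_randomize(src, seed = 7)))
})

test_that("ER sampled density matches p within binomial sampling error", {
  n <- 200; p <- 0.06; reps <- 50
  dens <- vapply(seq_len(reps), function(s) {
    graph_density(sample_model(model_spec("er", n = n, p = p), seed = s))
  }, 0)
  se <- sqrt(p * (1 - p) / (choose(n, 2) * reps))
  expect_lt(abs(mean(dens) - p), 3 * se)
})

test_that("density calibration hits its targets", {
  expect_equal(calibrate_model("er", 296, 0.06)$params$p, 0.06)
  expect_equal(calibrate_model("er", 334, 0.03)$params$p, 0.03)

  spec <- calibrate_model("geometric", n = 80, target_density = 0.15,
                          mc_samples = 10)
  dens <- mean(vapply(1:20, function(s) graph_density(sample_model(spec, s)), 0))
  expect_lt(abs(dens - 0.15) / 0.15, 0.10)

  spec <- calibrate_model("watts_strogatz", n = 100, target_density = 0.06)
  expect_equal(spec$params$k, 6)
  dens <- mean(vapply(1:20, function(s) graph_density(sample_model(spec, s)), 0))
  expect_lt(abs(dens - 0.06) / 0.06, 0.10)

  spec <- calibrate_model("barabasi_albert", n = 100, target_density = 0.06)
  expect_equal(spec$params$m, 3)

  expect_error(calibrate_model("barabasi_albert", n = 100,
                               target_density = 0.001), "calibration error")
  expect_error(calibrate_model("er", 100, 0), "between 0 and 1")
})

test_that("X-swap implements the published swap rule", {
  # single edge: no second edge to swap with
  one <- host_graph(rbind(c("a", "b")))
  expect_identical(igraph::as_edgelist(xswap_randomize(one, seed = 1)),
                   igraph::as_edgelist(one))

  # two disjoint edges admit exactly one swap: {u1,v1},{u2,v2} -> {u1,v2},{u2,v1}
  two <- host_graph(rbind(c("u1", "v1"), c("u2", "v2")))
  swapped <- xswap_randomize(two, n_swaps = 1, seed = 5)
  got <- igraph::as_edgelist(swapped)
  got <- got[order(got[, 1]), ]
  expect_equal(got, rbind(c("u1", "v2"), c("u2", "v1")))
})

test_that("X-swap preserves per-node in/out-degrees exactly", {
  for (s in 1:5) {
    src <- sample_model(model_spec("er", n = 100, p = 0.05, directed = TRUE),
                        seed = 40 + s)
    sw <- xswap_randomize(src, n_swaps = 10 * igraph::ecount(src), seed = s)
    expect_identical(degree_sequences(sw), degree_sequences(src))
    expect_equal(igraph::ecount(sw), igraph::ecount(src))
    expect_false(any(igraph::which_loop(sw)))
    expect_false(igraph::any_multiple(sw))
  }
})

test_that("density-matched ER under-predicts triangles in clustered graphs", {
  # low-rewire Watts-Strogatz fixture vs ER at the same density
  ws_spec <- model_spec("watts_strogatz", n = 60, k = 6, rewire = 0.05)
  fixture <- sample_model(ws_spec, seed = 8)
  d <- graph_density(fixture)
  er_spec <- calibrate_model("er", n = 60, target_density = d)
  tri <- parse_motif("A -> B\nB -> C\nC -> A", ignore_direction = TRUE)
  fix_count <- count_matches(tri, fixture)
  er_counts <- vapply(1:20, function(s) {
    count_matches(tri, sample_model(er_spec, seed = 100 + s))
  }, 0L)
  expect_lt(mean(er_counts), fix_count)
})
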