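cycle3 <- function() host_graph(rbind(c("x", "y"), c("y", "z"), c("z", "x")))

test_that("worked examples match their hand counts", {
  host <- cycle3()
  expect_equal(count_matches(parse_motif("A -> B"), host), 3)

  # path: every 3-node induced subgraph of the cycle has the closing edge
  path <- parse_motif("A -> B\nB -> C")
  expect_equal(count_matches(path, host, mode = "monomorphism"), 3)
  expect_equal(count_matches(path, host, mode = "isomorphism"), 0)

  # pigeonhole: motif larger than host
  quad <- parse_motif("A -> B\nB -> C\nC -> D")
  expect_equal(nrow(find_matches(quad, host)), 0)

  # single satisfying edge under an edge constraint
  h <- host_graph(data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"),
                             weight = c(12, 1, 1)))
  res <- find_matches(parse_motif("A -> B [weight >= 10]"), h)
  expect_equal(nrow(res), 1)
  expect_equal(unname(res[1, ]), c("a", "b"))

  # forbidden edge is a hard non-edge requirement in both modes
  m <- parse_motif("A -> B\nB !> A")
  h2 <- host_graph(rbind(c("u", "v"), c("v", "u"), c("u", "w")))
  for (mode in c("monomorphism", "isomorphism")) {
    res <- find_matches(m, h2, mode = mode)
    expect_equal(unname(res), cbind("u", "w"))
  }
})

test_that("single-node constrained motif counts satisfying hosts", {
  m <- motif(NULL, nodes = "A",
             node_constraints = list(constraint("A", "weight", ">", 5)))
  h <- host_graph(rbind(c("a", "b")), nodes = c("a", "b", "c"))
  igraph::V(h)$weight <- c(10, 2, 7)
  expect_equal(count_matches(m, h), 2)
  m_all <- motif(NULL, nodes = "A",
                 node_constraints = list(constraint("A", "weight", ">=", 0)))
  expect_equal(count_matches(m_all, h), igraph::vcount(h))
  expect_equal(count_matches(m, host_graph(NULL, nodes = character())), 0)
})

test_that("extend_mapping generates exactly the consistent children", {
  host <- cycle3()
  m <- parse_motif("A -> B")
  kids <- extend_mapping(character(), m, host)
  expect_length(kids, 3)  # unconstrained first node: every host node

  # next node needs an out-edge from an assigned node that has none left
  h <- host_graph(rbind(c("a", "b")), nodes = c("a", "b", "c"))
  m2 <- parse_motif("A -> B\nB -> C")
  kids <- extend_mapping(c(A = "a", B = "b"), m2, h)
  expect_length(kids, 0)  # b has out-degree 0

  # children equal the filter-by-definition oracle on random instances
  for (s in 1:15) {
    host <- random_host(8, seed = 400 + s)
    m <- random_motif(seed = 500 + s)
    first <- m$nodes[1]
    kids <- extend_mapping(character(), m, host)
    got <- sort(vapply(kids, `[[`, "", first))
    single <- motif(NULL, nodes = first,
                    node_constraints = Filter(
                      function(cst) cst$subject == first && is.null(cst$rhs_ref),
                      m$node_constraints))
    want <- sort(find_matches(single, host, dedup = FALSE)[, 1])
    expect_equal(got, want, info = paste("seed", s))
  }
})

test_that("queue search equals the brute-force oracle (randomized)", {
  for (s in 1:60) {
    host <- random_host(sample(6:11, 1), seed = 1200 + s)
    m <- random_motif(seed = 1300 + s)
    for (mode in c("monomorphism", "isomorphism")) {
      expect_identical(find_matches(m, host, mode = mode, dedup = FALSE),
                       oracle_matches(m, host, mode = mode),
                       info = paste("seed", s, mode))
    }
  }
})

test_that("isomorphism results are a subset of monomorphism results", {
  for (s in 1:15) {
    host <- random_host(9, seed = 1500 + s)
    m <- random_motif(seed = 1600 + s)
    mono <- apply(find_matches(m, host, mode = "monomorphism", dedup = FALSE),
                  1, paste, collapse = ",")
    iso <- apply(find_matches(m, host, mode = "isomorphism", dedup = FALSE),
                 1, paste, collapse = ",")
    expect_true(all(iso %in% mono))
  }
})

test_that("adding a constraint never increases the match count", {
  for (s in 1:15) {
    host <- random_host(9, seed = 1700 + s)
    m <- random_motif(seed = 1800 + s, constrained = FALSE)
    base <- count_matches(m, host, dedup = FALSE)
    m$node_constraints <- list(constraint(m$nodes[1], "weight", ">", 8))
    expect_lte(count_matches(m, host, dedup = FALSE), base)
  }
})

test_that("results are invariant under host relabeling and queue discipline", {
  for (s in 1:10) {
    host <- random_host(8, seed = 1900 + s)
    m <- random_motif(seed = 2000 + s)
    fifo <- find_matches(m, host, dedup = FALSE, queue = "fifo")
    lifo <- find_matches(m, host, dedup = FALSE, queue = "lifo")
    expect_identical(fifo, lifo)

    set.seed(s)
    perm <- sample(igraph::vcount(host))
    relabeled <- igraph::permute(host, perm)
    r2 <- find_matches(m, relabeled, dedup = FALSE)
    expect_identical(fifo, r2)  # same names, rows sorted either way

    # dedup counts are label-invariant even though representatives may differ
    expect_equal(count_matches(m, host, dedup = TRUE),
                 count_matches(m, relabeled, dedup = TRUE))
  }
})

test_that("motif node renaming only renames output columns", {
  host <- random_host(8, seed = 42)
  m <- parse_motif("A -> B\nB -> C\nA.weight > 3")
  ren <- parse_motif("P -> Q\nQ -> R\nP.weight > 3")
  a <- find_matches(m, host, dedup = FALSE)
  b <- find_matches(ren, host, dedup = FALSE)
  expect_equal(unname(a), unname(b))
  expect_equal(colnames(b), c("P", "Q", "R"))
})
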