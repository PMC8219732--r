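test_that("constraint simplification keeps the tightest bounds", {
  m <- parse_motif("A -> B\nA.size > 5\nA.size > 3")
  s <- simplify_constraints(m)
  expect_length(s$node_constraints, 1)
  expect_equal(s$node_constraints[[1]]$rhs, 5)

  m <- parse_motif("A -> B\nA.size = 7")
  expect_true(motif_identical(m, simplify_constraints(m)))

  m <- parse_motif("A -> B [weight > 1, weight > 4, weight <= 9, weight <= 12]")
  s <- simplify_constraints(m)
  expect_length(s$edge_constraints[["A->B"]], 2)
  rhs <- sort(vapply(s$edge_constraints[["A->B"]], function(cst) cst$rhs, 0))
  expect_equal(rhs, c(4, 9))
})

test_that("simplification never changes the match set (oracle property)", {
  for (s in 1:25) {
    m <- random_motif(seed = 7000 + s)
    host <- random_host(9, seed = 7100 + s)
    s1 <- find_matches(m, host, dedup = FALSE)
    s2 <- find_matches(simplify_constraints(m), host, dedup = FALSE)
    expect_identical(s1, s2)
  }
  # including genuinely redundant bound pairs
  m <- parse_motif("A -> B\nA.weight > 5\nA.weight > 3\nA.weight <= 15")
  host <- random_host(10, seed = 77)
  expect_identical(find_matches(simplify_constraints(m), host, dedup = FALSE),
                   find_matches(m, host, dedup = FALSE))
})

test_that("automorphism groups are detected exactly", {
  expect_equal(find_automorphisms(parse_motif("A -> B"))$order, 1)

  g <- find_automorphisms(parse_motif("A -> B\nB -> A"))
  expect_equal(g$order, 2)
  expect_length(g$orbits, 1)
  expect_setequal(g$orbits[[1]], c("A", "B"))

  # all 6 directed edges among 3 nodes: full symmetric group
  full3 <- motif(rbind(c("A", "B"), c("B", "A"), c("B", "C"), c("C", "B"),
                       c("A", "C"), c("C", "A")))
  expect_equal(find_automorphisms(full3)$order, 6)

  # directed 3-cycle: cyclic group of order 3, no transpositions
  c3 <- find_automorphisms(parse_motif("A -> B\nB -> C\nC -> A"))
  expect_equal(c3$order, 3)
  expect_length(c3$generating_pairs, 0)

  # constraints break symmetry
  half <- parse_motif("A -> B\nB -> A\nA.size > 5")
  expect_equal(find_automorphisms(half)$order, 1)
  both <- parse_motif("A -> B\nB -> A\nA.size > 5\nB.size > 5")
  expect_equal(find_automorphisms(both)$order, 2)

  # two big nodes each inhibiting two small nodes: orbits {A,B}, {C,D}
  bis <- parse_motif(system.file("extdata", "motifs",
                                 "big_inhibits_small.motif",
                                 package = "motifquery"), is_file = TRUE)
  g <- find_automorphisms(bis)
  orb <- lapply(g$orbits, sort)
  expect_true(any(vapply(orb, identical, logical(1), y = c("A", "B"))))
  expect_true(any(vapply(orb, identical, logical(1), y = c("C", "D"))))
  expect_equal(g$order, 4)
})

test_that("automorphism detection matches the brute-force oracle on random motifs", {
  for (s in 1:30) {
    m <- random_motif(seed = 8000 + s)
    expect_equal(find_automorphisms(m)$order, length(oracle_automorphisms(m)),
                 info = paste("seed", s))
  }
})

test_that("declared interchangeability is verified and merged", {
  ok <- parse_motif("A -> B\nB -> A\nA === B")
  g <- find_automorphisms(ok)
  expect_equal(g$order, 2)
  # same group whether declared or auto-detected
  auto <- find_automorphisms(parse_motif("A -> B\nB -> A"))
  expect_equal(g$permutations, auto$permutations)

  expect_error(find_automorphisms(parse_motif("A -> B\nA === B")),
               "not an automorphism")
  big <- motif(cbind(paste0("N", 1:11), c(paste0("N", 2:11), "N1")))
  expect_error(find_automorphisms(big), "limited to 10")
})

test_that("symmetry breaking returns exactly one representative per orbit", {
  # mutual pair on a mutual-pair host: 2 raw, 1 after breaking
  mp <- parse_motif("A -> B\nB -> A")
  host <- host_graph(rbind(c("u", "v"), c("v", "u")))
  expect_equal(count_matches(mp, host, dedup = FALSE), 2)
  broken <- break_symmetry(mp)
  expect_equal(count_matches(broken, host, dedup = TRUE), 1)
  expect_length(broken$ordering, 1)

  # asymmetric motif: unchanged
  asym <- parse_motif("A -> B\nB -> C")
  expect_length(break_symmetry(asym)$ordering, 0)
  h2 <- random_host(8, seed = 21)
  expect_equal(count_matches(asym, h2, dedup = TRUE),
               count_matches(asym, h2, dedup = FALSE))

  # triangle motif in direction-ignored K4: 24 raw, 4 after breaking
  tri <- parse_motif("A -> B\nB -> C\nC -> A", ignore_direction = TRUE)
  k4e <- t(combn(letters[1:4], 2))
  k4 <- host_graph(rbind(k4e, k4e[, 2:1]))
  expect_equal(count_matches(tri, k4, dedup = FALSE), 24)
  expect_equal(count_matches(tri, k4, dedup = TRUE), 4)
})

test_that("dedup count times group order equals raw count (random property)", {
  for (s in 1:25) {
    m <- random_motif(seed = 9000 + s, constrained = FALSE)
    host <- random_host(sample(6:10, 1), seed = 9100 + s)
    raw <- count_matches(m, host, dedup = FALSE)
    dd <- count_matches(m, host, dedup = TRUE)
    ord <- find_automorphisms(m)$order
    expect_equal(dd * ord, raw, info = paste("seed", s))
    # cross-check against the post-filter oracle
    expect_equal(dd, nrow(oracle_dedup(oracle_matches(m, host), m)),
                 info = paste("seed", s))
  }
})
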