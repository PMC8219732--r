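test_that("basic statements parse into the expected motif", {
  m <- parse_motif("A -> B")
  expect_setequal(m$nodes, c("A", "B"))
  expect_equal(unname(m$edges), cbind("A", "B"))

  m <- parse_motif("A -> B [weight >= 10]")
  cst <- m$edge_constraints[["A->B"]][[1]]
  expect_equal(cst$attribute, "weight")
  expect_equal(cst$op, ">=")
  expect_equal(cst$rhs, 10)

  m <- parse_motif("A -> B\nA.size > 50")
  cst <- m$node_constraints[[1]]
  expect_equal(cst$subject, "A")
  expect_equal(cst$op, ">")
  expect_equal(cst$rhs, 50)

  m <- parse_motif("A -> B\nA !> C\nB === A")
  expect_equal(unname(m$forbidden), cbind("A", "C"))
  expect_equal(m$interchangeable[[1]], c("B", "A"))

  # inter-node comparison and value types
  m <- parse_motif(paste("A -> B [type = \"GABA\", weight in [1, 2.5]]",
                         "A.radius > B.radius", sep = "\n"))
  expect_equal(m$node_constraints[[1]]$rhs_ref, c("B", "radius"))
  cs <- m$edge_constraints[["A->B"]]
  expect_equal(cs[[1]]$rhs, "GABA")
  expect_equal(cs[[2]]$rhs, list(1, 2.5))
})

test_that("macros expand with substitution, nesting, and hygiene", {
  m <- parse_motif("dual(x, y) {\n x -> y\n y -> x\n}\ndual(A, B)")
  expect_setequal(edge_key(m$edges[, 1], m$edges[, 2]), c("A->B", "B->A"))
  expect_setequal(m$nodes, c("A", "B"))  # locals never leak

  nested <- "
    edge(x, y) { x -> y [weight > 2] }
    m2(x, y) {
      edge(x, y)
      edge(y, x)
    }
    m2(A, B)
  "
  m <- parse_motif(nested)
  expect_equal(nrow(m$edges), 2)
  expect_length(m$edge_constraints[["A->B"]], 1)
  expect_length(m$edge_constraints[["B->A"]], 1)

  expect_error(parse_motif("loop(x) { loop(x) }\nloop(A)"), "recursive")
  expect_error(parse_motif("f(x) { x -> y }\nf(A)"), "not a macro parameter")
  expect_error(parse_motif("f(x, y) { x -> y }\nf(A)"), "expects 2")
  expect_error(parse_motif("g(A, B)"), "undefined macro")
})

test_that("parsing ignores comments and whitespace", {
  base <- parse_motif("A -> B\nB -> C\nA.size > 5")
  variants <- c(
    "A->B # an edge\n\n   B ->   C\nA.size>5 # threshold",
    "# leading note\nA -> B;B -> C\n  A.size  >  5",
    "A -> B\n# only a comment line\nB -> C\nA.size > 5\n")
  for (v in variants) {
    expect_true(motif_identical(base, parse_motif(v)))
  }
})

test_that("serialize/parse round-trips motif structure", {
  src <- "
    # author: tester
    A -> B [weight >= 10, type = \"GABA\"]
    B -> C
    C -> D
    D -> E [size in [1, 2]]
    A !> E
    A.radius > B.radius
    C.kind = \"exc\"
    A === B
  "
  m <- parse_motif(src, exact_match = TRUE)
  back <- parse_motif(serialize_motif(m))
  expect_true(motif_identical(m, back))
  expect_true(back$exact_match)  # flags survive via provenance directives
  expect_equal(back$provenance$author, "tester")

  # and after macro expansion
  m2 <- parse_motif("dual(x, y) { x -> y\n y -> x }\ndual(A, B)\ndual(B, C)")
  expect_true(motif_identical(m2, parse_motif(serialize_motif(m2))))

  # non-edge operator appears in the serialization
  expect_match(serialize_motif(parse_motif("A -> B\nA !> C")), "A !> C",
               fixed = TRUE)
})

test_that("parser reports errors with line context", {
  expect_error(parse_motif("A -> B\nA -> "), "line 2")
  expect_error(parse_motif("A => B"), "syntax error")
  expect_error(parse_motif("# only a comment"), "empty motif")
  expect_error(parse_motif("A.size > 5"), "empty motif")
})

test_that("shipped example motif files parse", {
  dir <- system.file("extdata", "motifs", package = "motifquery")
  tri <- parse_motif(file.path(dir, "triangle.motif"), is_file = TRUE)
  expect_equal(nrow(tri$edges), 3)
  bis <- parse_motif(file.path(dir, "big_inhibits_small.motif"), is_file = TRUE)
  expect_setequal(bis$nodes, c("A", "B", "C", "D"))
  expect_equal(nrow(bis$edges), 4)
  malt <- parse_motif(file.path(dir, "malt_kc.motif"), is_file = TRUE)
  expect_length(malt$node_constraints, 2)
})
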