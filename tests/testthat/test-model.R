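test_that("allowed and forbidden cells partition the four joint states", {
  for (k in relationship_kinds()) {
    expect_equal(nrow(allowed_cells(k)) + nrow(forbidden_cells(k)), 4L)
  }
  expect_equal(nrow(forbidden_cells("SIM")), 2L)
  expect_equal(nrow(forbidden_cells("SIM_DUAL")), 2L)
  for (k in c("F01", "F10", "F00", "F11"))
    expect_equal(nrow(forbidden_cells(k)), 1L)
  # the diagonal pattern of the similar relationship
  expect_equal(allowed_cells("SIM"),
               matrix(c(0L, 1L, 0L, 1L), 2, dimnames = list(NULL, c("a", "b"))))
  # the triangular pattern of a prerequisite
  expect_setequal(paste(allowed_cells("F01")[, 1], allowed_cells("F01")[, 2]),
                  c("0 0", "1 0", "1 1"))
  expect_equal(unname(allowed_cells("SIM_DUAL")[, 1]), c(0L, 1L))
  expect_equal(unname(allowed_cells("SIM_DUAL")[, 2]), c(1L, 0L))
  expect_error(allowed_cells("XYZ"), "unknown")
})

test_that("holds_in_state follows the forbidden-cell semantics", {
  expect_false(holds_in_state("F01", 0, 1))
  expect_true(holds_in_state("SIM", 1, 1))
  expect_false(holds_in_state("SIM_DUAL", 1, 1))
  expect_error(holds_in_state("SIM", 2, 0), "0 or 1")
})

test_that("compatibility of full states", {
  fx <- fig2_fixture()
  # third column of the embedded state table is compatible by construction
  expect_true(is_compatible(fx$states[, 3], fx$relations))
  # all-zero state violates any F00 relation
  expect_false(is_compatible(stats::setNames(rep(0, 7), rownames(fx$states)),
                             pair_relations("A", "D", "F00")))
  # empty relation set accepts anything
  expect_true(is_compatible(c(A = 1, B = 0), pair_relations()))
  expect_error(is_compatible(c(A = 1), pair_relations("A", "Z", "SIM")),
               "unknown element")
})

test_that("enumeration reproduces the embedded 13-state example", {
  fx <- fig2_fixture()
  st <- enumerate_compatible_states(rownames(fx$states), fx$relations)
  expect_equal(ncol(st), 13L)
  expect_setequal(apply(st, 2, paste, collapse = ""),
                  apply(fx$states, 2, paste, collapse = ""))
})

test_that("enumeration edge cases", {
  expect_equal(ncol(enumerate_compatible_states(3)), 8L)
  both <- pair_relations(c("a", "a"), c("b", "b"), c("SIM", "SIM_DUAL"))
  expect_equal(ncol(enumerate_compatible_states(c("a", "b"), both)), 0L)
  expect_error(enumerate_compatible_states(26), "m <= 25")
})

test_that("enumeration agrees with the double-loop oracle", {
  set.seed(42)
  for (rep in 1:10) {
    m <- sample(3:6, 1)
    els <- letters[1:m]
    nr <- sample(1:4, 1)
    pairs <- t(replicate(nr, sample(els, 2)))
    r <- pair_relations(pairs[, 1], pairs[, 2],
                        sample(relationship_kinds(), nr, replace = TRUE))
    a <- enumerate_compatible_states(els, r)
    b <- oracle_enumerate(els, r)
    expect_setequal(apply(a, 2, paste, collapse = ""),
                    apply(b, 2, paste, collapse = ""))
  }
})

test_that("closure is entailment-complete and idempotent", {
  # prerequisite transitivity
  r <- pair_relations(c("A", "B"), c("B", "C"), c("F01", "F01"))
  expect_true("A C F01" %in% rel_key(closure(r)))
  # substitution of similar elements
  r2 <- pair_relations(c("A", "B"), c("B", "C"), c("SIM", "F01"))
  expect_true("A C F01" %in% rel_key(closure(r2)))
  # idempotence and oracle agreement on random instances
  set.seed(7)
  for (rep in 1:10) {
    m <- sample(3:5, 1)
    els <- LETTERS[1:m]
    nr <- sample(1:4, 1)
    pairs <- t(replicate(nr, sample(els, 2)))
    r <- pair_relations(pairs[, 1], pairs[, 2],
                        sample(relationship_kinds(), nr, replace = TRUE))
    cl <- suppressWarnings(closure(r))
    expect_equal(rel_key(suppressWarnings(closure(cl))), rel_key(cl))
    # semantic completeness: compare on the prerequisite components (the
    # reduced representation folds F01+F10 into SIM, the oracle does not)
    clF <- suppressWarnings(closure(r, reduce = FALSE))
    orc <- oracle_closure(r)   # over the elements the relations mention
    if (!is.null(orc))
      expect_equal(rel_key(clF),
                   rel_key(orc[grepl("^F", orc$kind), , drop = FALSE]))
    # closure never shrinks the compatible state set
    expect_setequal(
      apply(enumerate_compatible_states(els, r), 2, paste, collapse = ""),
      apply(enumerate_compatible_states(els, cl), 2, paste, collapse = ""))
  }
})

test_that("covering edges reduce a chain and preserve the closure", {
  ch <- pair_relations(c("A", "B", "A"), c("B", "C", "C"),
                       c("F01", "F01", "F01"))
  expect_equal(rel_key(covering_edges(ch)), c("A B F01", "B C F01"))
  expect_equal(nrow(covering_edges(pair_relations())), 0L)
  expect_error(covering_edges(pair_relations(c("A", "A"), c("B", "B"),
                                             c("F01", "F10"))),
               "cycle across distinct similarity classes")
})

test_that("covering edges plus class links regenerate random closures", {
  set.seed(11)
  for (rep in 1:40) {
    r <- random_dab_network(sample(4:8, 1), runif(1, 0.2, 0.6), seed = rep)
    cl <- closure(r)
    cov <- covering_edges(r)
    links <- dabnet:::.class_links(similarity_classes(r))
    both <- pair_relations(c(cov$a, links$a), c(cov$b, links$b),
                           c(cov$kind, links$kind))
    expect_equal(rel_key(closure(both)), rel_key(cl))
  }
})
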