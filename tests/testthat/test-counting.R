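test_that("pair tabulation matches a hand tally of the worked example", {
  st <- table1_states()
  tb <- tabulate_pair(st, "A", "B")
  expect_equal(unlist(tb[c("n00", "n01", "n10", "n11", "N")]),
               c(n00 = 1L, n01 = 0L, n10 = 6L, n11 = 6L, N = 13L))
  z <- matrix(0L, 2, 5, dimnames = list(c("x", "y"), NULL))
  expect_equal(tabulate_pair(z, "x", "y")$n00, 5L)
  expect_error(tabulate_pair(st, "A", "A"), "distinct")
  expect_error(tabulate_pair(st, "A", "Z"), "unknown")
})

test_that("counting numbers satisfy their identities and examples", {
  cnt <- relationship_counts(pair_table(1, 0, 6, 6))
  expect_equal(cnt, c(SIM = 7L, SIM_DUAL = 6L, F01 = 13L, F10 = 7L,
                      F00 = 12L, F11 = 7L))
  expect_equal(max(cnt), 13L)
  cnt2 <- relationship_counts(pair_table(0, 0, 0, 9))
  expect_equal(cnt2, c(SIM = 9L, SIM_DUAL = 0L, F01 = 9L, F10 = 9L,
                       F00 = 9L, F11 = 0L))
  set.seed(5)
  for (rep in 1:50) {
    n <- rmultinom(1, sample(5:200, 1), runif(4))[, 1]
    cc <- relationship_counts(pair_table(n[1], n[2], n[3], n[4]))
    N <- sum(n)
    expect_equal(cc[["SIM"]] + cc[["SIM_DUAL"]], N)
    expect_equal(sum(cc[c("F01", "F10", "F00", "F11")]), 3L * N)
    expect_equal(cc[["F01"]], N - n[2])
  }
})

test_that("cells are recovered from reference counting-number rows", {
  tb <- cells_from_counts(c(SIM = 55, SIM_DUAL = 45, F01 = 98, F10 = 57,
                            F00 = 90, F11 = 55), 100)
  expect_equal(unlist(tb[1:4]),
               c(n00 = 10L, n01 = 2L, n10 = 43L, n11 = 45L))
  tb2 <- cells_from_counts(c(SIM = 26, SIM_DUAL = 74, F01 = 99, F10 = 27,
                             F00 = 89, F11 = 85), 100)
  expect_equal(unlist(tb2[1:4]),
               c(n00 = 11L, n01 = 1L, n10 = 73L, n11 = 15L))
  # round trip
  t0 <- pair_table(3, 14, 15, 9)
  expect_equal(unlist(cells_from_counts(relationship_counts(t0), t0$N)),
               unlist(t0))
  expect_error(cells_from_counts(c(SIM = 50, SIM_DUAL = 45, F01 = 98,
                                   F10 = 57, F00 = 90, F11 = 55), 100),
               "inconsistent")
})

test_that("confidence-bound thresholds reproduce the reference values", {
  expect_equal(ceiling(similar_threshold(100, 0.05)), 86)
  expect_equal(ceiling(prerequisite_threshold(100, 0.05)), 93)
  expect_equal(ceiling(similar_threshold(81, 0.1)), 61)
  expect_equal(ceiling(prerequisite_threshold(81, 0.1)), 69)
  # no noise, no slack
  expect_equal(similar_threshold(123, 0), 123)
  expect_equal(prerequisite_threshold(123, 0), 123)
  expect_error(similar_threshold(100, 0.6), "epsilon")
  expect_error(prerequisite_threshold(100, 0.5), "epsilon")
})

test_that("thresholds are monotone in N and epsilon", {
  for (e in c(0.02, 0.05, 0.1, 0.2)) {
    tsim <- vapply(10:300, similar_threshold, numeric(1), epsilon = e)
    tpre <- vapply(10:300, prerequisite_threshold, numeric(1), epsilon = e)
    expect_true(all(diff(tsim) > 0))
    expect_true(all(diff(tpre) > 0))
  }
  eg <- seq(0, 0.25, by = 0.01)
  expect_true(all(diff(vapply(eg, similar_threshold, numeric(1),
                              N = 100)) < 0))
  expect_true(all(diff(vapply(eg, prerequisite_threshold, numeric(1),
                              N = 100)) < 0))
})

test_that("the count screen selects by the ceiling rule", {
  cnt <- c(SIM = 55, SIM_DUAL = 45, F01 = 98, F10 = 57, F00 = 90, F11 = 55)
  expect_equal(screen_counts(cnt, 100, 0.05), "F01")
  bal <- relationship_counts(pair_table(25, 25, 25, 25))
  expect_length(screen_counts(bal, 100, 0.05), 0L)
  # noise-free true similar pair: SIM and the implied prerequisites reach N
  full <- relationship_counts(pair_table(60, 0, 0, 40))
  expect_setequal(screen_counts(full, 100, 0), c("SIM", "F01", "F10"))
})
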