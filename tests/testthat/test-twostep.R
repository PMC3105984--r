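test_that("infer_pair scores and selects per the two screens", {
  tab <- cells_from_counts(c(SIM = 55, SIM_DUAL = 45, F01 = 98, F10 = 57,
                             F00 = 90, F11 = 55), 100)
  r <- infer_pair(tab, epsilon = 0.05)
  expect_equal(nrow(r), 6L)
  expect_equal(r$kind[r$selected], "F01")
  # noise-free similar pair from the worked example
  st <- table1_states()
  rb <- infer_pair(tabulate_pair(st, "B", "E"), epsilon = 0)
  sel <- rb$kind[rb$selected]
  expect_true("SIM" %in% sel)
  # balanced table: nothing selected
  r0 <- infer_pair(pair_table(25, 25, 25, 25), epsilon = 0.05)
  expect_false(any(r0$selected))
})

test_that("the full two-step fit recovers the worked example noise-free", {
  fx <- fig2_fixture()
  fit <- dab_infer(fx$states, epsilon = 0)
  expect_s3_class(fit, "dab_network")
  expect_equal(rel_key(fit$selected), rel_key(fx$relations))
  expect_equal(nrow(fit$selected), 12L)
  # report shape: 21 pairs x 6 kinds with the counting identities per pair
  expect_equal(nrow(fit$report), 21L * 6L)
  for (p in unique(fit$report$pair)) {
    cc <- fit$report[fit$report$pair == p, ]
    expect_equal(sum(cc$count[cc$kind %in% c("SIM", "SIM_DUAL")]), 13L)
    expect_equal(sum(cc$count[grepl("^F", cc$kind)]), 3L * 13L)
  }
  expect_error(dab_infer(fx$states[1, , drop = FALSE], 0), "two elements")
})

test_that("noise-free inference returns the closure of random networks", {
  set.seed(31)
  for (rep in 1:10) {
    r <- random_dab_network(sample(4:7, 1), runif(1, 0.25, 0.6), seed = rep)
    els <- attr(r, "elements")
    st <- enumerate_compatible_states(els, r)
    if (ncol(st) < 2) next
    fit <- dab_infer(st, epsilon = 0)
    expect_equal(rel_key(fit$selected), rel_key(exact_relations(st)))
  }
})

test_that("neither screen alone reproduces the two-step selection", {
  fx <- fig2_fixture()
  x <- perturb(sample_states(fx$states, 100, seed = 5), 0.05, seed = 6)
  fit <- dab_infer(x, epsilon = 0.05)
  r <- fit$report
  expect_gt(sum(r$passed_count & !r$passed_pvalue), 0)
  expect_gt(sum(r$passed_pvalue & !r$passed_count), 0)
})

test_that("the fit object provides the standard methods", {
  fx <- fig2_fixture()
  fit <- dab_infer(fx$states, epsilon = 0)
  expect_output(print(fit), "12 selected")
  expect_output(print(summary(fit)), "Screen overlap")
  co <- coef(fit)
  expect_equal(unname(co["threshold_similar"]), 13)
  sim <- simulate(fit, nsim = 25, seed = 4, epsilon = 0.05)
  expect_equal(dim(sim), c(7L, 25L))
  expect_true(all(sim %in% 0:1))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("epsilon can be pooled-estimated from the data", {
  fx <- fig2_fixture()
  x <- perturb(sample_states(fx$states, 150, seed = 9), 0.05, seed = 10)
  fit <- dab_infer(x, epsilon = "estimate")
  expect_true(fit$epsilon_estimated)
  expect_gt(fit$epsilon, 0)
  expect_lt(fit$epsilon, 0.25)
})
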