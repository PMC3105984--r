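test_that("the noise map behaves at its boundary cases", {
  p <- c(0.2, 0.3, 0.1, 0.4)
  expect_equal(observed_cell_probs(p, 0), p)
  expect_equal(observed_cell_probs(p, 0.5), rep(0.25, 4))
  expect_equal(observed_cell_probs(rep(0.25, 4), 0.17), rep(0.25, 4))
  expect_error(observed_cell_probs(c(0.5, 0.5, 0.2, -0.2), 0.1), "sum")
})

test_that("forward and inverse noise maps are exact inverses on a grid", {
  set.seed(3)
  for (e in c(0, 0.05, 0.1, 0.25, 0.4, 0.49)) {
    for (rep in 1:10) {
      p <- as.numeric(rmultinom(1, 500, runif(4))) / 500
      q <- observed_cell_probs(p, e)
      n <- round(q * 1000)
      # feed exact frequencies through a table of matching composition
      tb <- pair_table(n[1], n[2], n[3], n[4])
      est <- estimate_true_probs(tb, e)
      q2 <- as.numeric(dabnet:::.flip_kernel(e) %*% est$raw)
      expect_equal(q2, n / sum(n), tolerance = 1e-12)
    }
  }
  # epsilon = 0 returns the empirical frequencies
  tb <- pair_table(10, 20, 30, 40)
  expect_equal(unname(estimate_true_probs(tb, 0)$raw),
               c(0.1, 0.2, 0.3, 0.4))
  expect_error(estimate_true_probs(tb, 0.5), "not invertible")
})

test_that("raw inverse outside [0,1] is flagged and clipped", {
  # heavy off-diagonal observation: diagonal true mass goes negative
  est <- estimate_true_probs(pair_table(10, 2, 43, 45), 0.05)
  expect_true(est$raw[["p01"]] < 0)
  expect_true(est$out_of_range)
  expect_true(all(est$clipped >= 0))
  expect_equal(sum(est$clipped), 1)
})

test_that("p-values are probabilities for random tables", {
  set.seed(9)
  for (rep in 1:500) {
    n <- rmultinom(1, sample(4:300, 1), runif(4))[, 1]
    tb <- pair_table(n[1], n[2], n[3], n[4])
    for (e in c(0, 0.05, 0.1, 0.2)) {
      pv <- vapply(relationship_kinds(), asymptotic_pvalue, numeric(1),
                   table = tb, epsilon = e)
      expect_true(all(pv >= 0 & pv <= 1))
    }
  }
})

test_that("a perfectly supported relationship attains the maximal p-value", {
  expect_equal(asymptotic_pvalue("SIM", pair_table(50, 0, 0, 50), 0), 1)
  expect_equal(asymptotic_pvalue("F01", pair_table(10, 0, 40, 50), 0), 1)
  # and the grossly violated one is rejected
  expect_lt(asymptotic_pvalue("SIM_DUAL", pair_table(50, 0, 0, 50), 0),
            1e-6)
  expect_lt(asymptotic_pvalue("F10", pair_table(10, 2, 43, 45), 0.05),
            1e-4)
})

test_that("true-kind p-values round to 1 in the majority of noisy pairs", {
  fx <- fig2_fixture()
  set.seed(21)
  hits <- 0L; tot <- 0L
  for (s in 1:20) {
    x <- perturb(sample_states(fx$states, 100, seed = s), 0.05,
                 seed = 1000 + s)
    for (i in seq_len(nrow(fx$relations))) {
      tb <- tabulate_pair(x, fx$relations$a[i], fx$relations$b[i])
      pv <- asymptotic_pvalue(fx$relations$kind[i], tb, 0.05)
      hits <- hits + (round(pv, 4) >= 1)
      tot <- tot + 1L
    }
  }
  expect_gt(hits / tot, 0.5)
})

test_that("constrained epsilon MLE recovers the generating rate", {
  # similarity-structured truth, large sample: identifiable
  q <- observed_cell_probs(c(0.35, 0, 0, 0.65), 0.1)
  n <- round(q * 10000)
  tb <- pair_table(n[1], n[2], n[3], n[4])
  est <- estimate_epsilon(tb, kind = "SIM")
  expect_equal(est$epsilon_hat, 0.1, tolerance = 0.02)
  expect_equal(est$epsilon_hat, oracle_constrained_eps(tb, "SIM"),
               tolerance = 0.01)
  # prerequisite-structured truth
  q2 <- observed_cell_probs(c(0.3, 0, 0.3, 0.4), 0.08)
  n2 <- round(q2 * 10000)
  tb2 <- pair_table(n2[1], n2[2], n2[3], n2[4])
  est2 <- estimate_epsilon(tb2, kind = "F01")
  expect_equal(est2$epsilon_hat, 0.08, tolerance = 0.02)
  # best-kind selection agrees with the generating structure
  expect_equal(estimate_epsilon(tb)$kind, "SIM")
})

test_that("epsilon MLE boundary behaviour", {
  expect_equal(estimate_epsilon(pair_table(50, 0, 0, 50),
                                kind = "SIM")$epsilon_hat, 0)
  expect_warning(est <- estimate_epsilon(pair_table(2, 0, 0, 1)),
                 "fewer than 4")
  expect_true(est$epsilon_hat >= 0 && est$epsilon_hat <= 0.5)
})

test_that("likelihood at the constrained MLE beats fixed alternatives", {
  set.seed(13)
  for (rep in 1:5) {
    n <- rmultinom(1, 150, c(0.3, 0.1, 0.25, 0.35))[, 1]
    tb <- pair_table(n[1], n[2], n[3], n[4])
    for (k in c("SIM", "F01")) {
      est <- estimate_epsilon(tb, kind = k)
      ncounts <- c(tb$n00, tb$n01, tb$n10, tb$n11)
      for (e0 in c(0, 0.25)) {
        ll0 <- dabnet:::.constrained_fit(ncounts, k, e0)$loglik
        expect_gte(est$loglik, ll0 - 1e-6)
      }
    }
  }
})
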