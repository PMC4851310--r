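test_that("rank density reduces to known closed forms", {
  m <- uniform_null()
  u <- seq(0.1, 6, length.out = 25)
  # single test: the model density itself
  expect_equal(rank_density(u, 1, 1, m), exp(-u), tolerance = 1e-12)
  expect_equal(max_density(u, 1, m), null_pdf(m, u), tolerance = 1e-12)
  # direct substitution, top of 5 at u = 1
  expect_equal(max_density(1, 5, m), 5 * (1 - exp(-1))^4 * exp(-1), tolerance = 1e-12)
  # least significant of n under the unit exponential: n exp(-n u)
  expect_equal(min_density(u, 7, m), 7 * exp(-7 * u), tolerance = 1e-12)
  expect_equal(min_density(0, 2, m), 2)
  expect_error(rank_density(1, 5, 6, m), "out of range")
  expect_error(rank_density(1, 5, 0, m), "out of range")
})

test_that("rank densities are normalized across ranks and model families", {
  models <- list(uniform_null(), gamma_null(1.1144, 0.9334),
                 beta_null(0.9, 1.1), chisq_null(2.5))
  cases <- rbind(c(3, 1), c(3, 2), c(3, 3), c(100, 1), c(100, 100))
  for (m in models) {
    for (k in seq_len(nrow(cases))) {
      n <- cases[k, 1]; r <- cases[k, 2]
      total <- integrate(rank_density, 0, Inf, n_tests = n, rank_from_top = r,
                         model = m, rel.tol = 1e-10)$value
      expect_equal(total, 1, tolerance = 1e-8,
                   label = sprintf("n=%d r=%d %s", n, r, class(m)[1]))
    }
  }
})

test_that("max density is the derivative of F(u)^n", {
  m <- gamma_null(1.3, 0.8)
  n <- 12
  u <- seq(0.5, 9.5, length.out = 10)
  h <- 1e-6
  num_deriv <- (null_cdf(m, u + h)^n - null_cdf(m, u - h)^n) / (2 * h)
  expect_equal(max_density(u, n, m), num_deriv, tolerance = 1e-6)
})

test_that("rank exceedance probabilities match Monte Carlo at n = 3", {
  set.seed(333)
  B <- 2e5
  for (m in list(uniform_null(), beta_null(0.9, 1.1), chisq_null(1.5))) {
    draws <- matrix(null_sim(m, 3 * B), nrow = 3)
    sorted <- apply(draws, 2, sort, decreasing = TRUE)
    x <- unname(quantile(sorted[1, ], 0.9))  # a tail point with real mass
    for (r in 1:3) {
      emp <- mean(sorted[r, ] > x)
      se <- sqrt(emp * (1 - emp) / B)
      theo <- experimentwise_p_rank(x, r, 3, m)
      expect_lt(abs(theo - emp), 3 * se + 1e-12)
    }
  }
})

test_that("the generalized correction collapses to Dunn-Sidak under Gamma(1,1)", {
  m <- uniform_null()
  for (p in c(1e-40, 1e-20, 1e-8, 1e-3, 0.1)) {
    for (n in c(1, 10, 1e6)) {
      ds <- -expm1(n * log1p(-p))  # 1 - (1 - p)^n
      expect_rel_equal(experimentwise_p_max(-log(p), n, m), ds, 1e-10)
    }
  }
})

test_that("worked-example corrections reproduce the published values", {
  g <- gamma_null(1.1144, 0.9334)
  x <- 73.7553
  expect_rel_equal(experimentwise_p_max(x, 1984813, g), oracle$pE_gamma_all, 1e-8)
  expect_rel_equal(experimentwise_p_max(x, 505309, g), oracle$pE_gamma_meff, 1e-8)
  expect_rel_equal(experimentwise_p_max(x, 1984813, g), 2.601e-23, 0.01)
  expect_rel_equal(experimentwise_p_max(x, 505309, g), 6.61e-24, 0.01)
  u <- neglog_transform(9.30e-33)
  expect_rel_equal(experimentwise_p_max(u, 1984813, uniform_null()), 1.85e-26, 0.005)
  expect_rel_equal(experimentwise_p_max(u, 505309, uniform_null()), 4.70e-27, 0.005)
  # n = 1: no correction at all
  expect_equal(experimentwise_p_max(x, 1, g), null_sf(g, x))
})

test_that("experiment-wise p is monotone in x, n and rank", {
  g <- gamma_null(1.2, 0.9)
  x <- c(5, 10, 20)
  p5 <- experimentwise_p_max(x, 1e4, g)
  expect_true(all(diff(p5) < 0))                      # decreasing in x
  expect_lt(experimentwise_p_max(10, 1e3, g),
            experimentwise_p_max(10, 1e6, g))         # increasing in n
  # "at least r of n exceed x" shrinks as r grows
  pr <- vapply(1:5, experimentwise_p_rank, numeric(1), x = 6, n_tests = 20, model = g)
  expect_true(all(diff(pr) < 0))
  # the top rank is always above the single-test survival probability
  expect_gte(experimentwise_p_max(10, 50, g), null_sf(g, 10))
})

test_that("arbitrary-rank tail probabilities match independent oracles", {
  g <- gamma_null(2, 1.5)
  # frozen explicit binomial-sum oracle: P(at least 3 of 20 exceed 8)
  expect_rel_equal(experimentwise_p_rank(8, 3, 20, g),
                   oracle$binom_tail_20_3, 1e-9)
  # P(min of 2 unit exponentials > 1) = e^-2
  expect_rel_equal(experimentwise_p_rank(1, 2, 2, uniform_null()), exp(-2), 1e-10)
  # rank 1 equals the closed-form top correction
  expect_rel_equal(experimentwise_p_rank(4, 1, 100, g),
                   experimentwise_p_max(4, 100, g), 1e-10)
  # adaptive quadrature of the rank density agrees with the closed form
  for (m in list(uniform_null(), gamma_null(1.1144, 0.9334), beta_null(0.9, 1.1))) {
    for (r in c(1, 2, 5)) {
      cf <- experimentwise_p_rank(3, r, 30, m)
      qd <- experimentwise_p_rank(3, r, 30, m, method = "quadrature")
      expect_rel_equal(qd, cf, 1e-8)
    }
  }
})

test_that("FWER thresholds reproduce published levels and invert correctly", {
  thr <- threshold_for_fwer(0.05, 1e4, uniform_null())
  expect_rel_equal(thr$p_threshold, 5.13e-6, 0.001)
  expect_rel_equal(thr$p_threshold, oracle$ds_alpha_1e4, 1e-7)
  # Dunn-Sidak per-test level in closed form
  expect_rel_equal(thr$p_threshold, 1 - (1 - 0.05)^(1e-4), 1e-10)
  expect_equal(threshold_for_fwer(0.05, 1, uniform_null())$p_threshold, 0.05,
               tolerance = 1e-12)
  # gamma model at the analytic Beta(0.9, 1.1) moments
  g <- gamma_null(oracle$beta_u_gamma_scale, oracle$beta_u_gamma_shape)
  thr_g <- threshold_for_fwer(0.05, 1e4, g)
  expect_rel_equal(thr_g$p_threshold, 1.36e-6, 0.01)
  expect_rel_equal(thr_g$u_threshold, oracle$g_u_threshold, 1e-7)
  # the threshold actually achieves the target FWER (uniroot-style check)
  for (m in list(uniform_null(), g, beta_null(0.8, 1.2))) {
    t2 <- threshold_for_fwer(0.01, 5e5, m)
    expect_rel_equal(experimentwise_p_max(t2$u_threshold, 5e5, m), 0.01, 1e-8)
  }
})

test_that("expected false positives and fold increase match the published example", {
  g <- gamma_null(1.1144, 0.9334)
  expect_equal(expected_false_positives(1e-5, 1e6, uniform_null()), 10,
               tolerance = 1e-9)
  expect_rel_equal(expected_false_positives(1e-5, 1e6, g), 26.6, 0.001)
  expect_rel_equal(expected_false_positives(1e-5, 1e6, g),
                   oracle$expected_fp_gamma, 1e-7)
  expect_rel_equal(fold_increase(uniform_null(), g, 1e-5), 2.66, 0.001)
})
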