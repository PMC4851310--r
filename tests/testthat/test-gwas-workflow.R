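make_table <- function(p) {
  out <- data.frame(marker_id = paste0("rs", seq_along(p)),
                    chromosome = "1", position = seq_along(p) * 10L,
                    p_value = p, stringsAsFactors = FALSE)
  class(out) <- c("association_table", "data.frame")
  out
}

test_that("association tables load, validate, and round-trip", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tBP\tP\tBETA",
               "rs1\t1\t100\t0.5\t0.1",
               "rs2\t2\t200\t1e-9\t0.9",
               "rs3\t2\t300\t0.03\t-0.2",
               "rs4\tX\t400\t1\t0.0",
               "rs5\t3\t500\t0.99\t0.4"), path)
  tbl <- load_association_table(path)
  expect_s3_class(tbl, "association_table")
  expect_equal(nrow(tbl), 5)
  expect_equal(tbl$p_value[2], 1e-9)
  expect_equal(tbl$chromosome[4], "X")

  writeLines(c("SNP\tCHR\tBP\tP", "rs1\t1\t1\t0", "rs2\t1\t2\t0.5"), path)
  expect_error(load_association_table(path), "row 1")
  writeLines(c("SNP\tCHR\tBP\tP", "rs1\t1\t1\t0.5", "rs1\t1\t2\t0.6"), path)
  expect_error(load_association_table(path), "duplicated")
  writeLines(c("SNP\tCHR\tBP", "rs1\t1\t1"), path)
  expect_error(load_association_table(path), "column 'P' missing")

  # write/read round trip on a generated study
  tbl2 <- generate_study(synthetic_study_spec(1000, "uniform", seed = 17))
  write_association_table(tbl2, path)
  back <- load_association_table(path)
  expect_equal(back$marker_id, tbl2$marker_id)
  expect_equal(back$p_value, tbl2$p_value, tolerance = 1e-14)
  unlink(path)
})

test_that("gzip-compressed tables are read transparently", {
  plain <- tempfile(fileext = ".tsv")
  write_association_table(make_table(c(0.5, 0.1, 0.9)), plain)
  gz <- paste0(plain, ".gz")
  con <- gzfile(gz, "w"); writeLines(readLines(plain), con); close(con)
  expect_equal(load_association_table(gz)$p_value, c(0.5, 0.1, 0.9),
               tolerance = 1e-14)
  unlink(c(plain, gz))
})

test_that("the study null is fitted on the post-exclusion set with a strict cutoff", {
  set.seed(41)
  tbl <- generate_study(synthetic_study_spec(1e5, "uniform", n_signals = 50,
                                             signal_p_ceiling = 1e-10, seed = 41))
  fit <- fit_study_null(tbl, 5e-8)
  expect_equal(fit$n_excluded, 50)
  expect_equal(fit$n_used, 1e5 - 50)
  # uniform nulls: fitted parameters within sampling noise of (1, 1);
  # moment-estimator standard errors at n = 1e5 are ~ sqrt(c * (1 + ...)/n) ~ 0.006
  expect_lt(abs(fit$model$scale - 1), 0.025)
  expect_lt(abs(fit$model$shape - 1), 0.025)
  # strictness: a marker exactly at the threshold is retained
  tbl2 <- make_table(c(5e-8, 0.2, 0.5, 0.7))
  expect_equal(fit_study_null(tbl2, 5e-8)$n_excluded, 0)
  expect_error(fit_study_null(make_table(c(1e-9, 1e-10))), "fewer than 2")
})

test_that("gamma-model parameters are recovered from a gamma-null study", {
  set.seed(43)
  tbl <- generate_study(synthetic_study_spec(1e6, "gamma_u", gamma_scale = 1.1144,
                                             gamma_shape = 0.9334, seed = 43))
  fit <- fit_study_null(tbl, 5e-8)
  expect_rel_equal(c(fit$model$scale, fit$model$shape), c(1.1144, 0.9334), 0.01)
})

test_that("analyze_study reproduces the published worked example", {
  # top hit supplied with filler nulls; the fitted model is supplied externally,
  # as the published parameter values are inputs here
  set.seed(47)
  tbl <- make_table(c(9.30e-33, runif(999)))
  g <- gamma_null(1.1144, 0.9334)
  rep <- analyze_study(tbl, model = g, m_eff = 505309, top_k = 3)
  # n for the correction overridden to the full published marker count
  hit <- rep$top_hits[1, ]
  u <- neglog_transform(9.30e-33)
  expect_equal(hit$p, 9.30e-33)
  expect_equal(hit$u, u, tolerance = 1e-10)
  expect_rel_equal(experimentwise_p_max(u, 1984813, uniform_null()), 1.85e-26, 0.005)
  expect_rel_equal(experimentwise_p_max(u, 1984813, g), 2.601e-23, 0.01)
  expect_rel_equal(hit$p_experimentwise_uniform_meff, 4.70e-27, 0.005)
  expect_rel_equal(hit$p_experimentwise_gamma_meff, 6.61e-24, 0.01)
  # single-marker study: experiment-wise p equals the model survival probability
  one <- analyze_study(make_table(0.01), model = g, top_k = 1)
  expect_equal(one$top_hits$p_experimentwise_gamma,
               null_sf(g, -log(0.01)), tolerance = 1e-12)
  expect_equal(one$top_hits$p_experimentwise_uniform, 0.01, tolerance = 1e-12)
})

test_that("heavier-tailed fitted nulls give larger corrected p-values", {
  set.seed(53)
  tbl <- make_table(c(1e-12, 1e-9, runif(500)))
  g <- gamma_null(1.1144, 0.9334)  # heavier tail than unit exponential
  rep <- analyze_study(tbl, model = g, top_k = 2)
  for (k in 1:2) {
    x <- rep$top_hits$u[k]
    expect_gte(null_sf(g, x), null_sf(uniform_null(), x))
    expect_gte(rep$top_hits$p_experimentwise_gamma[k],
               rep$top_hits$p_experimentwise_uniform[k])
  }
  # m_eff never increases the corrected p
  rep2 <- analyze_study(tbl, model = g, m_eff = 100, top_k = 2)
  expect_true(all(rep2$top_hits$p_experimentwise_gamma_meff <=
                  rep2$top_hits$p_experimentwise_gamma))
})

test_that("expected-false-positive table and histogram diagnostics are consistent", {
  set.seed(59)
  tbl <- generate_study(synthetic_study_spec(20000, "beta", beta_nu = 0.9,
                                             beta_omega = 1.1, n_signals = 10,
                                             signal_p_ceiling = 1e-9, seed = 59))
  rep <- analyze_study(tbl, top_k = 5, alphas = c(1e-3, 1e-5))
  expect_equal(rep$n_total, 20000)
  efp <- rep$expected_fp_table
  expect_equal(efp$expected_uniform, 20000 * c(1e-3, 1e-5), tolerance = 1e-9)
  expect_equal(efp$fold, efp$expected_fitted / efp$expected_uniform)
  h <- pvalue_histogram(tbl, bins = 50, exclusion_threshold = 5e-8)
  expect_equal(nrow(h), 50)
  expect_equal(sum(h$count), rep$n_total - rep$n_excluded)
  expect_equal(sum(pvalue_histogram(tbl)$count), rep$n_total)
})

test_that("reports round-trip through JSON and TSV at 6 significant digits", {
  set.seed(61)
  tbl <- make_table(c(1e-15, runif(200)))
  rep <- analyze_study(tbl, model = gamma_null(1.2, 0.9), top_k = 4,
                       gof_replicates = 100)
  expect_true(!is.null(rep$gof))
  expect_true(rep$gof$p_value >= 0 && rep$gof$p_value <= 1)
  js <- tempfile(fileext = ".json")
  write_report(rep, js, "json")
  back <- read_report(js)
  expect_equal(back$n_total, rep$n_total)
  expect_equal(back$top_hits$p_experimentwise_gamma,
               signif(rep$top_hits$p_experimentwise_gamma, 6), tolerance = 1e-12)
  expect_equal(back$fitted_model$scale_b, 1.2)
  tsv <- tempfile(fileext = ".tsv")
  write_report(rep, tsv, "tsv")
  expect_length(readLines(tsv), 4 + 1)  # top_k + header
  # empty-ish report still writes valid JSON
  rep0 <- analyze_study(make_table(0.5), model = gamma_null(1, 1), top_k = 0)
  write_report(rep0, js, "json")
  expect_silent(read_report(js))
  unlink(c(js, tsv))
})
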