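# Order-statistic densities of ranked results and the experiment-wise
# p-values and thresholds derived from them. The top-ranked statistic of n
# i.i.d. tests has density n F(u)^{n-1} f(u); integrating its tail gives the
# generalized family-wise correction, which collapses to Dunn-Sidak when the
# null model is the unit exponential (uniform p-values).

.check_rank <- function(n_tests, rank_from_top) {
  stopifnot(is.numeric(n_tests), length(n_tests) == 1L, is.finite(n_tests),
            n_tests >= 1,
            is.numeric(rank_from_top), length(rank_from_top) == 1L,
            rank_from_top == round(rank_from_top))
  if (rank_from_top < 1 || rank_from_top > n_tests)
    stop(sprintf("rank_from_top = %d out of range [1, %g]", rank_from_top, n_tests),
         call. = FALSE)
}

#' Density of the rank-r result among n independent tests
#'
#' Density of the r-th most significant transformed statistic out of
#' `n_tests` i.i.d. draws from the null model. In classical order-statistic
#' notation with ranks counted from the bottom, this is the i-th order
#' statistic with `i = n - r + 1`:
#' `i * choose(n, i) * F(u)^(i-1) * (1 - F(u))^(n-i) * f(u)`.
#' The public interface counts ranks from the top ("rank 1 = top hit"), the
#' convention users of association scans actually think in.
#'
#' Evaluation is in log space so extreme tails do not underflow; the `0 * Inf`
#' corner at the support boundary is resolved to the correct limit.
#'
#' @param u Vector of non-negative statistic values.
#' @param n_tests Number of tests `n` (may be a non-integer effective count).
#' @param rank_from_top Rank counted from the most significant result
#'   (1 = top hit, `n_tests` = least significant).
#' @param model A `null_model`.
#' @param log Return the log density.
#' @return Numeric vector of densities at `u`.
#' @examples
#' rank_density(1, n_tests = 5, rank_from_top = 1, model = uniform_null())
#' 5 * (1 - exp(-1))^4 * exp(-1)
#' @export
rank_density <- function(u, n_tests, rank_from_top = 1, model, log = FALSE) {
  .check_rank(n_tests, rank_from_top)
  .check_stat(u)
  n <- n_tests
  i <- n - rank_from_top + 1
  logF <- null_cdf(model, u, log.p = TRUE)
  logS <- null_sf(model, u, log.p = TRUE)
  logf <- null_pdf(model, u, log = TRUE)
  xlog <- function(a, lx) if (a == 0) 0 else a * lx  # 0 * -Inf -> 0 (a scalar)
  ld <- log(i) + lchoose(n, i) + xlog(i - 1, logF) + xlog(n - i, logS) + logf
  if (log) ld else exp(ld)
}

#' @rdname rank_density
#' @export
max_density <- function(u, n_tests, model, log = FALSE)
  rank_density(u, n_tests, rank_from_top = 1, model = model, log = log)

#' @rdname rank_density
#' @export
min_density <- function(u, n_tests, model, log = FALSE)
  rank_density(u, n_tests, rank_from_top = n_tests, model = model, log = log)

#' Experiment-wise p-value for the top-ranked result
#'
#' Probability, under the study-wide null, that the most significant of
#' `n_tests` statistics exceeds the observed value `x`: the tail integral of
#' [max_density()], which has the closed form `1 - F(x)^n`. Under the
#' [uniform_null()] model with `x = -ln(p)` this is exactly the Dunn-Sidak
#' corrected p-value `1 - (1 - p)^n`; under a fitted gamma model it is the
#' generalized correction that stays calibrated when null p-values are not
#' uniform.
#'
#' The closed form is evaluated as `-expm1(n * log1p(-sf(x)))` with the
#' survival function computed directly in the tail, which preserves full
#' relative precision for results as extreme as 1e-40; naive quadrature or a
#' `1 - cdf` composition would lose everything past 1e-16.
#'
#' @param x Observed top statistic (`-ln(p)` of the best hit for u-scale
#'   models), non-negative; vectorized.
#' @param n_tests Number of tests; a fractional effective number of
#'   independent tests is accepted.
#' @param model A `null_model`.
#' @return Experiment-wise p-value(s) in `[0, 1]`.
#' @examples
#' # Dunn-Sidak for p = 9.30e-33 among ~2M markers:
#' experimentwise_p_max(-log(9.30e-33), 1984813, uniform_null())
#' # generalized correction under a fitted gamma null:
#' experimentwise_p_max(73.7553, 1984813, gamma_null(1.1144, 0.9334))
#' @export
experimentwise_p_max <- function(x, n_tests, model) {
  stopifnot(is.numeric(n_tests), length(n_tests) == 1L, n_tests >= 1)
  .check_stat(x)
  s <- null_sf(model, x)
  -expm1(n_tests * log1p(-s))
}

#' Experiment-wise p-value for an arbitrary ranked result
#'
#' Probability under the null that the rank-r (from the top) statistic
#' exceeds `x` -- equivalently, that at least r of the n statistics exceed
#' `x`. The default evaluation uses the exact binomial-tail identity
#' `P(at least r of n exceed x) = I_s(r, n - r + 1)` with `s = sf(x)`
#' (the regularized incomplete beta function), which remains accurate at
#' survival probabilities far below double-epsilon where direct quadrature of
#' the rank density cannot resolve the integral. `method = "quadrature"`
#' integrates [rank_density()] adaptively and is retained as a cross-check
#' for moderate tails.
#'
#' @inheritParams experimentwise_p_max
#' @param rank_from_top Rank counted from the most significant result.
#' @param method `"closed_form"` (default) or `"quadrature"`.
#' @param rel.tol Relative tolerance for the quadrature path.
#' @return Experiment-wise p-value in `[0, 1]`.
#' @export
experimentwise_p_rank <- function(x, rank_from_top, n_tests, model,
                                  method = c("closed_form", "quadrature"),
                                  rel.tol = 1e-10) {
  method <- match.arg(method)
  .check_rank(n_tests, rank_from_top)
  stopifnot(length(x) == 1L)
  .check_stat(x)
  if (method == "closed_form") {
    if (rank_from_top == 1) return(experimentwise_p_max(x, n_tests, model))
    s <- null_sf(model, x)
    return(stats::pbeta(s, rank_from_top, n_tests - rank_from_top + 1))
  }
  res <- tryCatch(
    stats::integrate(rank_density, lower = x, upper = Inf,
                     n_tests = n_tests, rank_from_top = rank_from_top,
                     model = model, rel.tol = rel.tol, abs.tol = 0),
    error = function(e) stop(sprintf(
      "quadrature of the rank density failed on [%g, Inf): %s",
      x, conditionMessage(e)), call. = FALSE))
  if (res$message != "OK")
    stop(sprintf("quadrature did not converge: %s (abs.error %.3g)",
                 res$message, res$abs.error), call. = FALSE)
  min(res$value, 1)
}

#' Per-test significance threshold for a target family-wise error rate
#'
#' Solves `1 - F(u)^n = alpha` for the statistic threshold `u`, i.e. the
#' value the top-ranked result must exceed for experiment-wise significance
#' at level `alpha` under the null model. The solution is obtained through
#' the model's inverse survival function at the per-test level
#' `1 - (1 - alpha)^(1/n)` (computed in log space), which is exact; a
#' root-finding pass over `u` would only re-derive the same quantile.
#'
#' Both scales are reported: the threshold on the statistic scale and its
#' p-value equivalent `exp(-u)`, the back-transform of `u = -ln(p)`
#' irrespective of which null model shapes the distribution of `u`. For the
#' [uniform_null()] model the p-scale threshold is exactly the Dunn-Sidak
#' per-test level. (For the chi-squared model, whose statistic is not a
#' `-ln p`, the p-scale entry is the same formal back-transform and is
#' reported for interface consistency.)
#'
#' @param alpha Target experiment-wise error rate, in (0, 1).
#' @param n_tests Number of tests (fractional effective counts accepted).
#' @param model A `null_model`.
#' @return List with `u_threshold`, `p_threshold = exp(-u_threshold)`, and
#'   `per_test_sf`, the per-test survival probability solved for.
#' @examples
#' threshold_for_fwer(0.05, 1e4, uniform_null())$p_threshold  # 5.13e-06
#' @export
threshold_for_fwer <- function(alpha, n_tests, model) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is.numeric(n_tests), length(n_tests) == 1L, n_tests >= 1)
  per_test_sf <- -expm1(log1p(-alpha) / n_tests)
  u <- null_quantile_sf(model, per_test_sf)
  list(u_threshold = u, p_threshold = exp(-u), per_test_sf = per_test_sf)
}

#' Expected null exceedances of a nominal significance level
#'
#' Expected number of tests, out of `n_tests` true nulls, whose nominal
#' p-value falls below `alpha` when the transformed statistics actually
#' follow `model`: `n_tests * sf(-ln(alpha))`. Under the uniform model this
#' is the familiar `n * alpha`; under a heavier-tailed fitted null it
#' quantifies the false-positive inflation incurred by assuming uniformity.
#'
#' @param alpha Nominal per-test significance level, in (0, 1); vectorized.
#' @param n_tests Number of tests.
#' @param model A u-scale `null_model` (gamma or beta).
#' @return Expected count(s).
#' @examples
#' expected_false_positives(1e-5, 1e6, uniform_null())                 # 10
#' expected_false_positives(1e-5, 1e6, gamma_null(1.1144, 0.9334))     # 26.6
#' @export
expected_false_positives <- function(alpha, n_tests, model) {
  stopifnot(is.numeric(alpha), all(alpha > 0), all(alpha < 1),
            is.numeric(n_tests), length(n_tests) == 1L, n_tests >= 1)
  n_tests * null_sf(model, -log(alpha))
}

#' Fold increase in expected null positives between two null models
#'
#' Ratio of [expected_false_positives()] under `model_b` to that under
#' `model_a` at the same nominal level: how many times more null findings a
#' study accrues if the true null is `model_b` while thresholds were set
#' assuming `model_a`.
#'
#' @param model_a Reference null model (typically [uniform_null()]).
#' @param model_b Alternative (e.g. fitted) null model.
#' @param alpha Nominal level(s), vectorized.
#' @return Fold increase(s), dimensionless.
#' @export
fold_increase <- function(model_a, model_b, alpha) {
  stopifnot(is.numeric(alpha), all(alpha > 0), all(alpha < 1))
  null_sf(model_b, -log(alpha)) / null_sf(model_a, -log(alpha))
}
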