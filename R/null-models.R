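# Parametric null models for the statistic tracked across a large-scale study.
# The gamma and beta models operate on the u = -ln(p) scale; the chi-squared
# model operates directly on the test-statistic scale.

#' Gamma null model for negative-log-transformed p-values
#'
#' Models `U = -ln(p)` under the global null as `Gamma(scale = b, shape = c)`.
#' With `scale = shape = 1` this is the unit exponential, i.e. uniformly
#' distributed null p-values, and every correction computed from the model
#' collapses to the classical Dunn-Sidak form. Scale above 1 or shape below 1
#' thickens (respectively thins) the tail relative to the uniform case, which
#' is how systematic miscalibration of nominal p-values (stratification,
#' relatedness, asymptotic approximations) manifests in practice.
#'
#' @param scale Scale parameter `b`, positive.
#' @param shape Shape parameter `c`, positive.
#' @return An object of class `c("gamma_null", "null_model")`.
#' @examples
#' m <- gamma_null(1.1144, 0.9334)
#' null_sf(m, 73.7553)
#' @seealso [uniform_null()], [beta_null()], [chisq_null()], [null_cdf()]
#' @export
gamma_null <- function(scale = 1, shape = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale),
            is.numeric(shape), length(shape) == 1L, is.finite(shape))
  if (scale <= 0 || shape <= 0)
    stop("gamma_null: 'scale' and 'shape' must be strictly positive", call. = FALSE)
  structure(list(scale = scale, shape = shape),
            class = c("gamma_null", "null_model"))
}

#' Uniform null model (unit exponential on the u scale)
#'
#' Convenience constructor for `gamma_null(1, 1)`: uniformly distributed null
#' p-values, the implicit assumption of the Bonferroni and Dunn-Sidak
#' corrections.
#'
#' @return A `gamma_null` object with both parameters equal to 1.
#' @export
uniform_null <- function() gamma_null(1, 1)

#' Beta null model for nominal p-values
#'
#' Models the null p-values themselves as `Beta(shape1, shape2)`;
#' `shape1 = shape2 = 1` recovers the uniform. Evaluation functions take the
#' transformed statistic `u = -ln(p)`, so the model slots into the same
#' order-statistic machinery as the gamma model.
#'
#' @param shape1 First beta shape (the conventional nu), positive.
#' @param shape2 Second beta shape (the conventional omega), positive.
#' @return An object of class `c("beta_null", "null_model")`.
#' @export
beta_null <- function(shape1 = 1, shape2 = 1) {
  stopifnot(is.numeric(shape1), length(shape1) == 1L, is.finite(shape1),
            is.numeric(shape2), length(shape2) == 1L, is.finite(shape2))
  if (shape1 <= 0 || shape2 <= 0)
    stop("beta_null: both shape parameters must be strictly positive", call. = FALSE)
  structure(list(shape1 = shape1, shape2 = shape2),
            class = c("beta_null", "null_model"))
}

#' Chi-squared null model for test statistics
#'
#' Models the per-test statistic directly as chi-squared with `df` degrees of
#' freedom (possibly fractional). Unlike the gamma and beta models, evaluation
#' is on the statistic's own scale, not on `u = -ln(p)`.
#'
#' @param df Degrees of freedom, positive real.
#' @return An object of class `c("chisq_null", "null_model")`.
#' @export
chisq_null <- function(df = 1) {
  stopifnot(is.numeric(df), length(df) == 1L, is.finite(df))
  if (df <= 0)
    stop("chisq_null: 'df' must be strictly positive", call. = FALSE)
  structure(list(df = df), class = c("chisq_null", "null_model"))
}

#' @export
print.gamma_null <- function(x, ...) {
  cat(sprintf("Gamma null model on u = -ln(p): scale b = %g, shape c = %g\n",
              x$scale, x$shape))
  invisible(x)
}

#' @export
print.beta_null <- function(x, ...) {
  cat(sprintf("Beta null model on p: shape1 = %g, shape2 = %g\n",
              x$shape1, x$shape2))
  invisible(x)
}

#' @export
print.chisq_null <- function(x, ...) {
  cat(sprintf("Chi-squared null model on the test statistic: df = %g\n", x$df))
  invisible(x)
}

.check_stat <- function(q, what = "q") {
  if (!is.numeric(q) || anyNA(q) || any(!is.finite(q)))
    stop(sprintf("'%s' must be finite numeric", what), call. = FALSE)
  if (any(q < 0))
    stop(sprintf("'%s' must be non-negative (it is a -ln(p) or test statistic)", what),
         call. = FALSE)
  q
}

#' Null-model density, distribution, survival and quantile functions
#'
#' Generic evaluation of a fitted or constructed [null model][gamma_null] at
#' statistic values `q` (`u = -ln p` for the gamma and beta models, the raw
#' statistic for the chi-squared model).
#'
#' `null_sf()` is evaluated directly in the upper tail (never as `1 - cdf`),
#' so survival probabilities retain full double-precision relative accuracy
#' down to the 1e-40 range required for genome-scale corrections.
#' `null_quantile_sf()` inverts it: the statistic whose survival probability
#' is `s`. `null_sim()` draws from the model on the same scale.
#'
#' @param model A `null_model` object.
#' @param q Vector of non-negative statistic values.
#' @param log,log.p Logical; return log density / log probability.
#' @param s Vector of survival probabilities in (0, 1).
#' @param n Number of random draws.
#' @return Numeric vector: densities, probabilities, quantiles or draws.
#' @examples
#' null_cdf(gamma_null(1, 1), log(2))   # exponential median: 0.5
#' null_sf(chisq_null(1), 3.841)        # ~0.05
#' @name null_eval
NULL

#' @rdname null_eval
#' @export
null_pdf <- function(model, q, log = FALSE) UseMethod("null_pdf")

#' @rdname null_eval
#' @export
null_cdf <- function(model, q, log.p = FALSE) UseMethod("null_cdf")

#' @rdname null_eval
#' @export
null_sf <- function(model, q, log.p = FALSE) UseMethod("null_sf")

#' @rdname null_eval
#' @export
null_quantile_sf <- function(model, s) UseMethod("null_quantile_sf")

#' @rdname null_eval
#' @export
null_sim <- function(model, n) UseMethod("null_sim")

#' @export
null_pdf.gamma_null <- function(model, q, log = FALSE) {
  .check_stat(q)
  stats::dgamma(q, shape = model$shape, scale = model$scale, log = log)
}

#' @export
null_cdf.gamma_null <- function(model, q, log.p = FALSE) {
  .check_stat(q)
  stats::pgamma(q, shape = model$shape, scale = model$scale, log.p = log.p)
}

#' @export
null_sf.gamma_null <- function(model, q, log.p = FALSE) {
  .check_stat(q)
  stats::pgamma(q, shape = model$shape, scale = model$scale,
                lower.tail = FALSE, log.p = log.p)
}

#' @export
null_quantile_sf.gamma_null <- function(model, s) {
  stopifnot(all(s > 0), all(s < 1))
  stats::qgamma(s, shape = model$shape, scale = model$scale, lower.tail = FALSE)
}

#' @export
null_sim.gamma_null <- function(model, n) {
  stats::rgamma(n, shape = model$shape, scale = model$scale)
}

# beta model: statistic is u = -ln p, p = exp(-u); F_U(u) = P(p > exp(-u))

# log(1 - exp(-u)) without loss at either end of the range
.log1mexp <- function(u) {
  ifelse(u < log(2), log(-expm1(-u)), log1p(-exp(-u)))
}

#' @export
null_pdf.beta_null <- function(model, q, log = FALSE) {
  .check_stat(q)
  # f_U(u) = exp(-v u) (1 - exp(-u))^(w-1) / B(v, w), in logs so the far
  # tail (where exp(-u) underflows) stays finite
  ld <- -model$shape1 * q + (model$shape2 - 1) * .log1mexp(q) -
    lbeta(model$shape1, model$shape2)
  if (log) ld else exp(ld)
}

#' @export
null_cdf.beta_null <- function(model, q, log.p = FALSE) {
  .check_stat(q)
  stats::pbeta(exp(-q), model$shape1, model$shape2,
               lower.tail = FALSE, log.p = log.p)
}

#' @export
null_sf.beta_null <- function(model, q, log.p = FALSE) {
  .check_stat(q)
  stats::pbeta(exp(-q), model$shape1, model$shape2, log.p = log.p)
}

#' @export
null_quantile_sf.beta_null <- function(model, s) {
  stopifnot(all(s > 0), all(s < 1))
  -log(stats::qbeta(s, model$shape1, model$shape2))
}

#' @export
null_sim.beta_null <- function(model, n) {
  -log(stats::rbeta(n, model$shape1, model$shape2))
}

#' @export
null_pdf.chisq_null <- function(model, q, log = FALSE) {
  .check_stat(q)
  stats::dchisq(q, df = model$df, log = log)
}

#' @export
null_cdf.chisq_null <- function(model, q, log.p = FALSE) {
  .check_stat(q)
  stats::pchisq(q, df = model$df, log.p = log.p)
}

#' @export
null_sf.chisq_null <- function(model, q, log.p = FALSE) {
  .check_stat(q)
  stats::pchisq(q, df = model$df, lower.tail = FALSE, log.p = log.p)
}

#' @export
null_quantile_sf.chisq_null <- function(model, s) {
  stopifnot(all(s > 0), all(s < 1))
  stats::qchisq(s, df = model$df, lower.tail = FALSE)
}

#' @export
null_sim.chisq_null <- function(model, n) stats::rchisq(n, df = model$df)

#' Negative-log transform of p-values
#'
#' Maps nominal p-values to the analysis scale `u = -ln(p)`. The transform is
#' order-reversing: the most significant test has the largest `u`. Exact zeros
#' are rejected rather than silently clamped, because a clamped zero would
#' corrupt the tail of any null model fitted downstream; use
#' [clamp_pvalues()] first if truncated p-values are unavoidable.
#'
#' @param p Numeric vector of p-values, each in (0, 1].
#' @return Numeric vector `-log(p)`, non-negative.
#' @examples
#' neglog_transform(c(1, exp(-1), 9.30e-33))
#' @export
neglog_transform <- function(p) {
  if (!is.numeric(p) || length(p) == 0L)
    stop("p-values must be a non-empty numeric vector", call. = FALSE)
  bad <- which(!is.finite(p) | p <= 0 | p > 1)
  if (length(bad))
    stop(sprintf(
      "invalid p-values (must be finite, in (0, 1]) at index %s%s",
      paste(utils::head(bad, 5L), collapse = ", "),
      if (length(bad) > 5L) sprintf(" and %d more", length(bad) - 5L) else ""),
      call. = FALSE)
  -log(p)
}

#' Clamp zero or underflowed p-values to a floor
#'
#' Explicit opt-in replacement of p-values at or below `floor` with `floor`.
#' This is deliberately separate from [neglog_transform()], which rejects
#' zeros: clamping changes the extreme tail and should be a visible analyst
#' decision, not a silent default.
#'
#' @param p Numeric vector of p-values.
#' @param floor Smallest p-value to allow; defaults to the smallest positive
#'   normalized double.
#' @return `p` with values below `floor` replaced by `floor`.
#' @export
clamp_pvalues <- function(p, floor = .Machine$double.xmin) {
  stopifnot(is.numeric(p), is.numeric(floor), floor > 0)
  pmax(p, floor)
}
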