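# Estimation of null-model parameters from the observed statistics and a
# parametric-bootstrap goodness-of-fit check.

.sample_moments <- function(x) {
  n <- length(x)
  if (n < 2L) stop("at least 2 values are required to estimate moments", call. = FALSE)
  mu <- mean(x)
  s2 <- stats::var(x)  # n - 1 denominator throughout
  list(mean = mu, var = s2, n = n)
}

#' Fit the gamma null model by matching moments
#'
#' Sets the gamma parameters so that the model mean and variance equal the
#' sample mean and variance of the transformed statistics:
#' `scale = var/mean`, `shape = mean^2/var`. The sample variance uses the
#' `n - 1` denominator; at the sample sizes typical of genome-scale studies
#' the distinction from `n` is far below reporting precision, but it is fixed
#' here for reproducibility.
#'
#' @param u Numeric vector of non-negative `-ln(p)` values, length >= 2.
#' @return A [gamma_null()] model with a `"fit"` attribute recording the
#'   method, sample size and log-likelihood.
#' @examples
#' set.seed(1)
#' fit_gamma_moments(rgamma(5000, shape = 0.93, scale = 1.11))
#' @seealso [fit_gamma_mle()], [fit_beta_moments()]
#' @export
fit_gamma_moments <- function(u) {
  .check_stat(u, "u")
  m <- .sample_moments(u)
  if (m$var <= 0)
    stop("zero sample variance: gamma moments are undefined for constant input",
         call. = FALSE)
  model <- gamma_null(scale = m$var / m$mean, shape = m$mean^2 / m$var)
  attr(model, "fit") <- list(method = "moments", n = m$n,
                             loglik = gamma_loglik(model, u))
  model
}

#' Fit the gamma null model by maximum likelihood
#'
#' Profile-likelihood fit: the shape `c` solves the score equation
#' `log(c) - digamma(c) = log(mean(u)) - mean(log(u))` (found by bracketed
#' root-finding), after which `scale = mean(u)/c`. All values must be
#' strictly positive since the log-likelihood involves `log(u)`.
#'
#' @param u Numeric vector of strictly positive `-ln(p)` values, length >= 2.
#' @param tol Convergence tolerance passed to [stats::uniroot()].
#' @return A [gamma_null()] model with a `"fit"` attribute; its log-likelihood
#'   is never below that of the moment fit on the same data.
#' @export
fit_gamma_mle <- function(u, tol = 1e-12) {
  .check_stat(u, "u")
  if (length(u) < 2L) stop("at least 2 values are required", call. = FALSE)
  if (any(u == 0))
    stop("maximum-likelihood gamma fit requires strictly positive values ",
         "(p-values of exactly 1 transform to u = 0)", call. = FALSE)
  s <- log(mean(u)) - mean(log(u))
  if (!is.finite(s) || s <= 0)
    stop(sprintf(
      "gamma MLE failed: log(mean) - mean(log) = %.3g is not positive (degenerate or constant input)",
      s), call. = FALSE)
  score <- function(cc) log(cc) - digamma(cc) - s
  # log(c) - digamma(c) is strictly decreasing from +Inf to 0, so a bracket
  # always exists; widen geometrically from the Ye-Chen-style starting point.
  c0 <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  lo <- c0; hi <- c0
  while (score(lo) < 0 && lo > 1e-12) lo <- lo / 4
  while (score(hi) > 0 && hi < 1e12) hi <- hi * 4
  root <- tryCatch(
    stats::uniroot(score, lower = lo, upper = hi, tol = tol),
    error = function(e) stop(sprintf(
      "gamma MLE did not converge: %s (bracket [%.3g, %.3g], s = %.6g)",
      conditionMessage(e), lo, hi, s), call. = FALSE))
  shape <- root$root
  model <- gamma_null(scale = mean(u) / shape, shape = shape)
  attr(model, "fit") <- list(method = "mle", n = length(u),
                             loglik = gamma_loglik(model, u),
                             score_residual = root$f.root)
  model
}

#' Gamma log-likelihood of a sample
#'
#' @param model A [gamma_null()] model.
#' @param u Data vector on the `-ln(p)` scale.
#' @return Scalar log-likelihood.
#' @export
gamma_loglik <- function(model, u) {
  stopifnot(inherits(model, "gamma_null"))
  sum(stats::dgamma(u, shape = model$shape, scale = model$scale, log = TRUE))
}

#' Fit the beta null model to p-values by matching moments
#'
#' Standard method-of-moments beta estimates from the mean `m` and variance
#' `v` of the p-values: both shapes are proportional to `m(1-m)/v - 1`. The
#' moments are only compatible with a beta distribution when `v < m(1-m)`;
#' otherwise an error is raised.
#'
#' @param p Numeric vector of p-values strictly inside (0, 1), length >= 2.
#' @return A [beta_null()] model with a `"fit"` attribute.
#' @export
fit_beta_moments <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p)))
    stop("'p' must be finite numeric", call. = FALSE)
  if (any(p <= 0 | p >= 1))
    stop("beta moment fit requires p-values strictly inside (0, 1)", call. = FALSE)
  m <- .sample_moments(p)
  if (m$var <= 0)
    stop("zero sample variance: beta moments are undefined for constant input",
         call. = FALSE)
  if (m$var >= m$mean * (1 - m$mean))
    stop(sprintf(
      "sample variance %.4g >= mean(1-mean) = %.4g: moments incompatible with a beta distribution",
      m$var, m$mean * (1 - m$mean)), call. = FALSE)
  common <- m$mean * (1 - m$mean) / m$var - 1
  model <- beta_null(shape1 = m$mean * common, shape2 = (1 - m$mean) * common)
  attr(model, "fit") <- list(method = "moments", n = m$n)
  model
}

# Re-estimate a model of the same family from statistics on its own scale;
# used by the parametric bootstrap so estimation noise is replicated.
.refit <- function(model, x) UseMethod(".refit")
.refit.gamma_null <- function(model, x) fit_gamma_moments(x)
.refit.beta_null  <- function(model, x) fit_beta_moments(exp(-x))
.refit.chisq_null <- function(model, x) chisq_null(df = mean(x))  # E[chi^2_v] = v

#' Parametric-bootstrap goodness-of-fit test for a null model
#'
#' Kolmogorov-Smirnov supremum distance between the empirical distribution of
#' the statistics and the fitted model, with the null distribution of the
#' distance obtained by parametric bootstrap: each replicate simulates a
#' sample of the same size from the fitted model, *re-estimates* the
#' parameters on that sample, and recomputes the distance. Re-estimation per
#' replicate is essential because the classical KS reference distribution is
#' invalid when parameters are estimated from the data being tested.
#'
#' @param x Statistics on the model's own scale (`-ln(p)` for the gamma and
#'   beta models).
#' @param model A fitted `null_model`.
#' @param n_boot Number of bootstrap replicates, at least 100 (default 999).
#' @return An object of class `htest` with the observed statistic and the
#'   bootstrap p-value `(1 + #{D* >= D}) / (n_boot + 1)`.
#' @export
goodness_of_fit <- function(x, model, n_boot = 999) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  .check_stat(x, "x")
  stopifnot(inherits(model, "null_model"))
  if (n_boot < 100)
    stop("n_boot must be at least 100 for a usable bootstrap p-value", call. = FALSE)
  n <- length(x)
  ks_stat <- function(xx, mm) {
    Fx <- null_cdf(mm, sort(xx))
    i <- seq_len(n)
    max(i / n - Fx, Fx - (i - 1) / n)
  }
  D <- ks_stat(x, model)
  Dstar <- vapply(seq_len(n_boot), function(b) {
    sim <- null_sim(model, n)
    refit <- tryCatch(.refit(model, sim), error = function(e) NULL)
    if (is.null(refit)) return(NA_real_)
    ks_stat(sim, refit)
  }, numeric(1))
  Dstar <- Dstar[!is.na(Dstar)]
  pval <- (1 + sum(Dstar >= D)) / (length(Dstar) + 1)
  structure(list(
    statistic = c(D = D),
    p.value = pval,
    method = "Parametric-bootstrap Kolmogorov-Smirnov goodness-of-fit",
    data.name = deparse(substitute(x)),
    n_boot = length(Dstar)),
    class = "htest")
}
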