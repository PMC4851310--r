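# Effective number of independent tests from the marker correlation matrix.
# Linkage disequilibrium makes nearby markers redundant; substituting the
# effective count for the raw test count in the family-wise formulas relaxes
# the independence assumption.

.check_corr_matrix <- function(R, tol = 1e-8) {
  if (!is.matrix(R) || !is.numeric(R) || nrow(R) != ncol(R))
    stop("a square numeric matrix is required", call. = FALSE)
  if (anyNA(R)) stop("correlation matrix contains missing values", call. = FALSE)
  if (max(abs(R - t(R))) > tol)
    stop("correlation matrix is not symmetric within tolerance", call. = FALSE)
  if (max(abs(diag(R) - 1)) > tol)
    stop("correlation matrix must have a unit diagonal", call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(nrow(R), 1))
    stop(sprintf("correlation matrix is not positive semi-definite (min eigenvalue %.3g)",
                 min(ev)), call. = FALSE)
  ev
}

.meff_estimate <- function(m_total, m_eff, method) {
  structure(list(m_total = m_total,
                 m_eff = min(max(m_eff, 1), m_total),
                 method = method),
            class = "meff_estimate")
}

#' @export
print.meff_estimate <- function(x, ...) {
  cat(sprintf("Effective number of independent tests: %.2f of %g markers (%s)\n",
              x$m_eff, x$m_total, x$method))
  invisible(x)
}

#' Effective number of tests from the eigenvalue variance
#'
#' Cheverud/Nyholt-style estimate from the pairwise marker correlation
#' matrix: `M_eff = 1 + (M - 1) * (1 - Var(lambda)/M)`, where `lambda` are
#' the eigenvalues of the matrix and the variance uses the `M - 1`
#' denominator. With fully independent markers every eigenvalue is 1 and
#' `M_eff = M`; with perfectly correlated markers one eigenvalue carries all
#' the variance and `M_eff = 1`. The result is clipped to `[1, M]`.
#'
#' @param R Square symmetric correlation matrix with unit diagonal, positive
#'   semi-definite within tolerance. By convention this is the r-squared
#'   matrix of the markers; state clearly in your workflow which was
#'   supplied, as the two give different estimates.
#' @param tol Validation tolerance.
#' @return A `meff_estimate` with fields `m_total`, `m_eff`, `method`.
#' @examples
#' meff_eigenvalue_variance(diag(50))$m_eff  # 50
#' @export
meff_eigenvalue_variance <- function(R, tol = 1e-8) {
  ev <- .check_corr_matrix(R, tol)
  M <- nrow(R)
  if (M == 1L) return(.meff_estimate(1L, 1, "eigenvalue_variance"))
  m_eff <- 1 + (M - 1) * (1 - stats::var(ev) / M)
  .meff_estimate(M, m_eff, "eigenvalue_variance")
}

#' Effective number of tests by principal-component counting (simpleM)
#'
#' The smallest number of leading eigenvalues of the correlation matrix
#' whose sum captures at least `variance_fraction` of the total eigenvalue
#' sum. Negative eigenvalues arising from numerical noise are truncated to
#' zero before accumulation.
#'
#' @inheritParams meff_eigenvalue_variance
#' @param variance_fraction Fraction of total variance to capture, in (0, 1];
#'   default 0.995 as conventional for this estimator.
#' @return A `meff_estimate`.
#' @export
meff_simple_pca <- function(R, variance_fraction = 0.995, tol = 1e-8) {
  stopifnot(is.numeric(variance_fraction), length(variance_fraction) == 1L,
            variance_fraction > 0, variance_fraction <= 1)
  ev <- .check_corr_matrix(R, tol)
  ev <- pmax(sort(ev, decreasing = TRUE), 0)
  k <- which(cumsum(ev) / sum(ev) >= variance_fraction - 1e-12)[1]
  .meff_estimate(nrow(R), k, sprintf("simpleM (%.3f)", variance_fraction))
}

#' Effective number of tests by linear interpolation between panel anchors
#'
#' When the genotype-level correlation matrix of a study is unavailable,
#' published effective-test counts for genotyping panels of known size can
#' anchor a first-order approximation: a least-squares line through
#' `(marker_count, m_eff)` pairs, evaluated at the study's marker count and
#' clipped to `[1, query_count]`.
#'
#' @param anchors Two-column matrix or data frame: marker counts and their
#'   corresponding effective counts; at least 2 rows with distinct marker
#'   counts.
#' @param query_count Marker count of the study in hand.
#' @return A `meff_estimate`.
#' @examples
#' meff_linear_interpolation(cbind(c(10, 20), c(5, 10)), 30)$m_eff  # 15
#' @export
meff_linear_interpolation <- function(anchors, query_count) {
  anchors <- as.matrix(anchors)
  if (!is.numeric(anchors) || ncol(anchors) != 2L || nrow(anchors) < 2L)
    stop("'anchors' must be >= 2 rows of (marker_count, m_eff)", call. = FALSE)
  if (length(unique(anchors[, 1])) < 2L)
    stop("anchor marker counts must not all coincide", call. = FALSE)
  stopifnot(is.numeric(query_count), length(query_count) == 1L, query_count >= 1)
  fit <- stats::lm.fit(cbind(1, anchors[, 1]), anchors[, 2])
  m_eff <- sum(fit$coefficients * c(1, query_count))
  .meff_estimate(query_count, m_eff, "linear_interpolation")
}

#' Read a marker correlation matrix from a text file
#'
#' Two dialects are supported: a dense whitespace-delimited matrix (one row
#' per line), and a sparse 3-column `(i, j, value)` listing with 0-based
#' marker indices, from which a symmetric matrix with unit diagonal is
#' assembled (unlisted off-diagonal entries default to 0).
#'
#' @param path File path.
#' @param format `"auto"` (3 columns with small integer indices is treated
#'   as sparse), `"dense"` or `"sparse"`.
#' @return A numeric matrix suitable for the `meff_*` estimators.
#' @export
read_correlation_matrix <- function(path, format = c("auto", "dense", "sparse")) {
  format <- match.arg(format)
  raw <- utils::read.table(path, header = FALSE)
  if (format == "auto") {
    looks_sparse <- ncol(raw) == 3L &&
      all(raw[[1]] == round(raw[[1]])) && all(raw[[2]] == round(raw[[2]])) &&
      (nrow(raw) != 3L)  # a 3x3 dense matrix stays dense
    format <- if (looks_sparse) "sparse" else "dense"
  }
  if (format == "dense") {
    R <- as.matrix(raw)
    dimnames(R) <- NULL
    storage.mode(R) <- "double"
    return(R)
  }
  i <- raw[[1]] + 1L; j <- raw[[2]] + 1L; v <- raw[[3]]
  M <- max(i, j)
  R <- diag(1, M)
  R[cbind(i, j)] <- v
  R[cbind(j, i)] <- v
  diag(R) <- 1
  R
}
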