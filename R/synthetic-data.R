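# Deterministic generators of synthetic association studies and correlation
# matrices, so every pipeline stage is testable without external data.

#' Specify a synthetic association study
#'
#' Describes a study of `n_markers` tests whose null p-values follow one of
#' three generating models, plus an optional handful of true signals with
#' extreme p-values. Signal p-values are drawn log-uniform on
#' `[1e-35, signal_p_ceiling]`, which spans the magnitudes seen at the top of
#' well-powered genome scans without hardcoding any particular hit. Overlap
#' between the null and signal ranges is permitted (a null draw may
#' occasionally undercut a weak signal).
#'
#' @param n_markers Number of markers.
#' @param null_kind `"uniform"`, `"beta"` (p ~ Beta(beta_nu, beta_omega)) or
#'   `"gamma_u"` (-ln p ~ Gamma(scale gamma_scale, shape gamma_shape)).
#' @param beta_nu,beta_omega Beta shapes (used when `null_kind = "beta"`).
#' @param gamma_scale,gamma_shape Gamma parameters (when `null_kind = "gamma_u"`).
#' @param n_signals Number of true signals, `<= n_markers`.
#' @param signal_p_ceiling Largest p-value a signal may take.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `synthetic_study_spec` object.
#' @export
synthetic_study_spec <- function(n_markers,
                                 null_kind = c("uniform", "beta", "gamma_u"),
                                 beta_nu = 1, beta_omega = 1,
                                 gamma_scale = 1, gamma_shape = 1,
                                 n_signals = 0, signal_p_ceiling = 1e-8,
                                 seed = 1L) {
  null_kind <- match.arg(null_kind)
  stopifnot(n_markers >= 1, n_markers == round(n_markers),
            beta_nu > 0, beta_omega > 0, gamma_scale > 0, gamma_shape > 0,
            n_signals >= 0, n_signals == round(n_signals),
            n_signals <= n_markers,
            signal_p_ceiling > 1e-35, signal_p_ceiling < 1,
            is.numeric(seed), length(seed) == 1L)
  structure(list(n_markers = as.integer(n_markers), null_kind = null_kind,
                 beta_nu = beta_nu, beta_omega = beta_omega,
                 gamma_scale = gamma_scale, gamma_shape = gamma_shape,
                 n_signals = as.integer(n_signals),
                 signal_p_ceiling = signal_p_ceiling, seed = as.integer(seed)),
            class = "synthetic_study_spec")
}

#' Generate a synthetic association table
#'
#' Produces an `association_table` per the spec: deterministic "rs"-prefixed
#' sequential marker ids with chromosomes assigned round-robin over 1..22 and
#' positions at a fixed stride (cosmetic, non-biological -- positions play no
#' role in any computation). Null p-values follow the spec's generating
#' model; the first `n_signals` markers carry signal p-values drawn
#' log-uniform below `signal_p_ceiling`. Output is identical for identical
#' spec and seed.
#'
#' @param spec A [synthetic_study_spec()].
#' @return An `association_table` with `n_markers` rows.
#' @examples
#' tbl <- generate_study(synthetic_study_spec(1000, "beta",
#'   beta_nu = 0.9, beta_omega = 1.1, seed = 7))
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  set.seed(spec$seed)
  n <- spec$n_markers
  p <- switch(spec$null_kind,
    uniform = stats::runif(n),
    beta = stats::rbeta(n, spec$beta_nu, spec$beta_omega),
    gamma_u = exp(-stats::rgamma(n, shape = spec$gamma_shape,
                                 scale = spec$gamma_scale)))
  # runif can in principle return exactly 0; map the open boundary away
  p[p == 0] <- .Machine$double.xmin
  if (spec$n_signals > 0) {
    lo <- log10(1e-35); hi <- log10(spec$signal_p_ceiling)
    p[seq_len(spec$n_signals)] <- 10^stats::runif(spec$n_signals, lo, hi)
  }
  out <- data.frame(
    marker_id = paste0("rs", seq_len(n)),
    chromosome = as.character(rep_len(1:22, n)),
    position = as.integer(seq_len(n)) * 1000L,
    p_value = p,
    stringsAsFactors = FALSE)
  class(out) <- c("association_table", "data.frame")
  out
}

#' Generate a block-diagonal exchangeable correlation matrix
#'
#' `n_blocks` independent blocks of `block_size` markers each, with constant
#' correlation `within_r2` inside a block and zero between blocks. Always a
#' valid correlation matrix (symmetric, unit diagonal, positive
#' semi-definite), serving as a fixture with known eigenvalues for the
#' effective-tests estimators: each block contributes one eigenvalue
#' `1 + (block_size - 1) * within_r2` and `block_size - 1` eigenvalues
#' `1 - within_r2`.
#'
#' @param n_blocks Number of blocks.
#' @param block_size Markers per block.
#' @param within_r2 Within-block correlation, in `[0, 1]`.
#' @return A numeric matrix of dimension `n_blocks * block_size`.
#' @export
generate_block_correlation <- function(n_blocks, block_size, within_r2) {
  stopifnot(n_blocks >= 1, block_size >= 1,
            is.numeric(within_r2), length(within_r2) == 1L)
  if (within_r2 < 0 || within_r2 > 1)
    stop("within_r2 must lie in [0, 1]", call. = FALSE)
  block <- matrix(within_r2, block_size, block_size)
  diag(block) <- 1
  kronecker(diag(n_blocks), block)
}
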