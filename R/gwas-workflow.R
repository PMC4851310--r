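# End-to-end workflow on an association-results table: load, filter out
# genome-wide-significant hits, fit the gamma null to the remainder, and
# report experiment-wise p-values for the top hits under both the uniform
# and the fitted null, optionally with an effective-tests adjustment.

#' Load an association-results table
#'
#' Reads a tab-separated association file with a header. Column names follow
#' the convention of association-scan outputs: marker id `SNP`, chromosome
#' `CHR`, 1-based position `BP` and p-value `P` (names configurable, extra
#' columns ignored). Gzip-compressed files are read transparently. Rows with
#' unparseable or out-of-range p-values, and duplicated marker ids, abort the
#' load with the offending data rows listed.
#'
#' @param path Path to the file (optionally `.gz`).
#' @param p_col,id_col,chr_col,pos_col Column names in the header.
#' @return A `data.frame` of class `association_table` with columns
#'   `marker_id`, `chromosome`, `position`, `p_value`. Positions are carried
#'   through untouched and never used in computation.
#' @export
load_association_table <- function(path, p_col = "P", id_col = "SNP",
                                   chr_col = "CHR", pos_col = "BP") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  for (col in c(p_col, id_col)) {
    if (!col %in% names(raw))
      stop(sprintf("required column '%s' missing from header (found: %s)",
                   col, paste(names(raw), collapse = ", ")), call. = FALSE)
  }
  p <- suppressWarnings(as.numeric(raw[[p_col]]))
  bad <- which(is.na(p) | !is.finite(p) | p <= 0 | p > 1)
  if (length(bad))
    stop(sprintf(
      "invalid p-values (must parse to a number in (0, 1]) at data row %s%s",
      paste(utils::head(bad, 5L), collapse = ", "),
      if (length(bad) > 5L) sprintf(" and %d more", length(bad) - 5L) else ""),
      call. = FALSE)
  ids <- raw[[id_col]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicated marker ids: %s%s",
                 paste(utils::head(dup, 5L), collapse = ", "),
                 if (length(dup) > 5L) " ..." else ""), call. = FALSE)
  out <- data.frame(
    marker_id = ids,
    chromosome = if (chr_col %in% names(raw)) raw[[chr_col]] else NA_character_,
    position = if (pos_col %in% names(raw))
      suppressWarnings(as.integer(raw[[pos_col]])) else NA_integer_,
    p_value = p,
    stringsAsFactors = FALSE)
  class(out) <- c("association_table", "data.frame")
  out
}

#' Write an association table in the same dialect the loader reads
#'
#' @param table An `association_table` (or data frame with its columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(table, path) {
  stopifnot(all(c("marker_id", "chromosome", "position", "p_value") %in% names(table)))
  out <- data.frame(SNP = table$marker_id, CHR = table$chromosome,
                    BP = table$position,
                    P = formatC(table$p_value, format = "e", digits = 15))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit the study-wide gamma null after excluding significant hits
#'
#' The gamma null should describe the tests consistent with no association,
#' so markers already past the genome-wide significance threshold are set
#' aside before fitting (strict comparison, `p < exclusion_threshold`). The
#' model is then fitted by matching moments to the `-ln p` of the retained
#' markers.
#'
#' @param table An `association_table`.
#' @param exclusion_threshold Genome-wide significance level used for the
#'   exclusion; conventional default `5.0e-8`.
#' @return List with the fitted `model`, `n_excluded`, and `n_used`.
#' @export
fit_study_null <- function(table, exclusion_threshold = 5.0e-8) {
  stopifnot(is.data.frame(table), "p_value" %in% names(table),
            exclusion_threshold > 0, exclusion_threshold < 1)
  keep <- table$p_value >= exclusion_threshold
  if (sum(keep) < 2L)
    stop("fewer than 2 markers retained after exclusion; cannot fit a null model",
         call. = FALSE)
  model <- fit_gamma_moments(neglog_transform(table$p_value[keep]))
  list(model = model, n_excluded = sum(!keep), n_used = sum(keep))
}

#' Analyze an association study end to end
#'
#' Fits (or accepts) a gamma null model, then reports for each of the
#' `top_k` most significant markers the experiment-wise p-value under the
#' uniform null (the Dunn-Sidak correction) and under the fitted gamma null,
#' each computed with `n` equal to the total marker count and -- when an
#' effective number of independent tests is supplied -- with `n = m_eff`.
#' An expected-false-positive table across nominal levels quantifies the
#' inflation implied by the fitted null relative to uniform.
#'
#' The test count used in the corrections defaults to the total number of
#' markers interrogated (the correction answers "how many tests were
#' performed"), while the fit uses the post-exclusion set (the fit answers
#' "what does the null look like"); set `use_post_exclusion_n = TRUE` to
#' correct with the post-exclusion count instead.
#'
#' @param table An `association_table`.
#' @param exclusion_threshold Passed to [fit_study_null()].
#' @param model Optional externally supplied [gamma_null()]; skips fitting.
#' @param m_eff Optional effective number of independent tests (real-valued
#'   allowed), e.g. from the `meff_*` estimators or literature.
#' @param top_k Number of top hits to report (default 10).
#' @param alphas Nominal levels for the expected-false-positive table.
#' @param use_post_exclusion_n Correct with the post-exclusion marker count.
#' @param gof_replicates Parametric-bootstrap replicates for the
#'   goodness-of-fit entry; 0 (default) skips the test, which is the right
#'   choice for multi-million-row tables where it is slow and the fit is
#'   assessed graphically instead.
#' @return A list of class `study_report`; see the JSON schema written by
#'   [write_report()].
#' @export
analyze_study <- function(table, exclusion_threshold = 5.0e-8, model = NULL,
                          m_eff = NULL, top_k = 10,
                          alphas = 10^-(2:8),
                          use_post_exclusion_n = FALSE,
                          gof_replicates = 0) {
  stopifnot(is.data.frame(table), nrow(table) >= 1)
  n_total <- nrow(table)
  fit <- NULL
  if (is.null(model)) {
    fit <- fit_study_null(table, exclusion_threshold)
    model <- fit$model
    n_excluded <- fit$n_excluded
  } else {
    stopifnot(inherits(model, "gamma_null"))
    n_excluded <- sum(table$p_value < exclusion_threshold)
  }
  n_corr <- if (use_post_exclusion_n) n_total - n_excluded else n_total
  n_corr <- max(n_corr, 1)

  gof <- NULL
  if (gof_replicates > 0) {
    keep <- table$p_value >= exclusion_threshold
    gof_res <- goodness_of_fit(neglog_transform(table$p_value[keep]), model,
                               n_boot = gof_replicates)
    gof <- list(statistic = unname(gof_res$statistic), p_value = gof_res$p.value)
  }

  ord <- order(table$p_value, seq_len(n_total))  # stable: ties broken by input order
  top <- table[ord[seq_len(min(top_k, n_total))], , drop = FALSE]
  u <- if (nrow(top)) neglog_transform(top$p_value) else numeric(0)
  unif <- uniform_null()
  hits <- data.frame(
    marker_id = top$marker_id,
    p = top$p_value,
    u = u,
    p_experimentwise_uniform = experimentwise_p_max(u, n_corr, unif),
    p_experimentwise_gamma = experimentwise_p_max(u, n_corr, model),
    stringsAsFactors = FALSE)
  if (!is.null(m_eff)) {
    stopifnot(is.numeric(m_eff), length(m_eff) == 1L, m_eff >= 1)
    hits$p_experimentwise_uniform_meff <- experimentwise_p_max(u, m_eff, unif)
    hits$p_experimentwise_gamma_meff <- experimentwise_p_max(u, m_eff, model)
  }

  efp <- data.frame(
    alpha = alphas,
    expected_uniform = expected_false_positives(alphas, n_corr, unif),
    expected_fitted = expected_false_positives(alphas, n_corr, model),
    stringsAsFactors = FALSE)
  efp$fold <- efp$expected_fitted / efp$expected_uniform

  structure(list(
    n_total = n_total,
    n_excluded = n_excluded,
    n_used_for_fit = n_total - n_excluded,
    n_correction = n_corr,
    exclusion_threshold = exclusion_threshold,
    fitted_model = list(scale_b = model$scale, shape_c = model$shape),
    gof = gof,
    m_eff_used = if (is.null(m_eff)) NULL else m_eff,
    top_hits = hits,
    expected_fp_table = efp),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study of %d markers (%d excluded at p < %.2e for fitting)\n",
              x$n_total, x$n_excluded, x$exclusion_threshold))
  cat(sprintf("Fitted gamma null: scale b = %.4f, shape c = %.4f\n",
              x$fitted_model$scale_b, x$fitted_model$shape_c))
  if (!is.null(x$m_eff_used))
    cat(sprintf("Effective number of independent tests: %.0f\n", x$m_eff_used))
  cat("Top hits:\n")
  print(format(x$top_hits, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Histogram of p-values as a diagnostic export
#'
#' Bin counts of the (optionally post-exclusion) p-values over equal-width
#' bins on `[0, 1]`; the counts sum to the number of markers retained. Useful
#' for eyeballing departures from the flat histogram expected under a
#' uniform null.
#'
#' @param table An `association_table`.
#' @param bins Number of equal-width bins (default 50).
#' @param exclusion_threshold Optional; if given, markers with
#'   `p < exclusion_threshold` are omitted, matching [fit_study_null()].
#' @return Data frame with `bin_lower`, `bin_upper`, `count`.
#' @export
pvalue_histogram <- function(table, bins = 50, exclusion_threshold = NULL) {
  stopifnot(is.data.frame(table), bins >= 1)
  p <- table$p_value
  if (!is.null(exclusion_threshold)) p <- p[p >= exclusion_threshold]
  breaks <- seq(0, 1, length.out = bins + 1)
  cnt <- tabulate(pmin(findInterval(p, breaks, rightmost.closed = TRUE), bins),
                  nbins = bins)
  data.frame(bin_lower = breaks[-(bins + 1)], bin_upper = breaks[-1], count = cnt)
}

.signif6 <- function(x) {
  if (is.list(x)) return(lapply(x, .signif6))
  if (is.numeric(x)) return(signif(x, 6))
  x
}

#' Write a study report as JSON or TSV
#'
#' JSON output has a stable key order and all numeric values rounded to 6
#' significant digits (written in full, so the file round-trips losslessly
#' at that precision through [read_report()]). TSV output is the top-hits
#' table only: one header line plus one line per hit.
#'
#' @param report A `study_report` from [analyze_study()].
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "study_report"))
  if (format == "tsv") {
    hits <- report$top_hits
    num <- vapply(hits, is.numeric, logical(1))
    hits[num] <- lapply(hits[num], function(v) formatC(v, format = "e", digits = 5))
    utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  payload <- unclass(report)
  payload$top_hits <- as.data.frame(.signif6(report$top_hits))
  payload$expected_fp_table <- as.data.frame(.signif6(report$expected_fp_table))
  payload <- .signif6(payload)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot write report to '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE, null = "null"), con)
  invisible(path)
}

#' Read back a JSON study report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return A list of class `study_report`.
#' @export
read_report <- function(path) {
  rep <- jsonlite::fromJSON(path)
  rep$top_hits <- as.data.frame(rep$top_hits)
  rep$expected_fp_table <- as.data.frame(rep$expected_fp_table)
  class(rep) <- "study_report"
  rep
}
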