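#' Subject-wise bootstrap confidence interval for the per-TR group median
#'
#' Resamples subjects with replacement `n_boot` times, recomputes the per-TR
#' median, and returns percentile interval bounds at each TR.
#'
#' @param series Subjects x TR numeric matrix.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param level Confidence level in percent (default 95).
#' @param seed Optional integer seed (deterministic result when given).
#' @return A tibble with columns `tr` (0-based), `median`, `ci_low`,
#'   `ci_high`.
#' @export
bootstrap_median_ci <- function(series, n_boot = 5000L, level = 95,
                                seed = NULL) {
  series <- as_subject_matrix(series)
  if (nrow(series) < 2L)
    abort("bootstrap of the group median needs at least 2 subjects")
  n_boot <- assert_count(n_boot, "n_boot")
  alpha <- (1 - level / 100) / 2
  ci <- with_stage_seed(seed,
    cpp_boot_median_ci(series, n_boot, alpha, 1 - alpha))
  tibble::tibble(tr = seq_len(ncol(series)) - 1L,
                 median = as.numeric(cpp_col_median(series)),
                 ci_low = ci[1, ], ci_high = ci[2, ])
}

#' Phase-randomized surrogate of a time series
#'
#' Takes the FFT, replaces the phase of every free frequency component with an
#' independent uniform draw (conjugate-symmetric assignment; DC and Nyquist
#' components are left untouched so the output is real and the mean and
#' amplitude spectrum are preserved exactly), and inverts the FFT. Surrogates
#' share the original autocorrelation but carry no stimulus-locked timing.
#'
#' @param x Numeric vector, length >= 4.
#' @param seed Optional integer seed.
#' @return A real-valued surrogate series of the same length.
#' @export
phase_randomize <- function(x, seed = NULL) {
  if (!is.numeric(x) || length(x) < 4L) abort("need a numeric series of length >= 4")
  if (!all(is.finite(x))) abort("series contains non-finite values")
  n <- length(x)
  f <- fft(x)
  half <- (n - 1L) %/% 2L
  with_stage_seed(seed, {
    phi <- runif(half, 0, 2 * pi)
    g <- f
    g[1L + seq_len(half)] <- Mod(f[1L + seq_len(half)]) * exp(1i * phi)
    g[n + 1L - seq_len(half)] <- Conj(g[1L + seq_len(half)])
    Re(fft(g, inverse = TRUE)) / n
  })
}

#' Null distribution of the maximum surrogate group median
#'
#' Each draw phase-randomizes every subject's series independently, computes
#' the per-TR median across subjects, and keeps the maximum over all TRs.
#' The 95th percentile of these maxima is the family-wise detection threshold.
#'
#' @param series Subjects x TR matrix.
#' @param n_phase Number of phase-randomization draws (default 5000).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_phase` maxima.
#' @export
null_max_median <- function(series, n_phase = 5000L, seed = NULL) {
  series <- as_subject_matrix(series)
  if (nrow(series) < 2L) abort("need at least 2 subjects")
  if (ncol(series) < 4L) abort("need at least 4 TRs")
  n_phase <- assert_count(n_phase, "n_phase")
  with_stage_seed(seed, as.numeric(cpp_null_max_median(series, n_phase)))
}

#' Identify significantly synchronized TRs
#'
#' A TR is synchronized when the lower bound of the bootstrap confidence
#' interval for the group median exceeds the `null_quantile`-th percentile of
#' the phase-randomization max-null — a one-sided, family-wise-corrected
#' test for positive median deflections. Bootstrap and phase-null use
#' independent seed substreams (`seed` and `seed + 1`), so changing `n_boot`
#' does not perturb the null.
#'
#' @param series Subjects x TR matrix (z-scored per subject).
#' @param n_boot,n_phase Resampling counts (defaults 5000).
#' @param level Bootstrap confidence level in percent.
#' @param null_quantile Null percentile for the threshold (default 95).
#' @param seed Integer base seed (default 1).
#' @param two_sided Also test mirrored negative deflections (off by default;
#'   the upper CI bound must then fall below the matching lower null
#'   percentile of minima). Detected negative TRs are reported separately.
#' @return An object of class `sync_result`: `significant_trs` (sorted
#'   0-based indices), `median_trace`, `ci_low`, `ci_high`, `null_threshold`,
#'   `null_maxima`, `n_boot`, `n_phase`, `seed`, `tr_offset`.
#' @export
find_sync_trs <- function(series, n_boot = 5000L, n_phase = 5000L, level = 95,
                          null_quantile = 95, seed = 1L, two_sided = FALSE) {
  series_m <- as_subject_matrix(series)
  ci <- bootstrap_median_ci(series_m, n_boot = n_boot, level = level,
                            seed = seed)
  null_max <- null_max_median(series_m, n_phase = n_phase,
                              seed = if (is.null(seed)) NULL else seed + 1L)
  thr <- as.numeric(quantile(null_max, null_quantile / 100))
  sig <- ci$tr[ci$ci_low > thr]
  neg <- integer(0)
  thr_lo <- NA_real_
  if (two_sided) {
    null_min <- with_stage_seed(if (is.null(seed)) NULL else seed + 2L,
      -as.numeric(cpp_null_max_median(-series_m, as.integer(n_phase))))
    thr_lo <- as.numeric(quantile(null_min, 1 - null_quantile / 100))
    neg <- ci$tr[ci$ci_high < thr_lo]
  }
  structure(list(significant_trs = sort(sig),
                 negative_trs = sort(neg),
                 median_trace = ci$median, ci_low = ci$ci_low,
                 ci_high = ci$ci_high, null_threshold = thr,
                 null_threshold_low = thr_lo, null_maxima = null_max,
                 n_boot = as.integer(n_boot), n_phase = as.integer(n_phase),
                 seed = seed,
                 tr_offset = attr(series, "tr_offset") %||% 0L),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf(
    "<sync_result> %d / %d TRs synchronized (threshold %.3f; %d bootstraps, %d phase draws)\n",
    length(x$significant_trs), length(x$median_trace), x$null_threshold,
    x$n_boot, x$n_phase))
  invisible(x)
}

#' Detect synchronized TRs for every (group, session, ROI) cell of a study
#'
#' Maps [find_sync_trs()] over an aligned study. Each cell receives a
#' deterministic seed derived from `seed` and its row index.
#'
#' @param aligned Tibble from [align_study()].
#' @param ... Passed to [find_sync_trs()] (resampling counts, level).
#' @param seed Base seed.
#' @return `aligned` with extra columns `sync` (list of `sync_result`) and
#'   `n_sync`.
#' @export
detect_sync_study <- function(aligned, ..., seed = 1L) {
  res <- purrr::imap(aligned$series, function(m, i)
    find_sync_trs(m, ..., seed = seed + 10L * i))
  aligned$sync <- res
  aligned$n_sync <- vapply(res, function(r) length(r$significant_trs), integer(1))
  aligned
}

as_subject_matrix <- function(series) {
  if (inherits(series, "subject_series") || is.matrix(series)) {
    m <- unclass(series)
    if (!is.numeric(m)) abort("series matrix must be numeric")
    return(m)
  }
  abort("`series` must be a subjects x TR matrix")
}
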