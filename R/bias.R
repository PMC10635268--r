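#' Map synchronized TRs to lagged movie bins
#'
#' Each synchronized TR `t` (0-based, in the analyzed post-drop frame) is
#' first restored to scan/movie time `m = t + tr_offset_seconds`, then
#' contributes the five one-second bins `[m - lag_hi, m - lag_lo)` — the
#' movie content 5-10 s before the response, accounting for hemodynamic
#' delay. Bins outside `[0, n_bins)` are discarded and the union of unique
#' bins is returned.
#'
#' @param t_star Integer vector of 0-based synchronized TR indices (may be
#'   empty).
#' @param n_bins Number of movie bins available for clipping.
#' @param tr_offset_seconds Seconds dropped at scan start (default 10).
#' @param lag_lo,lag_hi Hemodynamic lag window bounds in seconds (default
#'   5 and 10).
#' @return Sorted integer vector of unique 0-based bin indices.
#' @export
map_trs_to_bins <- function(t_star, n_bins, tr_offset_seconds = 10L,
                            lag_lo = 5L, lag_hi = 10L) {
  if (!(lag_hi > lag_lo && lag_lo >= 0)) abort("need lag_hi > lag_lo >= 0")
  if (length(t_star) == 0L) return(integer(0))
  if (any(t_star != round(t_star)) || any(t_star < 0))
    abort("`t_star` must hold non-negative integer TR indices")
  m <- as.integer(t_star) + as.integer(tr_offset_seconds)
  bins <- as.integer(outer(m - lag_hi, seq_len(lag_hi - lag_lo) - 1L, `+`))
  sort(unique(bins[bins >= 0L & bins < n_bins]))
}

#' Content bias of a bin set
#'
#' The fraction of unique mapped bins carrying the label (e.g. drug content).
#' An empty bin set has no defined bias and returns `NA`.
#'
#' @param bins Integer vector of unique 0-based bin indices.
#' @param track A [label_track()].
#' @return A fraction in \[0, 1\], or `NA_real_` for an empty set.
#' @export
compute_bias <- function(bins, track) {
  stopifnot(inherits(track, "label_track"))
  if (length(bins) == 0L) return(NA_real_)
  if (min(bins) < 0L || max(bins) >= nrow(track))
    abort("bin index outside the label track (mapping should have clipped)")
  mean(track$label[bins + 1L])
}

# shared permutation machinery: each column holds n_perm biases of TR sets
# of the requested size placed uniformly without replacement over valid_trs
random_bias_matrix <- function(n_sync, valid_trs, track, n_perm, tr_offset,
                               lag_lo, lag_hi) {
  m <- cpp_random_biases(as.integer(n_sync), as.integer(valid_trs),
                         as.integer(track$label), as.integer(n_perm),
                         as.integer(tr_offset), as.integer(lag_lo),
                         as.integer(lag_hi))
  colnames(m) <- names(n_sync)
  m
}

perm_pvalue <- function(obs, null) (1 + sum(abs(null) >= abs(obs))) / (length(null) + 1)

#' Permutation test for a group difference in content bias
#'
#' Statistic: `bias(A) - bias(B)`. The null redistributes each group's
#' synchronized TRs uniformly at random (without replacement) over the valid
#' analyzed TR range, independently per group, and recomputes the statistic;
#' the two-sided p-value uses the add-one correction
#' `(1 + #\{|null| >= |obs|\}) / (n_perm + 1)`.
#'
#' @param t_star_a,t_star_b 0-based synchronized TR sets for the two groups
#'   (both non-empty; an empty set yields an undefined result that is
#'   excluded from FDR).
#' @param track A [label_track()].
#' @param valid_trs Integer vector of admissible 0-based TR indices (the
#'   analyzed range).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Optional integer seed.
#' @param tr_offset_seconds,lag_lo,lag_hi See [map_trs_to_bins()].
#' @return A list of class `bias_test`: `bias_a`, `bias_b`, `statistic`,
#'   `p_value`, `null` (permutation statistics), counts and the seed. When
#'   either set is empty, `statistic` and `p_value` are `NA` and
#'   `defined = FALSE`.
#' @export
group_difference_test <- function(t_star_a, t_star_b, track, valid_trs,
                                  n_perm = 5000L, seed = NULL,
                                  tr_offset_seconds = 10L, lag_lo = 5L,
                                  lag_hi = 10L) {
  stopifnot(inherits(track, "label_track"))
  n_bins <- nrow(track)
  if (length(t_star_a) > length(valid_trs) || length(t_star_b) > length(valid_trs))
    abort("|T*| exceeds the number of valid TRs")
  bias_a <- compute_bias(map_trs_to_bins(t_star_a, n_bins, tr_offset_seconds,
                                         lag_lo, lag_hi), track)
  bias_b <- compute_bias(map_trs_to_bins(t_star_b, n_bins, tr_offset_seconds,
                                         lag_lo, lag_hi), track)
  if (is.na(bias_a) || is.na(bias_b)) {
    return(structure(list(bias_a = bias_a, bias_b = bias_b,
                          statistic = NA_real_, p_value = NA_real_,
                          null = numeric(0), defined = FALSE,
                          n_sync = c(a = length(t_star_a), b = length(t_star_b)),
                          n_perm = as.integer(n_perm), seed = seed),
                     class = "bias_test"))
  }
  obs <- bias_a - bias_b
  nm <- with_stage_seed(seed, random_bias_matrix(
    c(a = length(t_star_a), b = length(t_star_b)), valid_trs, track, n_perm,
    tr_offset_seconds, lag_lo, lag_hi))
  null <- nm[, "a"] - nm[, "b"]
  structure(list(bias_a = bias_a, bias_b = bias_b, statistic = obs,
                 p_value = perm_pvalue(obs, null), null = null, defined = TRUE,
                 n_sync = c(a = length(t_star_a), b = length(t_star_b)),
                 n_perm = as.integer(n_perm), seed = seed),
            class = "bias_test")
}

#' Permutation test for a group difference in the session delta of bias
#'
#' Statistic: `(bias_base - bias_follow)` in group A minus the same delta in
#' group B — positive when group A's content bias declines more between
#' sessions. All four TR sets are randomized independently under the null.
#'
#' @param t_star_list Named list with elements `a_base`, `a_follow`,
#'   `b_base`, `b_follow` of 0-based TR sets (all non-empty for a defined
#'   result).
#' @inheritParams group_difference_test
#' @return A `bias_test` list with per-cell biases in `bias_cells`.
#' @export
session_delta_test <- function(t_star_list, track, valid_trs, n_perm = 5000L,
                               seed = NULL, tr_offset_seconds = 10L,
                               lag_lo = 5L, lag_hi = 10L) {
  stopifnot(inherits(track, "label_track"))
  need <- c("a_base", "a_follow", "b_base", "b_follow")
  if (!all(need %in% names(t_star_list)))
    abort(sprintf("`t_star_list` must contain %s", paste(need, collapse = ", ")))
  n_bins <- nrow(track)
  if (any(lengths(t_star_list[need]) > length(valid_trs)))
    abort("|T*| exceeds the number of valid TRs")
  b <- vapply(t_star_list[need], function(ts)
    compute_bias(map_trs_to_bins(ts, n_bins, tr_offset_seconds, lag_lo, lag_hi),
                 track), numeric(1))
  if (anyNA(b)) {
    return(structure(list(bias_cells = b, statistic = NA_real_,
                          p_value = NA_real_, null = numeric(0),
                          defined = FALSE, n_sync = lengths(t_star_list[need]),
                          n_perm = as.integer(n_perm), seed = seed),
                     class = "bias_test"))
  }
  obs <- (b["a_base"] - b["a_follow"]) - (b["b_base"] - b["b_follow"])
  sizes <- lengths(t_star_list[need])
  nm <- with_stage_seed(seed, random_bias_matrix(
    sizes, valid_trs, track, n_perm, tr_offset_seconds, lag_lo, lag_hi))
  null <- (nm[, "a_base"] - nm[, "a_follow"]) -
    (nm[, "b_base"] - nm[, "b_follow"])
  structure(list(bias_cells = b, statistic = unname(obs),
                 p_value = perm_pvalue(obs, null), null = null, defined = TRUE,
                 n_sync = sizes, n_perm = as.integer(n_perm), seed = seed),
            class = "bias_test")
}

#' Benjamini-Hochberg FDR over defined tests
#'
#' Wraps [stats::p.adjust()] step-up correction; `NA` entries (undefined
#' biases from empty TR sets) are excluded from the family before correction
#' and flagged, not assigned p = 1.
#'
#' @param p_values Numeric vector of p-values in (0, 1\], possibly with `NA`.
#' @param q Discovery threshold (default 0.05).
#' @return Tibble with columns `p`, `q_value`, `discovery`, `excluded`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L)
    return(tibble::tibble(p = numeric(0), q_value = numeric(0),
                          discovery = logical(0), excluded = logical(0)))
  ok <- !is.na(p_values)
  if (any(p_values[ok] <= 0 | p_values[ok] > 1))
    abort("p-values must lie in (0, 1]")
  qv <- rep(NA_real_, length(p_values))
  qv[ok] <- p.adjust(p_values[ok], method = "BH")
  tibble::tibble(p = p_values, q_value = qv,
                 discovery = !is.na(qv) & qv < q, excluded = !ok)
}

#' ROI-wise bias tests over a study's detected synchronization
#'
#' Runs the baseline group-difference test and the group-by-session delta
#' test for every ROI, then applies BH-FDR across ROIs separately for each
#' test family. Group "a" is the first group level encountered (the clinical
#' group in the synthetic design).
#'
#' @param detected Tibble from [detect_sync_study()].
#' @param track A [label_track()].
#' @param n_perm Permutations per test (default 5000).
#' @param seed Base seed; per-ROI seeds are derived deterministically, with
#'   independent substreams for the baseline and delta tests.
#' @param q FDR threshold.
#' @param baseline_session,follow_session Session labels.
#' @param ... Lag-window arguments passed through to the tests.
#' @return Per-ROI tibble: biases per cell, baseline and delta statistics,
#'   p, q, discovery flags and sync counts.
#' @export
bias_tests <- function(detected, track, n_perm = 5000L, seed = 1L, q = 0.05,
                       baseline_session = "baseline",
                       follow_session = "followup", ...) {
  groups <- unique(detected$group)
  if (length(groups) != 2L) abort("need exactly 2 groups")
  rois <- sort(unique(detected$roi))
  n_tr <- length(detected$sync[[1]]$median_trace)
  valid_trs <- seq_len(n_tr) - 1L
  get_ts <- function(g, s, r) {
    i <- which(detected$group == g & detected$session == s & detected$roi == r)
    detected$sync[[i]]$significant_trs
  }
  rows <- purrr::map(rois, function(r) {
    ts <- list(a_base = get_ts(groups[1], baseline_session, r),
               a_follow = get_ts(groups[1], follow_session, r),
               b_base = get_ts(groups[2], baseline_session, r),
               b_follow = get_ts(groups[2], follow_session, r))
    base <- group_difference_test(ts$a_base, ts$b_base, track, valid_trs,
                                  n_perm = n_perm, seed = seed + 2L * r, ...)
    delta <- session_delta_test(ts, track, valid_trs, n_perm = n_perm,
                                seed = seed + 2L * r + 1L, ...)
    tibble::tibble(
      roi = r,
      bias_a_base = base$bias_a, bias_b_base = base$bias_b,
      bias_a_follow = unname(delta$bias_cells["a_follow"]),
      bias_b_follow = unname(delta$bias_cells["b_follow"]),
      stat_baseline = base$statistic, p_baseline = base$p_value,
      stat_delta = delta$statistic, p_delta = delta$p_value,
      n_sync_a_base = length(ts$a_base), n_sync_a_follow = length(ts$a_follow),
      n_sync_b_base = length(ts$b_base), n_sync_b_follow = length(ts$b_follow))
  })
  out <- dplyr::bind_rows(rows)
  fb <- fdr_bh(out$p_baseline, q)
  fd <- fdr_bh(out$p_delta, q)
  out$q_baseline <- fb$q_value
  out$disc_baseline <- fb$discovery
  out$q_delta <- fd$q_value
  out$disc_delta <- fd$discovery
  out
}
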