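#' Leave-one-out inter-subject correlation
#'
#' For each subject, the Pearson correlation between their series and the
#' mean series of the rest of the group.
#'
#' @param series Subjects x TR matrix (>= 3 subjects) with subject row names.
#' @return Tibble with columns `subject_id` and `r` (`NA` and a flag for
#'   degenerate constant series).
#' @export
loo_isc <- function(series) {
  m <- as_subject_matrix(series)
  n <- nrow(m)
  if (n < 3L) abort("leave-one-out ISC needs at least 3 subjects")
  total <- colSums(m)
  r <- vapply(seq_len(n), function(i) {
    rest <- (total - m[i, ]) / (n - 1)
    if (sd(m[i, ]) == 0 || sd(rest) == 0) return(NA_real_)
    cor(m[i, ], rest)
  }, numeric(1))
  tibble::tibble(subject_id = rownames(m) %||% as.character(seq_len(n)),
                 r = r, degenerate = is.na(r))
}

#' Fisher-z aggregate of correlations
#'
#' `tanh(mean(atanh(r)))` — the ROI-set aggregation used to form one ISC
#' score per subject.
#'
#' @param r_values Correlations, all strictly inside (-1, 1).
#' @return A single aggregated correlation.
#' @export
fisher_aggregate <- function(r_values) {
  if (length(r_values) == 0L || anyNA(r_values))
    abort("`r_values` must be non-empty and complete")
  if (any(abs(r_values) >= 1))
    abort("|r| = 1 gives an infinite Fisher z; clip upstream")
  tanh(mean(atanh(r_values)))
}

#' Per-subject aggregated ISC scores over an ROI set
#'
#' Computes leave-one-out ISC within each (group, session, ROI in `roi_set`)
#' cell and aggregates over the ROI set by Fisher z per subject-session.
#'
#' @param aligned Tibble from [align_study()] (or [detect_sync_study()]).
#' @param roi_set Integer ROI indices to aggregate (e.g. the OFC set).
#' @return Tibble: `group`, `session`, `subject_id`, `isc` (aggregate r).
#' @export
isc_scores <- function(aligned, roi_set) {
  sub <- dplyr::filter(aligned, .data$roi %in% roi_set)
  if (nrow(sub) == 0L) abort("`roi_set` matches no ROI in `aligned`")
  per_roi <- sub |>
    dplyr::mutate(isc = purrr::map(.data$series, loo_isc)) |>
    dplyr::select("group", "session", "roi", "isc") |>
    tidyr::unnest("isc")
  per_roi |>
    dplyr::group_by(.data$group, .data$session, .data$subject_id) |>
    dplyr::summarise(isc = fisher_aggregate(pmin(pmax(.data$r, -0.999999),
                                                 0.999999)),
                     .groups = "drop")
}

#' Correlate ISC scores with behavioral measures
#'
#' For each measure, computes the Pearson correlation (with two-sided p) of
#' the aggregate ISC score against the measure at baseline, and of the
#' session deltas (follow-up minus baseline) of both variables; BH-FDR is
#' applied across the whole tested family.
#'
#' @param isc Tibble from [isc_scores()] (one group's subjects, typically the
#'   clinical group).
#' @param behavior Behavior table with `subject_id`, `session`, and the
#'   measure columns.
#' @param measures Character vector of measure column names.
#' @param baseline_session,follow_session Session labels.
#' @param q FDR threshold.
#' @return Tibble: `measure`, `contrast` ("baseline" or "delta"), `n`, `r`,
#'   `p`, `q_value`, `discovery`.
#' @export
isc_behavior_correlations <- function(isc, behavior, measures,
                                      baseline_session = "baseline",
                                      follow_session = "followup", q = 0.05) {
  wide_isc <- isc |>
    dplyr::select("subject_id", "session", "isc") |>
    tidyr::pivot_wider(names_from = "session", values_from = "isc")
  rows <- purrr::map(measures, function(mm) {
    if (!mm %in% names(behavior)) abort(sprintf("measure `%s` not found", mm))
    wb <- behavior |>
      dplyr::select("subject_id", "session", dplyr::all_of(mm)) |>
      tidyr::pivot_wider(names_from = "session", values_from = dplyr::all_of(mm))
    d <- dplyr::inner_join(wide_isc, wb, by = "subject_id",
                           suffix = c("_isc", "_beh"))
    base <- d[c(paste0(baseline_session, "_isc"), paste0(baseline_session, "_beh"))]
    base <- base[stats::complete.cases(base), ]
    delta <- tibble::tibble(
      isc = d[[paste0(follow_session, "_isc")]] - d[[paste0(baseline_session, "_isc")]],
      beh = d[[paste0(follow_session, "_beh")]] - d[[paste0(baseline_session, "_beh")]])
    delta <- delta[stats::complete.cases(delta), ]
    one <- function(x, y, contrast) {
      if (length(x) < 4L)
        abort(sprintf("fewer than 4 paired observations for `%s` (%s)", mm, contrast))
      ct <- suppressWarnings(cor.test(x, y))
      tibble::tibble(measure = mm, contrast = contrast, n = length(x),
                     r = unname(ct$estimate),
                     # guard against numerically-zero p at |r| ~ 1
                     p = max(ct$p.value, .Machine$double.xmin))
    }
    dplyr::bind_rows(one(base[[1]], base[[2]], "baseline"),
                     one(delta$isc, delta$beh, "delta"))
  })
  out <- dplyr::bind_rows(rows)
  fdr <- fdr_bh(out$p, q)
  out$q_value <- fdr$q_value
  out$discovery <- fdr$discovery
  out
}

#' Pooled two-sample t statistic from summary statistics
#'
#' Classic equal-variance two-sample t with `df = n1 + n2 - 2`, computed from
#' group means, SDs and sizes — the form used for sample-profile tables.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @return Tibble with `t`, `df`, `p` (two-sided).
#' @export
pooled_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) abort("SDs must be positive")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  tibble::tibble(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Paired nonparametric test of session deltas
#'
#' Wilcoxon signed-rank test on paired differences: zero differences are
#' dropped, ties get mid-ranks, the p-value is exact when possible (n <= 25,
#' no ties) and otherwise uses the tie-corrected normal approximation.
#'
#' @param delta_values Numeric vector of paired differences.
#' @param alternative Test sidedness (default two-sided).
#' @return Tibble with `statistic` (positive-rank sum V), `n_nonzero`, `p`.
#' @export
paired_nonparametric <- function(delta_values, alternative = "two.sided") {
  d <- delta_values[!is.na(delta_values)]
  nz <- d[d != 0]
  if (length(nz) < 5L) abort("need at least 5 non-zero differences")
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(wilcox.test(d, mu = 0, alternative = alternative,
                                     exact = exact, correct = !exact))
  tibble::tibble(statistic = unname(wt$statistic), n_nonzero = length(nz),
                 p = wt$p.value)
}
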