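#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a synchronization result into a per-TR tibble
#'
#' @param x A `sync_result`.
#' @param ... Unused.
#' @return Tibble with `tr` (0-based, analyzed frame), `median`, `ci_low`,
#'   `ci_high`, `significant`.
#' @method tidy sync_result
#' @export
tidy.sync_result <- function(x, ...) {
  tibble::tibble(tr = seq_along(x$median_trace) - 1L,
                 median = x$median_trace, ci_low = x$ci_low,
                 ci_high = x$ci_high,
                 significant = (seq_along(x$median_trace) - 1L) %in%
                   x$significant_trs)
}

#' @rdname tidy.sync_result
#' @method glance sync_result
#' @export
glance.sync_result <- function(x, ...) {
  tibble::tibble(n_tr = length(x$median_trace),
                 n_significant = length(x$significant_trs),
                 null_threshold = x$null_threshold,
                 n_boot = x$n_boot, n_phase = x$n_phase)
}

#' Tidy a bias permutation test
#'
#' @param x A `bias_test`.
#' @param ... Unused.
#' @return One-row tibble of biases, statistic, and p-value.
#' @method tidy bias_test
#' @export
tidy.bias_test <- function(x, ...) {
  if (!is.null(x$bias_cells)) {
    dplyr::bind_cols(tibble::as_tibble(as.list(x$bias_cells)),
                     tibble::tibble(statistic = x$statistic,
                                    p_value = x$p_value, defined = x$defined))
  } else {
    tibble::tibble(bias_a = x$bias_a, bias_b = x$bias_b,
                   statistic = x$statistic, p_value = x$p_value,
                   defined = x$defined)
  }
}

#' @rdname fit_srm_k1
#' @param x An `srm_fit`.
#' @param ... Unused.
#' @method glance srm_fit
#' @export
glance.srm_fit <- function(x, ...) {
  tibble::tibble(n_subjects = length(x$weights), n_iter = x$n_iter,
                 converged = x$converged,
                 objective = x$objective_trace[x$n_iter])
}

#' Plot a synchronization result
#'
#' Median trace with its bootstrap confidence ribbon, the family-wise null
#' threshold, and detected TRs highlighted.
#'
#' @param object A `sync_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sync_result
#' @export
autoplot.sync_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tr, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$null_threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_point(data = dplyr::filter(d, .data$significant),
                        colour = "firebrick", size = 0.8) +
    ggplot2::labs(x = "TR (analyzed frame)", y = "group median",
                  title = sprintf("%d synchronized TRs",
                                  length(object$significant_trs))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Carpet table of synchronized TRs across ROIs
#'
#' Long table (one row per ROI x TR) flagging synchronized TRs together with
#' the label of the movie content they map back to — the tabular form of a
#' carpet plot.
#'
#' @param detected Tibble from [detect_sync_study()].
#' @param track A [label_track()].
#' @param ... Lag-window arguments for [map_trs_to_bins()].
#' @return Tibble: `group`, `session`, `roi`, `tr`, `mapped_label_fraction`.
#' @export
carpet_table <- function(detected, track, ...) {
  purrr::pmap(detected[c("group", "session", "roi", "sync")],
              function(group, session, roi, sync) {
    ts <- sync$significant_trs
    if (length(ts) == 0L) return(NULL)
    frac <- vapply(ts, function(t)
      compute_bias(map_trs_to_bins(t, nrow(track), ...), track), numeric(1))
    tibble::tibble(group = group, session = session, roi = roi, tr = ts,
                   mapped_label_fraction = frac)
  }) |> dplyr::bind_rows()
}

#' Plot per-ROI bias contrasts
#'
#' Dot plot of the baseline group difference and the group-by-session delta
#' statistic per ROI, discoveries highlighted.
#'
#' @param bias Tibble from [bias_tests()].
#' @return A ggplot.
#' @export
plot_bias <- function(bias) {
  d <- tidyr::pivot_longer(
    bias, c("stat_baseline", "stat_delta"),
    names_to = "test", values_to = "statistic") |>
    dplyr::mutate(discovery = ifelse(.data$test == "stat_baseline",
                                     .data$disc_baseline, .data$disc_delta))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$roi, y = .data$statistic,
                                  colour = .data$discovery)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~test, ncol = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 na.value = "grey80") +
    ggplot2::labs(x = "ROI", y = "bias statistic") +
    ggplot2::theme_minimal()
}
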