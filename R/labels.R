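#' Generate a binary movie-content label track
#'
#' Produces a per-second binary label track (1 = labeled content, e.g. drug;
#' 0 = other) as a stand-in for rater annotations of a movie. Labels are drawn
#' as alternating blocks with geometric lengths (mean `block_length_mean`
#' seconds), then adjusted bin-by-bin at block edges so the realized count of
#' labeled bins equals `round(drug_fraction * n_bins)` exactly.
#'
#' @param n_bins Number of one-second movie bins.
#' @param drug_fraction Target fraction of labeled bins, in \[0, 1\].
#' @param block_length_mean Mean block (scene) length in seconds.
#' @param seed Integer seed; the track is deterministic given the seed.
#' @param label_name Name recorded for the label column (metadata only).
#' @return A tibble of class `label_track` with columns `bin_start_second`
#'   (0-based integer) and `label` (0/1), and attribute `label_name`.
#' @examples
#' tr <- generate_label_track(1023, 464 / 1023, seed = 1)
#' sum(tr$label) # exactly 464
#' @export
generate_label_track <- function(n_bins, drug_fraction, block_length_mean = 15,
                                 seed = NULL, label_name = "drug") {
  n_bins <- assert_count(n_bins, "n_bins")
  drug_fraction <- assert_fraction(drug_fraction, "drug_fraction")
  if (!is.finite(block_length_mean) || block_length_mean < 1)
    abort("`block_length_mean` must be >= 1 second")
  target <- as.integer(round(drug_fraction * n_bins))
  labels <- with_stage_seed(seed, {
    if (target == 0L) {
      rep(0L, n_bins)
    } else if (target == n_bins) {
      rep(1L, n_bins)
    } else {
      state <- as.integer(runif(1) < drug_fraction)
      lab <- integer(0)
      while (length(lab) < n_bins) {
        len <- 1L + stats::rgeom(1, 1 / block_length_mean)
        lab <- c(lab, rep(state, len))
        state <- 1L - state
      }
      lab <- lab[seq_len(n_bins)]
      # flip bins at block boundaries until the labeled count is exact
      while (sum(lab) != target) {
        edges <- which(diff(lab) != 0L)              # boundary between i, i+1
        if (sum(lab) > target) {
          cand <- unique(c(edges[lab[edges] == 1L], edges[lab[edges + 1L] == 1L] + 1L))
          if (!length(cand)) cand <- which(lab == 1L)
          lab[cand[sample.int(length(cand), 1L)]] <- 0L
        } else {
          cand <- unique(c(edges[lab[edges] == 0L], edges[lab[edges + 1L] == 0L] + 1L))
          if (!length(cand)) cand <- which(lab == 0L)
          lab[cand[sample.int(length(cand), 1L)]] <- 1L
        }
      }
      lab
    }
  })
  new_label_track(labels, label_name)
}

new_label_track <- function(labels, label_name = "drug") {
  if (!all(labels %in% c(0L, 1L))) abort("labels must be binary 0/1")
  out <- tibble::tibble(bin_start_second = seq_along(labels) - 1L,
                        label = as.integer(labels))
  class(out) <- c("label_track", class(out))
  attr(out, "label_name") <- label_name
  out
}

#' Construct a label track from an explicit 0/1 vector
#'
#' @param labels Integer vector of 0/1 values, one per one-second bin.
#' @param label_name Name recorded for the label (metadata only).
#' @return A `label_track` tibble.
#' @export
label_track <- function(labels, label_name = "drug") {
  new_label_track(labels, label_name)
}

#' Median-split a per-bin scalar feature into a binary label track
#'
#' Control analyses (loudness, brightness) label each one-second bin high/low
#' by a median split of a per-bin scalar feature.
#'
#' @param feature Numeric vector, one value per one-second bin.
#' @param label_name Name for the resulting label, e.g. `"loudness_high"`.
#' @return A `label_track` tibble where `label = 1` marks bins strictly above
#'   the median.
#' @export
median_split_labels <- function(feature, label_name = "feature_high") {
  if (!is.numeric(feature) || anyNA(feature))
    abort("`feature` must be a numeric vector without missing values")
  new_label_track(as.integer(feature > stats::median(feature)), label_name)
}

#' Read / write a label track as two-column TSV
#'
#' The on-disk layout is `bin_start_second` (0-based integer) and `label`
#' (0/1); feature tracks use the same layout with a float column.
#'
#' @param track A `label_track` tibble.
#' @param path File path.
#' @return `write_label_track()` returns `path` invisibly;
#'   `read_label_track()` returns a `label_track`.
#' @export
write_label_track <- function(track, path) {
  stopifnot(inherits(track, "label_track"))
  readr::write_tsv(tibble::as_tibble(track)[c("bin_start_second", "label")], path)
  invisible(path)
}

#' @rdname write_label_track
#' @param label_name Label name to attach on read.
#' @export
read_label_track <- function(path, label_name = "drug") {
  x <- readr::read_tsv(path, col_types = readr::cols(
    bin_start_second = readr::col_integer(), label = readr::col_integer()))
  if (!identical(x$bin_start_second, seq_len(nrow(x)) - 1L))
    abort("label track bins must be contiguous 0-based seconds")
  new_label_track(x$label, label_name)
}
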