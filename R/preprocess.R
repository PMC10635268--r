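#' Drop initial TRs from a voxel-by-TR matrix
#'
#' Removes the first `n` TRs (large stimulus-onset transients) and records the
#' offset in the `"tr_offset"` attribute so downstream TR-to-movie-time
#' mapping stays correct: analyzed TR index `t` (0-based) corresponds to scan
#' second `t + tr_offset`.
#'
#' @param x Numeric matrix, voxels x TRs (a vector is treated as one voxel).
#' @param n Number of initial TRs to remove.
#' @return The truncated matrix with attribute `tr_offset` (accumulating over
#'   repeated calls).
#' @export
drop_initial_trs <- function(x, n = 10L) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    abort("`n` must be a single non-negative integer")
  n <- as.integer(n)
  if (ncol(x) <= n)
    abort(sprintf("series has %d TRs, cannot drop %d", ncol(x), n))
  off <- attr(x, "tr_offset") %||% 0L
  if (n == 0L) return(x)
  out <- x[, -seq_len(n), drop = FALSE]
  attr(out, "tr_offset") <- off + n
  out
}

# discrete-cosine drift basis with all frequencies below 1/period Hz
dct_basis <- function(n, tr_seconds, period) {
  k_max <- floor(2 * n * tr_seconds / period)
  if (k_max < 1L) return(matrix(numeric(0), n, 0))
  tt <- 2 * (seq_len(n) - 1L) + 1L
  vapply(seq_len(k_max), function(k) cos(pi * k * tt / (2 * n)), numeric(n))
}

#' Expand motion confounds to the 24-parameter set
#'
#' Builds squares, backward-difference derivatives, and squared derivatives of
#' the six motion parameters; any additional columns (e.g. `csf`) are passed
#' through unchanged.
#'
#' @param confounds TR x k matrix (or data frame) whose first six columns are
#'   motion parameters.
#' @return TR x (4*6 + extras) numeric matrix.
#' @export
expand_confounds <- function(confounds) {
  confounds <- as.matrix(confounds)
  if (ncol(confounds) < 6L) abort("expected at least 6 motion columns")
  mot <- confounds[, 1:6, drop = FALSE]
  extra <- confounds[, -(1:6), drop = FALSE]
  d <- rbind(0, diff(mot))
  out <- cbind(mot, mot^2, d, d^2, extra)
  colnames(out) <- c(paste0("m", 1:6), paste0("m", 1:6, "_sq"),
                     paste0("m", 1:6, "_d"), paste0("m", 1:6, "_dsq"),
                     colnames(extra) %||% character(0))
  out
}

#' Clean voxel time series in a single least-squares step
#'
#' Jointly regresses out an intercept, a linear trend, a discrete-cosine
#' high-pass drift basis (all frequencies below `1/highpass_period` Hz) and
#' any supplied confound columns in one projection, then z-scores each voxel
#' row. The joint fit guarantees the residual is exactly orthogonal to every
#' nuisance column — sequential filtering could reintroduce drift.
#'
#' @param x Voxels x TR numeric matrix (a vector is treated as one voxel).
#' @param confounds Optional TR x k numeric matrix of confound regressors.
#' @param tr_seconds TR in seconds.
#' @param highpass_period High-pass cutoff period in seconds (default 140).
#' @param standardize Z-score rows after projection (default `TRUE`); set
#'   `FALSE` to inspect the raw residual, e.g. to measure the filter's
#'   transfer function.
#' @return Cleaned matrix of the same shape, `tr_offset` attribute preserved.
#' @export
clean_series <- function(x, confounds = NULL, tr_seconds = 1,
                         highpass_period = 140, standardize = TRUE) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  if (!all(is.finite(x))) abort("series contains non-finite values")
  design <- cbind(1, seq_len(n) - (n + 1) / 2,
                  dct_basis(n, tr_seconds, highpass_period))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n)
      abort(sprintf("confounds have %d rows but series has %d TRs",
                    nrow(confounds), n))
    if (!all(is.finite(confounds))) abort("confounds contain non-finite values")
    design <- cbind(design, confounds)
  }
  qrd <- qr(design)
  res <- t(qr.resid(qrd, t(x)))
  res <- zap_spanned_rows(res, x)
  out <- if (standardize) zscore_rows(res) else res
  attr(out, "tr_offset") <- attr(x, "tr_offset")
  out
}

# rows whose residual is numerically zero relative to the input lie inside
# the projected-out span; zero them so z-scoring cannot amplify roundoff
zap_spanned_rows <- function(res, x) {
  in_scale <- pmax(apply(x, 1, function(r) max(abs(r))), .Machine$double.eps)
  res_scale <- apply(res, 1, function(r) max(abs(r)))
  dead <- res_scale < 1e-10 * in_scale
  if (any(dead)) res[dead, ] <- 0
  res
}

#' Extract a subject's global component
#'
#' Averages all retained voxels (across all ROIs) at each TR and z-scores the
#' result — a proxy for stimulus-driven global arousal/engagement.
#'
#' @param x A voxels x TR matrix, or a list of such matrices (one per ROI),
#'   for one subject.
#' @return A z-scored TR-length numeric vector.
#' @export
extract_global_component <- function(x) {
  if (is.list(x)) x <- do.call(rbind, x)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (nrow(x) < 1L || ncol(x) < 2L) abort("need at least one voxel series")
  zscore(colMeans(x))
}

#' Selective component: residualize voxels on the global component
#'
#' Regresses each voxel's series onto the subject's global component (with
#' intercept) and z-scores the residual, removing shared arousal so that
#' synchronization reflects selective, content-locked responses.
#'
#' @param x Voxels x TR matrix (a vector is treated as one voxel).
#' @param g Global component vector of matching length.
#' @return Z-scored residual matrix; `tr_offset` attribute preserved.
#' @export
selective_component <- function(x, g) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (length(g) != ncol(x))
    abort(sprintf("global component length %d != %d TRs", length(g), ncol(x)))
  qrd <- qr(cbind(1, g))
  out <- zscore_rows(zap_spanned_rows(t(qr.resid(qrd, t(x))), x))
  attr(out, "tr_offset") <- attr(x, "tr_offset")
  out
}

#' Run the full custom preprocessing chain over a study
#'
#' Per subject and session: drop the first `n_drop` TRs, regress confounds
#' (24-parameter motion expansion + CSF) jointly with the high-pass drift
#' basis and a linear trend, z-score, extract the global component from all
#' cleaned voxels, and keep the z-scored selective (global-residualized)
#' component per voxel. Order is fixed: drop, clean, global, selective.
#'
#' @param study A `synthetic_study` (or any list with compatible `voxel` and
#'   `confounds` tibbles).
#' @param n_drop Initial TRs to drop (default 10).
#' @param highpass_period High-pass period in seconds (default 140).
#' @return The study with `voxel$data` replaced by cleaned selective-component
#'   matrices (attribute `tr_offset = n_drop`), plus a `global` tibble of
#'   per-subject-session global components.
#' @export
preprocess_study <- function(study, n_drop = 10L, highpass_period = 140) {
  vox <- study$voxel
  glob_rows <- list()
  for (key in split(seq_len(nrow(vox)),
                    paste(vox$group, vox$session, vox$subject_id))) {
    first <- key[1L]
    conf <- study$confounds$confounds[[which(
      study$confounds$group == vox$group[first] &
        study$confounds$session == vox$session[first] &
        study$confounds$subject_id == vox$subject_id[first])]]
    conf <- expand_confounds(conf)[-seq_len(n_drop), , drop = FALSE]
    stacked <- do.call(rbind, lapply(vox$data[key], drop_initial_trs, n = n_drop))
    attr(stacked, "tr_offset") <- as.integer(n_drop)
    cleaned <- clean_series(stacked, conf, tr_seconds = study$config$tr_seconds,
                            highpass_period = highpass_period)
    g <- extract_global_component(cleaned)
    sel <- selective_component(cleaned, g)
    row0 <- 0L
    for (j in seq_along(key)) {
      nv <- nrow(vox$data[[key[j]]])
      m <- sel[row0 + seq_len(nv), , drop = FALSE]
      attr(m, "tr_offset") <- as.integer(n_drop)
      vox$data[[key[j]]] <- m
      row0 <- row0 + nv
    }
    glob_rows[[length(glob_rows) + 1L]] <- tibble::tibble(
      group = vox$group[first], session = vox$session[first],
      subject_id = vox$subject_id[first], global = list(g))
  }
  study$voxel <- vox
  study$global <- dplyr::bind_rows(glob_rows)
  study$preprocessed <- list(n_drop = as.integer(n_drop),
                             highpass_period = highpass_period)
  study
}
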