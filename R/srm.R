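#' Fit a single-component shared response model for one ROI
#'
#' Alternating least squares for the model `X_i ~ w_i s` with unit-norm
#' per-subject weight vectors `w_i` (voxel space) and one shared time series
#' `s`: given `s`, `w_i = X_i s / ||X_i s||`; given the weights,
#' `s = mean_i(w_i' X_i)`. Initialization is deterministic — the leading
#' right singular vector of the subject-stacked data — and the sign of `s` is
#' fixed so that its correlation with the across-subject mean voxel signal is
#' non-negative. Voxel counts may differ between subjects.
#'
#' @param x_list List of voxel x TR matrices, one per subject (>= 2 subjects,
#'   equal TR counts).
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Iteration cap.
#' @return An object of class `srm_fit`: `shared_series` (TR vector),
#'   `weights` (list of unit vectors), `objective_trace` (non-increasing),
#'   `converged`, `n_iter`.
#' @export
fit_srm_k1 <- function(x_list, tol = 1e-8, max_iter = 100L) {
  if (!is.list(x_list) || length(x_list) < 2L)
    abort("need at least 2 subjects")
  x_list <- lapply(x_list, function(m) if (is.vector(m)) matrix(m, 1L) else m)
  n_tr <- unique(vapply(x_list, ncol, integer(1)))
  if (length(n_tr) != 1L) abort("all subjects must share the TR count")
  if (any(vapply(x_list, function(m) all(m == 0), logical(1))))
    abort("all-zero subject matrix")
  stacked <- do.call(rbind, x_list)
  s <- leading_right_singular(stacked)
  n <- length(x_list)
  obj <- function(w_list, s)
    sum(vapply(seq_len(n), function(i)
      sum((x_list[[i]] - w_list[[i]] %o% s)^2), numeric(1)))
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  w_list <- NULL
  for (it in seq_len(max_iter)) {
    w_list <- lapply(x_list, function(X) {
      v <- as.numeric(X %*% s)
      nv <- sqrt(sum(v^2))
      if (nv == 0) abort("degenerate weight update (X s = 0)")
      v / nv
    })
    s <- Reduce(`+`, lapply(seq_len(n), function(i)
      as.numeric(crossprod(x_list[[i]], w_list[[i]])))) / n
    cur <- obj(w_list, s)
    trace <- c(trace, cur)
    if (is.finite(prev) && abs(prev - cur) <= tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  mean_vox <- colMeans(stacked)
  if (sd(mean_vox) > 0 && sd(s) > 0 && cor(s, mean_vox) < 0) {
    s <- -s
    w_list <- lapply(w_list, function(w) -w)
  }
  structure(list(shared_series = s, weights = w_list,
                 objective_trace = trace, converged = converged,
                 n_iter = length(trace)),
            class = "srm_fit")
}

# leading right singular vector; goes through the smaller Gram matrix
leading_right_singular <- function(m) {
  if (nrow(m) <= ncol(m)) {
    u <- eigen(tcrossprod(m), symmetric = TRUE)$vectors[, 1]
    v <- as.numeric(crossprod(m, u))
    v / sqrt(sum(v^2))
  } else {
    as.numeric(eigen(crossprod(m), symmetric = TRUE)$vectors[, 1])
  }
}

#' Project subjects onto the fitted shared component
#'
#' Subject `i`'s ROI time series is `w_i' X_i`, z-scored. All downstream
#' analyses (synchronization, ISC) operate on these per-subject projections.
#'
#' @param fit An `srm_fit`.
#' @param x_list The per-subject voxel x TR matrices the fit corresponds to.
#' @return A subjects x TR matrix of z-scored series (class
#'   `subject_series`), row names taken from `names(x_list)` when present.
#' @export
project_subjects <- function(fit, x_list) {
  stopifnot(inherits(fit, "srm_fit"))
  x_list <- lapply(x_list, function(m) if (is.vector(m)) matrix(m, 1L) else m)
  if (length(x_list) != length(fit$weights))
    abort("subject count differs from the fit")
  rows <- lapply(seq_along(x_list), function(i) {
    if (nrow(x_list[[i]]) != length(fit$weights[[i]]))
      abort(sprintf("subject %d: %d voxels but %d weights", i,
                    nrow(x_list[[i]]), length(fit$weights[[i]])))
    as.numeric(fit$weights[[i]] %*% x_list[[i]])
  })
  out <- zscore_rows(do.call(rbind, rows))
  rownames(out) <- names(x_list)
  class(out) <- c("subject_series", class(out))
  out
}

#' Align a preprocessed study: one z-scored series per subject, ROI, session
#'
#' Fits the single-component shared response model separately per
#' (group, session, ROI) and projects each subject, reducing multi-voxel data
#' to a subjects x TR matrix per cell.
#'
#' @param study A preprocessed study (see [preprocess_study()]).
#' @return A tibble with columns `group`, `session`, `roi`, `series`
#'   (list of subjects x TR matrices with subject row names) and
#'   `srm_converged`.
#' @export
align_study <- function(study) {
  vox <- study$voxel
  cells <- dplyr::distinct(vox, .data$group, .data$session, .data$roi)
  out <- purrr::pmap(cells, function(group, session, roi) {
    sel <- vox$group == group & vox$session == session & vox$roi == roi
    xs <- vox$data[sel]
    names(xs) <- vox$subject_id[sel]
    fit <- fit_srm_k1(xs)
    series <- project_subjects(fit, xs)
    attr(series, "tr_offset") <- attr(xs[[1]], "tr_offset") %||% 0L
    tibble::tibble(group = group, session = session, roi = roi,
                   series = list(series), srm_converged = fit$converged)
  })
  dplyr::bind_rows(out)
}
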