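#' Family-wise error calibration experiment under the global null
#'
#' Repeatedly simulates one group and session with all stimulus amplitudes
#' zero (shared arousal, confound leakage, drift and noise retained), runs
#' the full pipeline (preprocess, SRM alignment, synchronization detection)
#' and records, per ROI, whether any TR was declared synchronized. Under
#' correct family-wise control the per-ROI rate of any detection stays at or
#' below the nominal level.
#'
#' @param n_reps Number of replicate simulated datasets.
#' @param seed Base seed; replicate r uses `seed + r` for the data and a
#'   widely spaced derived seed for the detection resampling.
#' @param n_subjects Group size.
#' @param n_rois ROIs per replicate.
#' @param n_trs Scan TRs before the 10-TR drop.
#' @param voxels_per_roi Voxels per ROI.
#' @param n_boot,n_phase Detection resampling counts.
#' @return A list: `rate` (fraction of ROI analyses with any detection),
#'   `hits`, `n_units`, and the binomial bound `bound = 0.05 + 2 * SE`.
#' @export
calibration_experiment <- function(n_reps = 200L, seed = 1L,
                                   n_subjects = 15L, n_rois = 20L,
                                   n_trs = 310L, voxels_per_roi = 4L,
                                   n_boot = 500L, n_phase = 1000L) {
  hits <- 0L
  units <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(
      n_subjects_per_group = c(n_subjects, 2L), n_rois = n_rois,
      voxels_per_roi = voxels_per_roi, n_trs = n_trs,
      drug_locked_rois = integer(0), ofc_rois = 1L,
      drug_amplitude = matrix(0, 2, 2), nondrug_amplitude = matrix(0, 2, 2),
      seed = seed + r)
    study <- simulate_study(cfg)
    study$voxel <- dplyr::filter(study$voxel, .data$group == "g1",
                                 .data$session == "baseline")
    study$confounds <- dplyr::filter(study$confounds, .data$group == "g1",
                                     .data$session == "baseline")
    det <- detect_sync_study(align_study(preprocess_study(study)),
                             n_boot = n_boot, n_phase = n_phase,
                             seed = seed + 100000L + 1000L * r)
    hits <- hits + sum(det$n_sync > 0L)
    units <- units + nrow(det)
  }
  se <- sqrt(0.05 * 0.95 / units)
  list(rate = hits / units, hits = hits, n_units = units,
       bound = 0.05 + 2 * se)
}

#' Planted-effect recovery experiment
#'
#' Repeatedly simulates the two-group, two-session design with the clinical
#' group's drug amplitude dropping from 1.5 to 0.5 noise-SD across sessions
#' in the planted ROIs while the comparison group stays flat, runs the full
#' pipeline, and scores (i) the session-delta bias test against the planted
#' ROI set (sensitivity / specificity at BH q < 0.05) and (ii) recovery of
#' the planted ISC-delta / craving-delta correlation (95% CI coverage via
#' Fisher z).
#'
#' @param n_reps Number of replicates.
#' @param seed Base seed (per-replicate seeds derived as in
#'   [calibration_experiment()]).
#' @param n_subjects Subjects per group.
#' @param n_rois Total ROIs (the first `n_planted` are drug-locked).
#' @param n_planted Planted drug-locked ROIs (also the "OFC" ISC set).
#' @param n_trs Scan TRs before the drop.
#' @param voxels_per_roi Voxels per ROI.
#' @param n_boot,n_phase,n_perm Resampling counts.
#' @param q FDR threshold.
#' @return A list: `sensitivity`, `specificity`, `coverage`, `mean_delta_r`,
#'   `planted_rho`, and the per-replicate tibble `replicates`.
#' @export
recovery_experiment <- function(n_reps = 50L, seed = 1L, n_subjects = 15L,
                                n_rois = 10L, n_planted = 3L, n_trs = 610L,
                                voxels_per_roi = 16L, n_boot = 400L,
                                n_phase = 400L, n_perm = 2000L, q = 0.05) {
  planted <- seq_len(n_planted)
  rows <- vector("list", n_reps)
  planted_rho <- NA_real_
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(
      n_subjects_per_group = c(n_subjects, n_subjects), n_rois = n_rois,
      voxels_per_roi = voxels_per_roi, n_trs = n_trs,
      drug_locked_rois = planted, ofc_rois = planted, seed = seed + r)
    study <- simulate_study(cfg)
    planted_rho <- study$truth$planted_rho
    det <- detect_sync_study(align_study(preprocess_study(study)),
                             n_boot = n_boot, n_phase = n_phase,
                             seed = seed + 100000L + 1000L * r)
    bias <- bias_tests(det, study$label_track, n_perm = n_perm,
                       seed = seed + 1000000L + 1000L * r, q = q)
    flagged <- bias$roi[bias$disc_delta %in% TRUE]
    isc <- isc_scores(det, planted)
    iscb <- isc_behavior_correlations(
      dplyr::filter(isc, .data$group == "g1"),
      dplyr::filter(study$behavior, .data$group == "g1"),
      "scene_induced_craving_max", q = q)
    est_r <- iscb$r[iscb$contrast == "delta"]
    n_pairs <- iscb$n[iscb$contrast == "delta"]
    ci <- tanh(atanh(est_r) + c(-1, 1) * qnorm(0.975) / sqrt(n_pairs - 3))
    rows[[r]] <- tibble::tibble(
      rep = r,
      tp = sum(planted %in% flagged), fn = n_planted - sum(planted %in% flagged),
      fp = sum(!(flagged %in% planted)), tn = (n_rois - n_planted) -
        sum(!(flagged %in% planted)),
      delta_r = est_r, ci_low = ci[1], ci_high = ci[2],
      covered = ci[1] <= planted_rho & planted_rho <= ci[2])
  }
  reps <- dplyr::bind_rows(rows)
  list(sensitivity = sum(reps$tp) / (sum(reps$tp) + sum(reps$fn)),
       specificity = sum(reps$tn) / (sum(reps$tn) + sum(reps$fp)),
       coverage = mean(reps$covered),
       mean_delta_r = mean(reps$delta_r),
       planted_rho = planted_rho,
       replicates = reps)
}

#' Exhaustive-enumeration check of the permutation test
#'
#' On an instance small enough to enumerate (6 valid TRs, two synchronized
#' TRs per group), compares the Monte-Carlo permutation p-value of
#' [group_difference_test()] with the exact p over all placements of both
#' TR sets.
#'
#' @param seed Seed for the Monte-Carlo run.
#' @param n_perm Monte-Carlo permutation count.
#' @return A list: `p_mc`, `p_exact`, `mc_se`, the observed statistic, and
#'   the instance definition.
#' @export
perm_oracle_check <- function(seed = 1L, n_perm = 5000L) {
  labels <- rep(c(1L, 1L, 0L, 1L, 0L, 0L, 0L, 1L), 2)  # fixed 16-bin track
  track <- label_track(labels)
  valid_trs <- 0:5
  t_a <- c(0L, 1L)
  t_b <- c(1L, 2L)   # observed statistic 1/6, exact p ~ 0.204
  test <- group_difference_test(t_a, t_b, track, valid_trs, n_perm = n_perm,
                                seed = seed)
  placements <- utils::combn(valid_trs, 2L, simplify = FALSE)
  bias_of <- function(ts)
    compute_bias(map_trs_to_bins(ts, nrow(track)), track)
  b_all <- vapply(placements, bias_of, numeric(1))
  null_exact <- as.numeric(outer(b_all, b_all, `-`))
  p_exact <- mean(abs(null_exact) >= abs(test$statistic))
  list(p_mc = test$p_value, p_exact = p_exact,
       mc_se = sqrt(p_exact * (1 - p_exact) / n_perm),
       statistic = test$statistic, t_a = t_a, t_b = t_b,
       n_placements = length(b_all)^2)
}
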