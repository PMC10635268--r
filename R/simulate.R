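#' Configuration for the synthetic naturalistic-fMRI study generator
#'
#' Bundles and validates all generator parameters. Defaults emulate the study
#' design the package targets: two groups (a clinical group of 30 and a
#' comparison group of 25), two sessions, a 1033-TR scan at 1 s TR (1023
#' analyzed seconds after the initial 10-TR drop), and a movie label track
#' with 45.4% labeled (drug) seconds. Amplitudes are effect sizes in units of
#' the voxel noise SD. `drug_amplitude` / `nondrug_amplitude` are 2 x 2
#' matrices (rows = groups, columns = sessions): drug-locked ROIs follow
#' `drug_amplitude * z(HRF x events in labeled bins) + nondrug_amplitude *
#' z(HRF x events in unlabeled bins)` (both event components unit-variance,
#' shared across groups and sessions like the movie itself), while every
#' other ROI follows its own unit-variance smooth "narrative" series scaled
#' by `nondrug_amplitude` — synchronized but content-unbiased, a live null
#' for the bias tests.
#'
#' The default amplitude matrix plants the clinical phenotype: group 1's drive
#' toward labeled content drops from 1.5 to 0.5 across sessions while group 2
#' stays flat, so the group-by-session delta test has a known positive target.
#' Craving is linked to the per-subject, per-session coupling coefficient
#' (uniform on \[0.5, 1.5\]) that scales the shared drive, not to realized
#' ISC, so recovering the ISC-craving correlation is a genuine inference test.
#'
#' @param n_subjects_per_group Integer vector of length 2.
#' @param n_rois Number of ROIs.
#' @param voxels_per_roi Voxels simulated per ROI.
#' @param n_trs Scan length in TRs before the initial drop.
#' @param tr_seconds TR in seconds.
#' @param drug_fraction Target labeled fraction of movie bins.
#' @param block_length_mean Mean label block (scene) length, seconds.
#' @param drug_locked_rois Indices of ROIs whose shared drive follows the
#'   label track.
#' @param ofc_rois Indices of the ROI set aggregated for the ISC-behavior
#'   analysis (the synthetic stand-in for the OFC set).
#' @param drug_amplitude,nondrug_amplitude 2 x 2 numeric matrices
#'   (group x session), in noise-SD units.
#' @param global_amplitude Amplitude of the shared per-group-session arousal
#'   component added to every voxel.
#' @param noise_sd SD of white voxel noise.
#' @param craving_link_slope,craving_link_intercept,craving_link_noise
#'   Scene-induced craving is `intercept + slope * coupling + N(0, noise)`,
#'   rounded onto a discrete 0-10 scale.
#' @param confound_leak_sd SD of per-voxel loadings on the (standardized)
#'   motion/CSF confounds leaked into the data.
#' @param drift_sd SD of the per-voxel linear drift amplitude.
#' @param seed Integer seed; the whole study is deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects_per_group = c(30L, 25L),
                       n_rois = 450L,
                       voxels_per_roi = 16L,
                       n_trs = 1033L,
                       tr_seconds = 1,
                       drug_fraction = 464 / 1023,
                       block_length_mean = 30,
                       drug_locked_rois = 1:10,
                       ofc_rois = 1:5,
                       drug_amplitude = rbind(c(1.5, 0.5), c(1, 1)),
                       nondrug_amplitude = rbind(c(0.9, 0.9), c(1, 1)),
                       global_amplitude = 0.5,
                       noise_sd = 1,
                       craving_link_slope = 2,
                       craving_link_intercept = 4,
                       craving_link_noise = 0.9,
                       confound_leak_sd = 0.3,
                       drift_sd = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_subjects_per_group = vapply(n_subjects_per_group, assert_count,
                                  integer(1), name = "n_subjects_per_group"),
    n_rois = assert_count(n_rois, "n_rois"),
    voxels_per_roi = assert_count(voxels_per_roi, "voxels_per_roi"),
    n_trs = assert_count(n_trs, "n_trs"),
    tr_seconds = tr_seconds,
    drug_fraction = assert_fraction(drug_fraction, "drug_fraction"),
    block_length_mean = block_length_mean,
    drug_locked_rois = as.integer(drug_locked_rois),
    ofc_rois = as.integer(ofc_rois),
    drug_amplitude = drug_amplitude,
    nondrug_amplitude = nondrug_amplitude,
    global_amplitude = global_amplitude,
    noise_sd = noise_sd,
    craving_link_slope = craving_link_slope,
    craving_link_intercept = craving_link_intercept,
    craving_link_noise = craving_link_noise,
    confound_leak_sd = confound_leak_sd,
    drift_sd = drift_sd,
    seed = as.integer(seed)
  )
  if (length(cfg$n_subjects_per_group) != 2L)
    abort("`n_subjects_per_group` must have length 2")
  for (nm in c("drug_amplitude", "nondrug_amplitude")) {
    m <- cfg[[nm]]
    if (!is.matrix(m) || !all(dim(m) == c(2L, 2L)) || !all(is.finite(m)))
      abort(sprintf("`%s` must be a finite 2 x 2 (group x session) matrix", nm))
  }
  if (cfg$n_trs <= 10L) abort("`n_trs` must exceed the 10 dropped TRs")
  if (length(cfg$drug_locked_rois) &&
      (min(cfg$drug_locked_rois) < 1L || max(cfg$drug_locked_rois) > cfg$n_rois))
    abort("`drug_locked_rois` out of ROI range")
  if (length(cfg$ofc_rois) &&
      (min(cfg$ofc_rois) < 1L || max(cfg$ofc_rois) > cfg$n_rois))
    abort("`ofc_rois` out of ROI range")
  if (cfg$noise_sd <= 0) abort("`noise_sd` must be positive")
  structure(cfg, class = "sim_config")
}

#' Simulate a two-group, two-session naturalistic-fMRI study
#'
#' Generates voxel-level BOLD-like data with known stimulus-locked structure:
#' within each (group, session, ROI) all subjects share one latent drive
#' (HRF-convolved label drive for drug-locked ROIs, a smooth narrative series
#' elsewhere), scaled per subject by a coupling coefficient in \[0.5, 1.5\];
#' a shared arousal (global) component, standardized motion/CSF confound
#' leakage, a per-voxel linear drift, and white noise are added on top.
#' Behavioral craving tables and a ground-truth record for scoring recovery
#' are included.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_study` with elements `config`,
#'   `label_track`, `voxel` (tibble: group, session, subject_id, roi, data =
#'   voxel x TR matrix), `confounds` (tibble: group, session, subject_id,
#'   confounds = TR x 7 matrix), `behavior` (tibble), and `truth`.
#' @examples
#' cfg <- sim_config(n_subjects_per_group = c(4, 4), n_rois = 3,
#'                   voxels_per_roi = 4, n_trs = 80, drug_locked_rois = 1,
#'                   ofc_rois = 1, seed = 7)
#' study <- simulate_study(cfg)
#' study$voxel
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a `sim_config`")
  groups <- c("g1", "g2")
  sessions <- c("baseline", "followup")
  n_bins <- config$n_trs - 10L
  withr::with_seed(config$seed, {
    track <- generate_label_track(n_bins, config$drug_fraction,
                                  config$block_length_mean)
    h <- hrf_kernel(config$tr_seconds)
    h_sum1 <- as.numeric(h) / sum(h)   # unit-sum kernel: plateau == amplitude
    pad <- config$n_trs - n_bins
    lab <- c(track$label, rep(0, pad)) # movie second m plays at scan TR m

    conv_drive <- function(stim)
      convolve(stim, rev(h_sum1), type = "open")[seq_len(config$n_trs)]

    # Stimulus-locked event components, shared across subjects, groups and
    # sessions (everyone watches the same movie): sparse salient moments
    # (about one eligible bin in five carries a unit impulse) inside labeled
    # (drug) bins and inside unlabeled bins, each HRF-convolved and
    # standardized to unit variance so the configured amplitudes are effect
    # sizes in noise-SD units. Unit-intensity impulses keep the two event
    # types cleanly separated in peak height, so which content dominates the
    # detected synchronization peaks is governed by the amplitude ratio.
    # Locked ROIs mix the two event components; every other ROI follows its
    # own unit-variance sparse narrative series — synchronized but
    # content-unbiased.
    movie_on <- c(rep(1, n_bins), rep(0, pad))
    # Each ROI gets its own event realization (different regions respond to
    # different aspects of the same movie). For a locked ROI the common
    # scale — the SD of that ROI's all-events response — makes equal drug and
    # non-drug amplitudes give equal per-event response heights and a
    # combined drive of exactly that amplitude in noise-SD units.
    roi_events <- lapply(seq_len(config$n_rois), function(r) {
      ev <- stats::rbinom(config$n_trs, 1, 0.2) * movie_on
      if (r %in% config$drug_locked_rois) {
        ev_scale <- sd(conv_drive(ev))
        d <- conv_drive(ev * lab) / ev_scale
        u <- conv_drive(ev * (1 - lab)) / ev_scale
        list(drug = d - mean(d), nondrug = u - mean(u))
      } else {
        list(narrative = zscore(conv_drive(ev)))
      }
    })

    # shared arousal per group x session
    arousal <- lapply(seq_along(groups), function(g)
      lapply(seq_along(sessions), function(s)
        zscore(conv_drive(rnorm(config$n_trs)))))

    # per-(group, session) ROI drives
    drives <- lapply(seq_along(groups), function(g)
      lapply(seq_along(sessions), function(s) {
        ad <- config$drug_amplitude[g, s]
        an <- config$nondrug_amplitude[g, s]
        lapply(seq_len(config$n_rois), function(r) {
          if (r %in% config$drug_locked_rois) {
            ad * roi_events[[r]]$drug + an * roi_events[[r]]$nondrug
          } else {
            an * roi_events[[r]]$narrative
          }
        })
      }))

    subj_ids <- lapply(seq_along(groups), function(g)
      sprintf("%s_s%02d", groups[g], seq_len(config$n_subjects_per_group[g])))

    coupling <- tidyr::expand_grid(
      group = groups, session = sessions) |>
      dplyr::rowwise() |>
      dplyr::mutate(ids = list(subj_ids[[match(.data$group, groups)]])) |>
      dplyr::ungroup() |>
      tidyr::unnest_longer("ids", values_to = "subject_id") |>
      dplyr::mutate(coupling = runif(dplyr::n(), 0.5, 1.5))

    tgrid <- seq(-1, 1, length.out = config$n_trs)
    voxel_rows <- list()
    conf_rows <- list()
    for (g in seq_along(groups)) {
      for (s in seq_along(sessions)) {
        for (i in seq_len(config$n_subjects_per_group[g])) {
          sid <- subj_ids[[g]][i]
          c_is <- coupling$coupling[coupling$group == groups[g] &
                                      coupling$session == sessions[s] &
                                      coupling$subject_id == sid]
          # confounds: 6 motion-like + 1 CSF-like smooth random walks
          conf <- vapply(1:7, function(k) cumsum(rnorm(config$n_trs, sd = 0.05)),
                         numeric(config$n_trs))
          colnames(conf) <- c(paste0("motion_", 1:6), "csf")
          conf_std <- scale(conf)
          conf_rows[[length(conf_rows) + 1L]] <- tibble::tibble(
            group = groups[g], session = sessions[s], subject_id = sid,
            confounds = list(conf))
          mats <- vector("list", config$n_rois)
          for (r in seq_len(config$n_rois)) {
            w <- runif(config$voxels_per_roi, 0.5, 1)
            beta_conf <- matrix(rnorm(7 * config$voxels_per_roi,
                                      sd = config$confound_leak_sd), 7)
            drift <- rnorm(config$voxels_per_roi, sd = config$drift_sd)
            # arousal enters every voxel with unit loading, not scaled by w
            signal <- w %o% (c_is * drives[[g]][[s]][[r]]) +
              matrix(config$global_amplitude * arousal[[g]][[s]],
                     config$voxels_per_roi, config$n_trs, byrow = TRUE)
            m <- signal + t(conf_std %*% beta_conf) + drift %o% tgrid +
              matrix(rnorm(config$voxels_per_roi * config$n_trs,
                           sd = config$noise_sd),
                     config$voxels_per_roi, config$n_trs)
            mats[[r]] <- m
          }
          voxel_rows[[length(voxel_rows) + 1L]] <- tibble::tibble(
            group = groups[g], session = sessions[s], subject_id = sid,
            roi = seq_len(config$n_rois), data = mats)
        }
      }
    }
    voxel <- dplyr::bind_rows(voxel_rows)
    confounds <- dplyr::bind_rows(conf_rows)

    behavior <- coupling |>
      dplyr::mutate(
        scene_induced_craving_max = pmin(10, pmax(0, round(
          config$craving_link_intercept +
            config$craving_link_slope * .data$coupling +
            rnorm(dplyr::n(), sd = config$craving_link_noise)))),
        pre_movie_craving = pmin(9L, pmax(0L, as.integer(round(
          rnorm(dplyr::n(), mean = ifelse(.data$group == "g1", 3, 0.5), sd = 1.5))))),
        movie_induced_craving = as.integer(round(rnorm(dplyr::n(), 0, 1.5))),
        hcq_total = ifelse(.data$group == "g1",
                           pmax(0, round(rnorm(dplyr::n(), 39, 13.5))), NA_real_)
      ) |>
      dplyr::select(!"coupling")
    demo <- behavior |>
      dplyr::distinct(.data$group, .data$subject_id) |>
      dplyr::mutate(age = round(rnorm(dplyr::n(), 40, 9), 1),
                    sex = sample(c("F", "M"), dplyr::n(), replace = TRUE))
    behavior <- dplyr::left_join(behavior, demo, by = c("group", "subject_id"))

    var_dc <- 2 / 12  # variance of the difference of two U(0.5, 1.5) draws
    truth <- list(
      drug_locked_rois = config$drug_locked_rois,
      ofc_rois = config$ofc_rois,
      drug_amplitude = config$drug_amplitude,
      nondrug_amplitude = config$nondrug_amplitude,
      coupling = coupling,
      arousal = arousal,
      planted_rho = config$craving_link_slope * sqrt(var_dc) /
        sqrt(config$craving_link_slope^2 * var_dc +
               2 * config$craving_link_noise^2),
      seed = config$seed
    )

    structure(list(config = config, label_track = track, voxel = voxel,
                   confounds = confounds, behavior = behavior, truth = truth),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cfg <- x$config
  cat("<synthetic_study>\n",
      sprintf("  groups: %d + %d subjects, 2 sessions\n",
              cfg$n_subjects_per_group[1], cfg$n_subjects_per_group[2]),
      sprintf("  %d ROIs x %d voxels, %d TRs (%d analyzed)\n",
              cfg$n_rois, cfg$voxels_per_roi, cfg$n_trs, cfg$n_trs - 10L),
      sprintf("  label track: %d/%d bins labeled (%.1f%%)\n",
              sum(x$label_track$label), nrow(x$label_track),
              100 * mean(x$label_track$label)),
      sprintf("  drug-locked ROIs: %s\n",
              paste(cfg$drug_locked_rois, collapse = ", ")), sep = "")
  invisible(x)
}

#' Write the synthetic study's tabular interfaces to disk
#'
#' Writes the label track (TSV), per-subject confounds (TSV), the behavior
#' table (CSV), and a JSON sidecar recording shapes, indexing and seed.
#' Voxel arrays themselves are kept in memory (they are regenerated exactly
#' from the seed) — only their shape metadata is persisted.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_label_track(study$label_track, file.path(dir, "label_track.tsv"))
  readr::write_csv(study$behavior, file.path(dir, "behavior.csv"))
  conf_dir <- file.path(dir, "confounds")
  dir.create(conf_dir, showWarnings = FALSE)
  purrr::pwalk(study$confounds, function(group, session, subject_id, confounds)
    readr::write_tsv(tibble::as_tibble(confounds),
                     file.path(conf_dir, sprintf("%s_%s.tsv", subject_id, session))))
  sidecar <- list(
    n_subjects_per_group = study$config$n_subjects_per_group,
    n_rois = study$config$n_rois,
    voxels_per_roi = study$config$voxels_per_roi,
    n_trs = study$config$n_trs,
    groups = unique(study$voxel$group),
    sessions = unique(study$voxel$session),
    seed = study$config$seed)
  jsonlite::write_json(sidecar, file.path(dir, "study_sidecar.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
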