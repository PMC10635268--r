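default_pipeline_config <- function() {
  list(
    simulate = list(
      n_subjects_per_group = c(30L, 25L), n_rois = 450L, voxels_per_roi = 8L,
      n_trs = 1033L, drug_fraction = 464 / 1023, drug_locked_rois = 1:10,
      ofc_rois = 1:5, seed = 1L),
    preprocess = list(n_drop = 10L, highpass_period = 140),
    detect = list(n_boot = 5000L, n_phase = 5000L, level = 95,
                  null_quantile = 95, seed = 1L),
    bias = list(n_perm = 5000L, q = 0.05, tr_offset_seconds = 10L,
                lag_lo = 5L, lag_hi = 10L, seed = 2L),
    isc = list(measures = c("scene_induced_craving_max", "pre_movie_craving",
                            "movie_induced_craving", "hcq_total"),
               q = 0.05)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file `%s` not found", config))
    config <- yaml::read_yaml(config)
  }
  def <- default_pipeline_config()
  bad_sections <- setdiff(names(config), names(def))
  if (length(bad_sections))
    abort(sprintf("unknown config section(s): %s",
                  paste(bad_sections, collapse = ", ")))
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (length(bad))
      abort(sprintf("unknown key(s) in `%s`: %s", sec, paste(bad, collapse = ", ")))
    def[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  def
}

#' Run the full analysis pipeline on a (simulated) study
#'
#' Orchestrates simulate, preprocess, SRM alignment, synchronization
#' detection, ROI-wise bias testing and the ISC-behavior analysis as one
#' reproducible run. All tabular outputs (per-ROI bias CSV, carpet table,
#' ISC scores, ISC-behavior correlations) plus a JSON manifest recording the
#' effective configuration and stage seeds are written to `out_dir`.
#'
#' @param config A config list, or a path to a YAML file with (a subset of)
#'   sections `simulate`, `preprocess`, `detect`, `bias`, `isc`; unknown keys
#'   are rejected. Omitted keys take the defaults, which equal the reference
#'   analysis values (5000 bootstraps / phase draws / permutations, 95%
#'   levels, 140 s high-pass, 10 dropped TRs, 5-10 s lag window, q = 0.05).
#' @param out_dir Output directory; created if missing. `NULL` skips writing.
#' @param study Optionally a pre-built `synthetic_study` (the `simulate`
#'   section is then ignored).
#' @param verbose Log stage progress to stderr.
#' @return A list with `study`, `aligned` (with sync results), `bias`, `isc`,
#'   `isc_behavior`, `manifest` — invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, study = NULL,
                         verbose = TRUE) {
  cfg <- read_pipeline_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    say("[%s] ...", name)
    tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e))))
  }
  if (is.null(study)) {
    study <- stage("simulate",
      simulate_study(do.call(sim_config, cfg$simulate)))
  }
  study <- stage("preprocess",
    preprocess_study(study, n_drop = cfg$preprocess$n_drop,
                     highpass_period = cfg$preprocess$highpass_period))
  aligned <- stage("align", align_study(study))
  detected <- stage("detect",
    detect_sync_study(aligned, n_boot = cfg$detect$n_boot,
                      n_phase = cfg$detect$n_phase, level = cfg$detect$level,
                      null_quantile = cfg$detect$null_quantile,
                      seed = cfg$detect$seed))
  bias <- stage("bias",
    bias_tests(detected, study$label_track, n_perm = cfg$bias$n_perm,
               seed = cfg$bias$seed, q = cfg$bias$q,
               tr_offset_seconds = cfg$bias$tr_offset_seconds,
               lag_lo = cfg$bias$lag_lo, lag_hi = cfg$bias$lag_hi))
  isc <- stage("isc", isc_scores(detected, study$truth$ofc_rois))
  clinical <- unique(detected$group)[1]
  iscb <- stage("isc_behavior",
    isc_behavior_correlations(dplyr::filter(isc, .data$group == clinical),
                              dplyr::semi_join(study$behavior,
                                               dplyr::filter(isc, .data$group == clinical),
                                               by = "subject_id"),
                              measures = intersect(cfg$isc$measures,
                                                   names(study$behavior)),
                              q = cfg$isc$q))
  manifest <- list(
    package_version = as.character(utils::packageVersion("cinesync")),
    config = cfg,
    timestamp = format(Sys.time(), tz = "UTC"),
    decisions = list(
      srm_fit = "per group and session, deterministic PCA initialization",
      detection = "one-sided positive deflections; strict ci_low > threshold",
      null_placement = "uniform without replacement over analyzed TRs",
      undefined_bias = "empty T* excluded from FDR family",
      tr_offset = "significant TR indices are post-drop; +n_drop restored before the lag window"))
  out <- list(study = study, aligned = detected, bias = bias, isc = isc,
              isc_behavior = iscb, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(bias, file.path(out_dir, "bias_per_roi.csv"))
    readr::write_csv(carpet_table(detected, study$label_track,
                                  tr_offset_seconds = cfg$bias$tr_offset_seconds,
                                  lag_lo = cfg$bias$lag_lo,
                                  lag_hi = cfg$bias$lag_hi),
                     file.path(out_dir, "carpet_table.csv"))
    readr::write_csv(isc, file.path(out_dir, "isc_scores.csv"))
    readr::write_csv(iscb, file.path(out_dir, "isc_behavior.csv"))
    write_label_track(study$label_track, file.path(out_dir, "label_track.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    say("[done] outputs in %s", out_dir)
    return(invisible(out))
  }
  out
}

#' Validate tabular pipeline inputs against their schemas
#'
#' Checks a label-track TSV (contiguous 0-based bins, binary labels), a
#' behavior CSV (required columns, session labels) and a study sidecar JSON
#' (positive counts, subject-count consistency) without running anything.
#'
#' @param paths Named list with any of `label_track`, `behavior`, `sidecar`.
#' @return Tibble of violations (`input`, `problem`); zero rows means clean.
#' @export
validate_inputs <- function(paths) {
  bad <- list()
  note <- function(input, problem)
    bad[[length(bad) + 1L]] <<- tibble::tibble(input = input, problem = problem)
  if (!is.null(paths$label_track)) {
    if (!file.exists(paths$label_track)) {
      note("label_track", sprintf("file `%s` not found", paths$label_track))
    } else {
      x <- readr::read_tsv(paths$label_track, show_col_types = FALSE)
      if (!identical(names(x), c("bin_start_second", "label")))
        note("label_track", "columns must be bin_start_second, label")
      else {
        if (!all(x$label %in% c(0, 1)))
          note("label_track", "labels must be binary 0/1")
        if (!identical(as.integer(x$bin_start_second), seq_len(nrow(x)) - 1L))
          note("label_track", "bins must be contiguous 0-based seconds")
      }
    }
  }
  if (!is.null(paths$behavior)) {
    if (!file.exists(paths$behavior)) {
      note("behavior", sprintf("file `%s` not found", paths$behavior))
    } else {
      b <- readr::read_csv(paths$behavior, show_col_types = FALSE)
      need <- c("subject_id", "group", "session")
      miss <- setdiff(need, names(b))
      if (length(miss))
        note("behavior", paste("missing column(s):", paste(miss, collapse = ", ")))
      else if (!all(b$session %in% c("baseline", "followup")))
        note("behavior", "session must be baseline/followup")
    }
  }
  if (!is.null(paths$sidecar)) {
    if (!file.exists(paths$sidecar)) {
      note("sidecar", sprintf("file `%s` not found", paths$sidecar))
    } else {
      s <- jsonlite::read_json(paths$sidecar, simplifyVector = TRUE)
      for (k in c("n_subjects_per_group", "n_rois", "voxels_per_roi", "n_trs"))
        if (is.null(s[[k]]) || any(s[[k]] < 1))
          note("sidecar", sprintf("`%s` missing or non-positive", k))
      if (!is.null(s$n_subjects_per_group) && length(s$n_subjects_per_group) != 2)
        note("sidecar", "n_subjects_per_group must have length 2")
    }
  }
  if (length(bad)) dplyr::bind_rows(bad)
  else tibble::tibble(input = character(0), problem = character(0))
}
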