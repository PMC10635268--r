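# small simulated studies reused across test files

tiny_study <- function(seed = 7, n_rois = 3, n_subj = c(6, 6), n_trs = 160,
                       locked = 1L, voxels = 6) {
  simulate_study(sim_config(
    n_subjects_per_group = n_subj, n_rois = n_rois, voxels_per_roi = voxels,
    n_trs = n_trs, drug_locked_rois = locked, ofc_rois = locked, seed = seed))
}

# subjects x TR matrix with a common signal plus idiosyncratic noise
shared_signal_matrix <- function(n_subj = 10, n_tr = 200, snr = 2, seed = 1) {
  withr::with_seed(seed, {
    s <- as.numeric(scale(stats::filter(rnorm(n_tr + 20), rep(1, 5),
                                        sides = 1)[-(1:20)]))
    m <- t(vapply(seq_len(n_subj), function(i) snr * s + rnorm(n_tr),
                  numeric(n_tr)))
    rownames(m) <- sprintf("s%02d", seq_len(n_subj))
    m
  })
}
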