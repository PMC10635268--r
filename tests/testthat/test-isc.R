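test_that("leave-one-out ISC handles exact and degenerate cases", {
  v <- as.numeric(scale(rnorm(60)))
  m <- rbind(v, v, v)
  rownames(m) <- c("a", "b", "c")
  out <- loo_isc(m)
  expect_equal(out$r, rep(1, 3), tolerance = 1e-12)
  m2 <- rbind(v, v, v, -v)
  expect_equal(loo_isc(m2)$r[4], -1, tolerance = 1e-12)
  expect_error(loo_isc(m[1:2, ]), "3 subjects")
  m3 <- rbind(v, v, rep(2, 60))
  out3 <- loo_isc(m3)
  expect_true(out3$degenerate[3])
})

test_that("loo ISC is invariant to affine positive transforms of a subject", {
  withr::local_seed(1)
  m <- shared_signal_matrix(n_subj = 6, n_tr = 120, seed = 2)
  base <- loo_isc(m)
  m2 <- m
  m2[3, ] <- 5 + 2.7 * m2[3, ]
  expect_equal(loo_isc(m2)$r[3], base$r[3], tolerance = 1e-12)
})

test_that("Fisher aggregation follows the closed form", {
  expect_equal(fisher_aggregate(c(0.5, 0.5)), 0.5, tolerance = 1e-12)
  expect_equal(fisher_aggregate(c(0.3, -0.3)), 0, tolerance = 1e-12)
  expect_equal(fisher_aggregate(c(0.2, 0.8)),
               tanh((atanh(0.2) + atanh(0.8)) / 2), tolerance = 1e-12)
  expect_error(fisher_aggregate(c(0.2, 1)), "infinite")
  expect_error(fisher_aggregate(numeric(0)), "non-empty")
})

test_that("planted coupling ranks are recovered by loo ISC", {
  study <- tiny_study(seed = 13, n_rois = 8, n_subj = c(20, 2), n_trs = 310,
                      voxels = 8)
  al <- align_study(preprocess_study(study))
  cell <- dplyr::filter(al, group == "g1", session == "baseline", roi == 1)
  out <- loo_isc(cell$series[[1]])
  cpl <- dplyr::filter(study$truth$coupling, group == "g1",
                       session == "baseline")
  d <- dplyr::inner_join(out, cpl, by = "subject_id")
  expect_gt(cor(d$r, d$coupling, method = "spearman"), 0.8)
})

test_that("ISC scores aggregate over the ROI set per subject-session", {
  study <- tiny_study(seed = 17, n_rois = 2, n_subj = c(4, 4), n_trs = 160,
                      locked = 1:2)
  al <- align_study(preprocess_study(study))
  isc <- isc_scores(al, 1:2)
  expect_equal(nrow(isc), 16)  # 8 subjects x 2 sessions
  expect_true(all(abs(isc$isc) < 1))
  expect_error(isc_scores(al, 99), "no ROI")
})

test_that("behavior correlations report r, p and BH q per measure", {
  withr::local_seed(3)
  n <- 20
  ids <- sprintf("s%02d", 1:n)
  isc <- tibble::tibble(
    group = "g1",
    session = rep(c("baseline", "followup"), each = n),
    subject_id = rep(ids, 2),
    isc = rnorm(2 * n, 0.5, 0.1))
  beh <- tibble::tibble(
    session = rep(c("baseline", "followup"), each = n),
    subject_id = rep(ids, 2))
  # craving exactly tracks the ISC delta; a second measure is pure noise
  wide <- tidyr::pivot_wider(isc, names_from = "session", values_from = "isc")
  delta <- wide$followup - wide$baseline
  beh$craving <- c(rep(0, n), delta)
  beh$noise_measure <- rnorm(2 * n)
  out <- isc_behavior_correlations(isc, beh, c("craving", "noise_measure"))
  r_delta <- out$r[out$measure == "craving" & out$contrast == "delta"]
  expect_equal(r_delta, 1, tolerance = 1e-10)
  expect_equal(nrow(out), 4)
  expect_true(all(c("q_value", "discovery") %in% names(out)))
  expect_error(
    isc_behavior_correlations(isc[c(1:3, n + 1:3), ], beh, "craving"),
    "fewer than 4")
  expect_error(isc_behavior_correlations(isc, beh, "absent"), "not found")
})

test_that("pooled t reproduces published group comparisons", {
  age <- pooled_t(39.97, 10.76, 25, 40.00, 8.41, 30)
  expect_equal(age$df, 53)
  expect_lt(abs(age$t - (-0.011)), 0.001)
  viq <- pooled_t(110.28, 6.85, 25, 96.53, 11.73, 30)
  expect_lt(abs(viq$t - 5.2), 0.05)
  nviq <- pooled_t(11.96, 2.76, 25, 10.43, 3.15, 30)
  expect_lt(abs(nviq$t - 1.9), 0.05)
  # antisymmetry and the trivial zero case
  expect_equal(pooled_t(1, 1, 10, 2, 1, 12)$t, -pooled_t(2, 1, 12, 1, 1, 10)$t)
  expect_equal(pooled_t(5, 2, 8, 5, 3, 9)$t, 0)
  expect_error(pooled_t(1, 0, 5, 2, 1, 5), "positive")
  expect_error(pooled_t(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("paired nonparametric test matches exact sign-assignment logic", {
  # all-positive deltas: negative-rank sum 0, V = 15, one-sided p = 1/32
  out <- paired_nonparametric(1:5, alternative = "greater")
  expect_equal(out$statistic, 15)
  expect_equal(out$p, 1 / 32)
  # perfectly symmetric deltas: two-sided p = 1
  sym <- c(-1, 1, -2, 2, -3, 3)
  expect_equal(paired_nonparametric(sym)$p, 1)
  # negation leaves the two-sided p unchanged
  d <- c(2, -1, 4, 3, -2, 5, 1.5)
  expect_equal(paired_nonparametric(d)$p, paired_nonparametric(-d)$p)
  expect_error(paired_nonparametric(c(0, 0, 0, 0, 0, 1)), "5 non-zero")
})
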