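test_that("TR-to-bin mapping applies the offset and 5-10 s lag window", {
  expect_identical(map_trs_to_bins(0L, n_bins = 100), 0:4)
  expect_identical(map_trs_to_bins(c(0L, 1L), n_bins = 100), 0:5)
  # m = 3 puts the whole window below bin 0
  expect_identical(map_trs_to_bins(0L, n_bins = 100, tr_offset_seconds = 3),
                   integer(0))
  # clipping at the top of the track
  expect_identical(map_trs_to_bins(5L, n_bins = 8), 5:7)
  expect_identical(map_trs_to_bins(integer(0), n_bins = 10), integer(0))
  expect_error(map_trs_to_bins(0L, 10, lag_lo = 10, lag_hi = 5), "lag_hi")
  expect_error(map_trs_to_bins(-1L, 10), "non-negative")
})

test_that("bias is the labeled fraction of unique bins", {
  tr <- label_track(c(1, 1, 0, 0, 1, 0))
  expect_equal(compute_bias(0:3, tr), 0.5)
  expect_true(is.na(compute_bias(integer(0), tr)))
  expect_error(compute_bias(6L, tr), "outside")
  # duplicated TR contributions collapse to unique bins
  b1 <- compute_bias(map_trs_to_bins(c(0L, 0L, 1L), 20), label_track(rep(c(1, 0), 10)))
  b2 <- compute_bias(map_trs_to_bins(c(0L, 1L), 20), label_track(rep(c(1, 0), 10)))
  expect_equal(b1, b2)
})

test_that("full coverage of the reference track reproduces 45.4%", {
  tr <- generate_label_track(1023, 464 / 1023, seed = 1)
  expect_equal(compute_bias(0:1022, tr), 464 / 1023, tolerance = 1e-12)
})

test_that("group difference test degenerates correctly", {
  tr <- generate_label_track(64, 0.5, seed = 2)
  valid <- 0:49
  same <- c(3L, 10L, 20L)
  res <- group_difference_test(same, same, tr, valid, n_perm = 200, seed = 1)
  expect_equal(res$statistic, 0)
  expect_gt(res$p_value, 0.9)
  # all-drug track: both biases 1, statistic 0, p = 1
  all_drug <- label_track(rep(1L, 64))
  res2 <- group_difference_test(c(1L, 5L), c(9L, 30L), all_drug, valid,
                                n_perm = 100, seed = 1)
  expect_equal(res2$bias_a, 1)
  expect_equal(res2$bias_b, 1)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  # empty set -> undefined, excluded
  res3 <- group_difference_test(integer(0), c(1L, 2L), tr, valid, n_perm = 50)
  expect_false(res3$defined)
  expect_true(is.na(res3$p_value))
  expect_error(group_difference_test(0:60, c(1L), tr, valid, 50), "exceeds")
})

test_that("Monte-Carlo p matches exhaustive enumeration on a tiny instance", {
  chk <- perm_oracle_check(seed = 3, n_perm = 4000)
  expect_lt(abs(chk$p_mc - chk$p_exact), 3 * chk$mc_se + 1 / 4001)
  expect_equal(chk$n_placements, 225)
})

test_that("label swap maps bias to its complement and keeps p", {
  tr <- generate_label_track(64, 0.4, seed = 5)
  flipped <- label_track(1L - tr$label)
  valid <- 0:49
  a <- c(0L, 7L, 31L)
  b <- c(2L, 15L, 40L)
  r1 <- group_difference_test(a, b, tr, valid, n_perm = 500, seed = 11)
  r2 <- group_difference_test(a, b, flipped, valid, n_perm = 500, seed = 11)
  expect_equal(r2$bias_a, 1 - r1$bias_a)
  expect_equal(r2$statistic, -r1$statistic)
  expect_equal(r2$p_value, r1$p_value)
})

test_that("session delta test is antisymmetric in the groups", {
  tr <- generate_label_track(64, 0.5, seed = 6)
  valid <- 0:49
  ts <- list(a_base = c(0L, 9L), a_follow = c(4L, 30L),
             b_base = c(2L, 22L), b_follow = c(8L, 40L))
  r <- session_delta_test(ts, tr, valid, n_perm = 300, seed = 3)
  swapped <- list(a_base = ts$b_base, a_follow = ts$b_follow,
                  b_base = ts$a_base, b_follow = ts$a_follow)
  r2 <- session_delta_test(swapped, tr, valid, n_perm = 300, seed = 3)
  expect_equal(r2$statistic, -r$statistic)
  # identical cells -> statistic 0; missing cell -> undefined
  same <- list(a_base = ts$a_base, a_follow = ts$a_base,
               b_base = ts$a_base, b_follow = ts$a_base)
  expect_equal(session_delta_test(same, tr, valid, 100, seed = 1)$statistic, 0)
  empty <- ts
  empty$b_follow <- integer(0)
  expect_false(session_delta_test(empty, tr, valid, 100, seed = 1)$defined)
})

test_that("permutation p-values are valid under the null", {
  tr <- generate_label_track(128, 0.45, seed = 7)
  valid <- 0:99
  withr::local_seed(8)
  ps <- vapply(1:150, function(i) {
    a <- sample(valid, 6)
    b <- sample(valid, 6)
    group_difference_test(a, b, tr, valid, n_perm = 400)$p_value
  }, numeric(1))
  level <- mean(ps <= 0.05)
  expect_lte(level, 0.05 + 3 * sqrt(0.05 * 0.95 / 150))
})

test_that("BH correction matches the hand-computed step-up", {
  out <- fdr_bh(c(0.01, 0.02, 0.03))
  expect_equal(out$q_value, c(0.03, 0.03, 0.03))
  expect_true(all(out$discovery))
  expect_false(any(fdr_bh(rep(1, 5))$discovery))
  expect_true(fdr_bh(0.04)$discovery)
  mixed <- fdr_bh(c(0.01, NA, 0.5))
  expect_true(mixed$excluded[2])
  expect_equal(mixed$q_value[c(1, 3)], p.adjust(c(0.01, 0.5), "BH"))
  expect_equal(nrow(fdr_bh(numeric(0))), 0)
  expect_error(fdr_bh(c(0, 0.5)), "\\(0, 1\\]")
})

test_that("study-level bias table flags the planted contrast", {
  study <- tiny_study(seed = 31, n_rois = 2, n_subj = c(8, 8), n_trs = 310,
                      locked = 1L, voxels = 16)
  det <- detect_sync_study(align_study(preprocess_study(study)),
                           n_boot = 300, n_phase = 300, seed = 4)
  bias <- bias_tests(det, study$label_track, n_perm = 500, seed = 6)
  expect_equal(nrow(bias), 2)
  expect_true(all(c("bias_a_base", "stat_delta", "q_delta") %in% names(bias)))
  # the drug-locked ROI shows a higher baseline bias in group 1 than the
  # narrative ROI does
  expect_gt(bias$bias_a_base[1], bias$bias_b_base[1] - 0.05)
  ct <- carpet_table(det, study$label_track)
  expect_true(all(ct$mapped_label_fraction >= 0 & ct$mapped_label_fraction <= 1))
})
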