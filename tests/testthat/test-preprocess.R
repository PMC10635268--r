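test_that("initial-TR drop shortens the series and records the offset", {
  m <- matrix(rnorm(3 * 1033), 3)
  out <- drop_initial_trs(m, 10)
  expect_equal(ncol(out), 1023)
  expect_equal(attr(out, "tr_offset"), 10)
  expect_equal(out[, 1], m[, 11])
  expect_identical(drop_initial_trs(m, 0), m)
  expect_error(drop_initial_trs(matrix(rnorm(5), 1), 10), "cannot drop")
  # offsets accumulate over repeated drops
  expect_equal(attr(drop_initial_trs(out, 5), "tr_offset"), 15)
})

test_that("cleaning annihilates confound columns and linear trends", {
  n <- 200
  withr::local_seed(1)
  conf <- matrix(rnorm(n * 3), n)
  expect_warning(
    out <- clean_series(matrix(conf[, 2], 1), conf),
    "constant"
  )
  expect_equal(as.numeric(out), rep(0, n))
  ramp <- seq_len(n)
  expect_warning(out2 <- clean_series(matrix(ramp, 1)), "constant")
  expect_equal(as.numeric(out2), rep(0, n))
  # residual orthogonal to every confound column and the trend
  x <- matrix(rnorm(5 * n), 5)
  res <- clean_series(x, conf)
  for (k in 1:3) expect_lt(max(abs(cor(t(res), conf[, k]))), 1e-8)
  expect_lt(max(abs(cor(t(res), ramp))), 1e-8)
  expect_equal(unname(rowMeans(res)), rep(0, 5), tolerance = 1e-8)
  expect_equal(unname(apply(res, 1, sd)), rep(1, 5), tolerance = 1e-6)
})

test_that("high-pass filter passes 20 s cycles and removes 400 s cycles", {
  n <- 1023
  t <- seq_len(n)
  fast <- sin(2 * pi * t / 20)
  slow <- sin(2 * pi * t / 400)
  out_fast <- clean_series(matrix(fast, 1), standardize = FALSE)
  out_slow <- clean_series(matrix(slow, 1), standardize = FALSE)
  expect_gt(sd(out_fast) / sd(fast), 0.95)
  expect_gt(1 - sd(out_slow) / sd(slow), 0.9)
})

test_that("cleaning rejects malformed inputs", {
  expect_error(clean_series(matrix(c(1, NA, 3, 4), 1)), "non-finite")
  expect_error(clean_series(matrix(rnorm(10), 1), matrix(rnorm(8), 4)),
               "rows")
  expect_error(clean_series(matrix(rnorm(10), 1), matrix(c(NA, rnorm(9)), 10)),
               "non-finite")
})

test_that("motion expansion produces the 24-parameter set plus extras", {
  conf <- matrix(rnorm(50 * 7), 50)
  colnames(conf) <- c(paste0("motion_", 1:6), "csf")
  ex <- expand_confounds(conf)
  expect_equal(ncol(ex), 25)
  expect_equal(ex[, 7], conf[, 1]^2, ignore_attr = TRUE)
  expect_equal(ex[2:50, 13], diff(conf[, 1]), ignore_attr = TRUE)
  expect_equal(ex[, 25], conf[, 7], ignore_attr = TRUE)
})

test_that("global component averages voxels and z-scores", {
  withr::local_seed(2)
  v <- matrix(rnorm(100), 1)
  expect_equal(extract_global_component(v), as.numeric(scale(v[1, ])),
               tolerance = 1e-12)
  two <- rbind(v[1, ], -v[1, ])
  expect_warning(g <- extract_global_component(two), "constant")
  expect_equal(g, rep(0, 100))
  expect_error(extract_global_component(matrix(numeric(0), 0, 10)), "voxel")
})

test_that("planted arousal is recovered by the global component", {
  study <- simulate_study(sim_config(
    n_subjects_per_group = c(2, 2), n_rois = 24, voxels_per_roi = 8,
    n_trs = 310, drug_locked_rois = 1, ofc_rois = 1, seed = 5))
  pp <- preprocess_study(study)
  idx <- which(pp$global$group == "g1" & pp$global$session == "baseline")[1]
  g <- pp$global$global[[idx]]
  # the estimand is the arousal as seen through the cleaning projection
  # (trend, drift basis and this subject's confound columns)
  conf <- study$confounds$confounds[[which(
    study$confounds$group == "g1" & study$confounds$session == "baseline" &
      study$confounds$subject_id == pp$global$subject_id[idx])]]
  planted <- study$truth$arousal[[1]][[1]][-(1:10)]
  proxy <- as.numeric(clean_series(matrix(planted, 1),
                                   expand_confounds(conf)[-(1:10), ]))
  expect_gt(cor(g, proxy), 0.9)
})

test_that("selective component removes the global direction and nothing else", {
  withr::local_seed(3)
  n <- 150
  g <- as.numeric(scale(rnorm(n)))
  expect_warning(out <- selective_component(matrix(g, 1), g), "constant")
  expect_equal(as.numeric(out), rep(0, n))
  # orthogonal input passes through (up to z-scoring)
  x <- rnorm(n)
  x_orth <- as.numeric(scale(residuals(lm(x ~ g))))
  kept <- selective_component(matrix(x_orth, 1), g)
  expect_equal(as.numeric(kept), x_orth, tolerance = 1e-8)
  # mixed input: residual tracks the non-global part
  e <- rnorm(n)
  mixed <- 0.7 * g + e
  res <- selective_component(matrix(mixed, 1), g)
  expect_gt(cor(as.numeric(res), e), 0.99)
  expect_lt(abs(cor(as.numeric(res), g)), 1e-10)
  # idempotence
  twice <- selective_component(res, g)
  expect_lt(max(abs(twice - res)), 1e-10)
  expect_error(selective_component(matrix(rnorm(10), 1), rnorm(9)), "length")
})

test_that("study preprocessing yields z-scored selective components", {
  study <- tiny_study(n_subj = c(3, 3), n_rois = 2, n_trs = 120)
  pp <- preprocess_study(study)
  m <- pp$voxel$data[[1]]
  expect_equal(ncol(m), 110)
  expect_equal(attr(m, "tr_offset"), 10)
  expect_equal(unname(rowMeans(m)), rep(0, nrow(m)), tolerance = 1e-8)
  expect_equal(unname(apply(m, 1, sd)), rep(1, nrow(m)), tolerance = 1e-6)
  g <- pp$global$global[[1]]
  expect_lt(max(abs(m %*% g / (length(g) - 1))), 1e-8)
})
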