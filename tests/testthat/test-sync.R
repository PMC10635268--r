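test_that("bootstrap interval collapses for identical subjects", {
  v <- sin(seq(0, 6, length.out = 50))
  m <- matrix(rep(v, each = 4), 4)
  ci <- bootstrap_median_ci(m, n_boot = 200, seed = 1)
  expect_equal(ci$ci_low, v, tolerance = 1e-12)
  expect_equal(ci$ci_high, v, tolerance = 1e-12)
  expect_equal(ci$median, v, tolerance = 1e-12)
  expect_error(bootstrap_median_ci(matrix(rnorm(10), 1), 100), "2 subjects")
})

test_that("two-subject bootstrap medians match exact enumeration", {
  # subjects {0, 2}: the four equally likely resamples give medians
  # 0, 1, 1, 2, so P(median = 1) = 1/2 and the bounds live on {0, 1, 2}
  m <- matrix(c(0, 2), 2, 1)
  withr::with_seed(4, {
    meds <- replicate(2000, {
      idx <- sample(2, 2, replace = TRUE)
      median(m[idx, 1])
    })
  })
  expect_true(all(meds %in% c(0, 1, 2)))
  expect_lt(abs(mean(meds == 1) - 0.5), 3 * sqrt(0.25 / 2000))
  ci <- bootstrap_median_ci(m, n_boot = 2000, seed = 4)
  expect_true(ci$ci_low >= 0 && ci$ci_high <= 2)
})

test_that("bootstrap interval covers the true median at roughly nominal rate", {
  withr::local_seed(11)
  hits <- vapply(1:400, function(i) {
    m <- matrix(rnorm(20), 20, 1)
    ci <- bootstrap_median_ci(m, n_boot = 300)
    ci$ci_low <= 0 && 0 <= ci$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("phase randomization preserves the amplitude spectrum exactly", {
  withr::local_seed(1)
  for (n in c(64, 65, 100)) {
    x <- rnorm(n)
    s <- phase_randomize(x, seed = 2)
    expect_lt(max(abs(Mod(fft(s)) - Mod(fft(x))) /
                    pmax(Mod(fft(x)), 1e-12)), 1e-10)
    expect_equal(mean(s), mean(x), tolerance = 1e-12)
    expect_true(is.double(s) && !is.complex(s))
  }
  expect_identical(phase_randomize(rep(3, 16), seed = 1), rep(3, 16))
  expect_error(phase_randomize(c(1, 2, 3)), "length >= 4")
  expect_error(phase_randomize(c(1, NA, 3, 4)), "non-finite")
})

test_that("a phase-randomized sinusoid is the same sinusoid shifted in phase", {
  n <- 120
  t <- seq_len(n)
  x <- sin(2 * pi * 6 * t / n)
  s <- phase_randomize(x, seed = 7)
  # the (possibly fractional) phase shift is absorbed by a sin/cos basis at
  # the same frequency, which must explain the surrogate perfectly
  fit <- lm(s ~ sin(2 * pi * 6 * t / n) + cos(2 * pi * 6 * t / n))
  expect_gt(summary(fit)$r.squared, 1 - 1e-10)
  expect_equal(sd(s), sd(x), tolerance = 1e-10)
})

test_that("null maxima match an independent R implementation draw-for-draw", {
  # mirrors the C++ RNG consumption exactly: Marsaglia polar phases per
  # subject (ascending frequency), subjects in order, draws in order
  marsaglia_phase <- function(k) {
    out <- complex(k)
    for (i in seq_len(k)) {
      repeat {
        u <- 2 * runif(1) - 1
        v <- 2 * runif(1) - 1
        s2 <- u * u + v * v
        if (s2 < 1 && s2 > 0) break
      }
      out[i] <- complex(real = (u * u - v * v) / s2, imaginary = 2 * u * v / s2)
    }
    out
  }
  ref_null <- function(m, n_phase, seed) {
    withr::with_seed(seed, vapply(seq_len(n_phase), function(d) {
      surr <- t(apply(m, 1, function(x) {
        n <- length(x)
        f <- fft(x)
        half <- (n - 1) %/% 2
        ph <- marsaglia_phase(half)
        g <- f
        g[1 + seq_len(half)] <- Mod(f[1 + seq_len(half)]) * ph
        g[n + 1 - seq_len(half)] <- Conj(g[1 + seq_len(half)])
        Re(fft(g, inverse = TRUE)) / n
      }))
      max(apply(surr, 2, median))
    }, numeric(1)))
  }
  withr::local_seed(0)
  for (dims in list(c(7, 48), c(6, 49), c(5, 33))) {
    m <- matrix(rnorm(prod(dims)), dims[1])
    expect_equal(null_max_median(m, 5, seed = 11), ref_null(m, 5, 11),
                 tolerance = 1e-10)
  }
  expect_length(null_max_median(matrix(rnorm(40), 4), 1, seed = 1), 1)
})

test_that("synchronized TRs are detected where a strong common deflection sits", {
  withr::local_seed(21)
  n_tr <- 200
  m <- matrix(rnorm(12 * n_tr, sd = 1), 12)
  bump <- exp(-((seq_len(n_tr) - 100)^2) / 8)  # common deflection at TR 99
  m <- m + 6 * matrix(rep(bump, each = 12), 12)
  m <- t(apply(m, 1, scale))
  sr <- find_sync_trs(m, n_boot = 400, n_phase = 400, seed = 2)
  expect_true(any(abs(sr$significant_trs - 99) <= 2))
  expect_true(all(sr$ci_low[sr$significant_trs + 1] > sr$null_threshold))
  expect_true(all(sr$ci_low <= sr$median_trace & sr$median_trace <= sr$ci_high))
})

test_that("all-zero input yields an empty synchronized set", {
  m <- matrix(0, 6, 50)
  sr <- suppressWarnings(find_sync_trs(m, n_boot = 100, n_phase = 100, seed = 1))
  expect_length(sr$significant_trs, 0)
})

test_that("detection is reproducible and subject-order invariant", {
  m <- shared_signal_matrix(n_subj = 10, n_tr = 150, snr = 1.5, seed = 3)
  a <- find_sync_trs(m, n_boot = 500, n_phase = 500, seed = 9)
  b <- find_sync_trs(m, n_boot = 500, n_phase = 500, seed = 9)
  expect_identical(a$significant_trs, b$significant_trs)
  expect_identical(a$null_threshold, b$null_threshold)
  perm <- m[sample(nrow(m)), ]
  c <- find_sync_trs(perm, n_boot = 500, n_phase = 500, seed = 9)
  # the median trace is exactly symmetric in subjects
  expect_equal(c$median_trace, a$median_trace, tolerance = 1e-12)
  expect_identical(c$significant_trs, a$significant_trs)
})

test_that("raising all subjects at a detected TR cannot remove it", {
  m <- shared_signal_matrix(n_subj = 10, n_tr = 150, snr = 1.5, seed = 5)
  a <- find_sync_trs(m, n_boot = 400, n_phase = 400, seed = 9)
  expect_gt(length(a$significant_trs), 0)
  t0 <- a$significant_trs[1]
  m2 <- m
  m2[, t0 + 1] <- m2[, t0 + 1] + 0.5
  b <- find_sync_trs(m2, n_boot = 400, n_phase = 400, seed = 9)
  expect_true(t0 %in% b$significant_trs)
})

test_that("changing the bootstrap count leaves the phase null untouched", {
  m <- shared_signal_matrix(n_subj = 8, n_tr = 100, seed = 6)
  a <- find_sync_trs(m, n_boot = 200, n_phase = 300, seed = 4)
  b <- find_sync_trs(m, n_boot = 400, n_phase = 300, seed = 4)
  expect_identical(a$null_maxima, b$null_maxima)
  expect_identical(a$null_threshold, b$null_threshold)
})

test_that("the mirrored negative test only runs when requested", {
  withr::local_seed(31)
  n_tr <- 150
  m <- matrix(rnorm(10 * n_tr), 10)
  dip <- exp(-((seq_len(n_tr) - 75)^2) / 8)
  m <- t(apply(m - 6 * matrix(rep(dip, each = 10), 10), 1, scale))
  one <- find_sync_trs(m, n_boot = 300, n_phase = 300, seed = 2)
  expect_length(one$negative_trs, 0)
  both <- find_sync_trs(m, n_boot = 300, n_phase = 300, seed = 2,
                        two_sided = TRUE)
  expect_true(any(abs(both$negative_trs - 74) <= 2))
  expect_identical(both$significant_trs, one$significant_trs)
})

test_that("tidy and autoplot expose the per-TR evidence", {
  m <- shared_signal_matrix(n_subj = 8, n_tr = 100, seed = 8)
  sr <- find_sync_trs(m, n_boot = 200, n_phase = 200, seed = 2)
  td <- tidy(sr)
  expect_equal(nrow(td), 100)
  expect_equal(sum(td$significant), length(sr$significant_trs))
  g <- glance(sr)
  expect_equal(g$n_significant, length(sr$significant_trs))
  p <- ggplot2::autoplot(sr)
  expect_s3_class(p, "ggplot")
})
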