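# Time-course conditioning, framewise displacement, QC and nuisance
# regression.

test_that("initial-volume truncation follows the discard contract", {
  ts <- raw_tc(T = 200)
  expect_equal(nrow(truncate_initial(ts, 10)), 190)
  expect_identical(unclass(truncate_initial(ts, 0)), unclass(ts))
  expect_error(truncate_initial(ts, 200), class = "dynfc_validation_error")
  expect_match(tail(attr(truncate_initial(ts, 10), "provenance"), 1),
               "truncate")
})

test_that("despike compresses outliers and leaves inliers untouched", {
  set.seed(21)
  x <- rnorm(500, sd = 0.5)
  ts <- tc_matrix(cbind(x), tr = 2)
  # spike-free series passes through essentially unchanged
  expect_lt(max(abs(unclass(despike(ts)) - x)), 1e-9)
  # a single 10-MAD spike is squashed to at most (thr + 1) robust SDs,
  # measured on the scale the despiker itself estimates (the spiked series)
  x_sp <- x
  x_sp[100] <- median(x) + 10 * mad(x)
  s <- mad(x_sp)
  out <- unclass(despike(tc_matrix(cbind(x_sp), tr = 2)))
  expect_lte(abs(out[100] - median(x_sp)), 4 * s + s)
  expect_lt(max(abs(out[-100] - x_sp[-100])), 1e-9)
  # constant series: degenerate scale, unchanged, no NaN
  cts <- tc_matrix(cbind(rep(2, 50)), tr = 2)
  expect_identical(unclass(despike(cts))[, 1], rep(2, 50))
})

test_that("zero-phase Butterworth matches its closed-form gain", {
  tr <- 2
  fs <- 1 / tr
  T <- 2000
  t_sec <- (0:(T - 1)) * tr
  # forward-backward amplitude = squared one-pass magnitude
  # = 1 / (1 + (tan(pi f/fs)/tan(pi fc/fs))^(2 * order))  (bilinear warping)
  gain_ff <- function(f) 1 / (1 + (tan(pi * f / fs) / tan(pi * 0.15 / fs))^10)
  fit_amp <- function(y, f) {
    keep <- (T %/% 10):(T - T %/% 10)
    X <- cbind(sin(2 * pi * f * t_sec), cos(2 * pi * f * t_sec))[keep, ]
    sqrt(sum(qr.coef(qr(X), y[keep])^2))
  }
  for (f in c(0.05, 0.16, 0.20)) {
    ts <- tc_matrix(cbind(sin(2 * pi * f * t_sec)), tr = tr)
    y <- unclass(butterworth_lowpass(ts))[, 1]
    expect_equal(fit_amp(y, f), gain_ff(f), tolerance = 0.05)
  }
  # DC is preserved
  dc <- tc_matrix(cbind(rep(3.7, 200)), tr = tr)
  expect_lt(max(abs(unclass(butterworth_lowpass(dc)) - 3.7)), 1e-8)
  # cutoff at/above Nyquist is named in the error
  expect_error(butterworth_lowpass(raw_tc(), cutoff_hz = 0.25), "Nyquist",
               class = "dynfc_config_error")
})

test_that("framewise displacement follows the 6-parameter formula", {
  T <- 20
  m <- list(translations = matrix(0, T, 3), rotations = matrix(0, T, 3))
  expect_equal(compute_fd(m)$fd, rep(0, T))
  # single 1 mm x-translation step
  m$translations[10:T, 1] <- 1
  fd <- compute_fd(m)$fd
  expect_equal(fd[10], 1.0)
  expect_equal(sum(fd), 1.0)
  # single 0.02 rad rotation step contributes 0.02 * 50 = 1 mm
  m2 <- list(translations = matrix(0, T, 3), rotations = matrix(0, T, 3))
  m2$rotations[5:T, 2] <- 0.02
  expect_equal(compute_fd(m2)$fd[5], 1.0)
  expect_equal(compute_fd(m2, head_radius_mm = 100)$fd[5], 2.0)
})

test_that("motion QC applies the strict 3 mm / 3 degree rule", {
  mk <- function(t_mm, r_deg) {
    list(translations = matrix(c(t_mm, rep(0, 29)), 10, 3),
         rotations = matrix(c(r_deg * pi / 180, rep(0, 29)), 10, 3))
  }
  expect_true(motion_qc(mk(2.9, 1))$included)
  expect_false(motion_qc(mk(3.1, 0))$included)
  expect_false(motion_qc(mk(0, 3.2))$included)
  # exactly at the limit: retained (strict inequality)
  expect_true(motion_qc(mk(3.0, 3.0))$included)
})

test_that("nuisance regression equals the normal-equations solution", {
  set.seed(31)
  n <- 60
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- rnorm(n)
  res <- regress_nuisance(y, X, keep_intercept = FALSE)
  M <- cbind(1, X$a, X$b)
  beta <- solve(t(M) %*% M, t(M) %*% y)
  expect_lt(max(abs(res - (y - M %*% beta))), 1e-8)
  # y in the span of X -> residuals vanish
  y_span <- 2 + 3 * X$a - X$b
  expect_lt(max(abs(regress_nuisance(y_span, X, keep_intercept = FALSE))),
            1e-10)
  # y orthogonal to the regressors is returned unchanged
  y_orth <- residuals(lm(y ~ a + b, data = X))
  expect_lt(max(abs(regress_nuisance(y_orth, X, keep_intercept = FALSE) -
                      y_orth)), 1e-10)
  # collinear columns are reported
  X_bad <- data.frame(a = X$a, b = X$a)
  expect_error(regress_nuisance(y, X_bad), "collinear",
               class = "dynfc_validation_error")
})

test_that("motion traces round-trip through the 6-column text format", {
  m <- simulate_motion(50, seed = 5)
  path <- tempfile()
  write_motion(m, path)
  back <- read_motion(path)
  expect_equal(back$translations, m$translations, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$mean_fd, m$mean_fd, tolerance = 1e-12)
})

test_that("conditioning records the pipeline order in provenance", {
  ts <- preprocess_timecourse(raw_tc(T = 160))
  prov <- attr(ts, "provenance")
  idx <- vapply(c("truncate", "despike", "detrend", "lowpass"),
                function(s) grep(s, prov)[1], numeric(1))
  expect_true(all(diff(idx) > 0))
})

test_that("filtering then correlating is invariant to affine rescaling", {
  ts <- conditioned_tc(T = 150, C = 3, seed = 7)
  z1 <- sfnc(ts)$z
  scaled <- unclass(ts)
  scaled[, 2] <- 5 * scaled[, 2] - 3
  ts2 <- tc_matrix(scaled, tr = 2, provenance = attr(ts, "provenance"))
  z2 <- sfnc(ts2)$z
  expect_equal(z1, z2, tolerance = 1e-10)
})
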