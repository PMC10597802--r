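# Tapered windows, graphical lasso, Manhattan k-means, elbow selection and
# temporal properties.

test_that("window spec derives durations from primitives", {
  spec <- window_spec()
  expect_equal(spec$width_seconds, 44)
  expect_equal(spec$step_seconds, 2)
  expect_equal(spec$taper_seconds, 6)
  spec30 <- window_spec(width_tr = 30)
  expect_equal(spec30$width_seconds, 60)
})

test_that("the taper is positive, symmetric, centre-peaked and normalised", {
  spec <- window_spec()
  w <- build_taper(spec)
  expect_length(w, 22)
  expect_true(all(w > 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w, rev(w), tolerance = 1e-12)
  expect_equal(which.max(w), 11, tolerance = 1)
  # sigma -> 0 limit: uniform weights
  w0 <- build_taper(window_spec(taper_sigma_tr = 1e-4))
  expect_equal(w0, rep(1 / 22, 22), tolerance = 1e-6)
  expect_warning(build_taper(window_spec(taper_sigma_tr = 0)), "rectangular")
})

test_that("sliding windows follow the W = floor((T-width)/step)+1 contract", {
  spec <- window_spec()
  sw <- sliding_windows(matrix(0, 150, 3), spec)
  expect_length(sw$starts, 129)
  expect_identical(sw$starts[1], 0L)
  expect_length(sliding_windows(matrix(0, 22, 3), spec)$starts, 1)
  expect_error(sliding_windows(matrix(0, 21, 3), spec),
               class = "dynfc_validation_error")
  sw5 <- sliding_windows(matrix(0, 150, 3), window_spec(step_tr = 5))
  expect_length(sw5$starts, floor((150 - 22) / 5) + 1)
})

test_that("graphical lasso hits the unpenalised and penalty-dominated limits", {
  set.seed(61)
  X <- matrix(rnorm(5000 * 5), 5000, 5) %*%
    chol(nearest_spd_cor(matrix(0.3, 5, 5) + 0.7 * diag(5)))
  S <- cov(X)
  expect_lt(max(abs(graphical_lasso(S, 0) - solve(S))), 1e-10)
  Th <- graphical_lasso(S, 100)
  expect_lt(max(abs(Th[upper.tri(Th)])), 1e-6)
  expect_error(graphical_lasso(S, -1), class = "dynfc_config_error")
})

test_that("windowed connectivity keeps provenance, lambda and both scales", {
  ts <- conditioned_tc(T = 80, C = 4, seed = 62)
  ws <- windowed_connectivity(ts, seed = 1)
  expect_s3_class(ws, "windowed_series")
  expect_equal(dim(ws$z), c(80 - 22 + 1, 4, 4))
  expect_true(ws$lambda_selected %in% default_lambda_grid())
  for (w in c(1, 30)) {
    expect_lt(max(abs(ws$z[w, , ] - t(ws$z[w, , ]))), 1e-10)
    expect_identical(diag(ws$z[w, , ]), rep(0, 4))
  }
  expect_error(windowed_connectivity(raw_tc(T = 80, C = 4)),
               class = "dynfc_validation_error")
  expect_error(windowed_connectivity(ts, lambda_grid = numeric()),
               class = "dynfc_config_error")
  # partial scale at lambda -> 0 equals the direct inverse-covariance oracle
  spec <- window_spec()
  wsp <- windowed_connectivity(ts, lambda_grid = 1e-9, scale = "partial",
                               seed = 1)
  seg <- sliding_windows(ts, spec)$segments[[10]]
  S <- dynfc:::weighted_cov(seg, build_taper(spec))
  Th <- solve(S)
  pc <- -Th / sqrt(outer(diag(Th), diag(Th)))
  diag(pc) <- 0
  z_oracle <- fisher_z(pc); diag(z_oracle) <- 0
  expect_lt(max(abs(wsp$z[10, , ] - z_oracle)), 1e-4)
})

test_that("Manhattan k-means honours the L1 minimiser and its invariants", {
  set.seed(63)
  X <- matrix(rnorm(200 * 6), 200, 6)
  # k = 1: centroid is the coordinate-wise median
  f1 <- kmeans_manhattan(X, 1, seed = 2)
  expect_equal(drop(f1$centroid_vecs), apply(X, 2, median),
               tolerance = 1e-12, ignore_attr = TRUE)
  # exact recovery of duplicated points
  pts <- matrix(rnorm(3 * 6, sd = 5), 3, 6)
  Xd <- pts[rep(1:3, each = 10), ]
  fd <- kmeans_manhattan(Xd, 3, seed = 3)
  expect_equal(fd$objective, 0, tolerance = 1e-12)
  expect_equal(length(unique(fd$assignments)), 3)
  # objective trace is nonincreasing on random data
  fr <- kmeans_manhattan(X, 4, n_replicates = 1, seed = 4)
  expect_true(all(diff(fr$trace) <= 1e-9))
  # states are relabelled in descending pooled frequency
  expect_true(all(diff(fr$frequency) <= 0))
  expect_error(kmeans_manhattan(X[1:2, ], 3),
               class = "dynfc_validation_error")
})

test_that("the elbow finds planted cluster counts and handles degeneracy", {
  set.seed(64)
  centers <- matrix(rnorm(3 * 8, sd = 6), 3, 8)
  X <- centers[rep(1:3, each = 60), ] + matrix(rnorm(180 * 8), 180, 8)
  hits <- vapply(1:6, function(i) {
    el <- elbow_select(X, k_candidates = 2:6, n_replicates = 3,
                       seed = 100 + i)
    el$k_selected == 3
  }, logical(1))
  expect_gte(mean(hits), 5 / 6 - 1e-9)
  el <- elbow_select(X, k_candidates = 2:6, seed = 1)
  expect_length(el$validity_curve, 5)
  # identical samples: flat curve, warning, smallest candidate
  Xf <- matrix(1, 30, 4)
  expect_warning(elf <- elbow_select(Xf, k_candidates = 2:4, seed = 1),
                 "flat")
  expect_equal(elf$k_selected, 2L)
})

test_that("temporal properties match hand-built cases", {
  spec <- window_spec()        # step_seconds = 2
  tp <- temporal_properties(list(s1 = c(1, 1, 1)), spec, k = 3)
  expect_equal(tp$fraction_time[tp$state == 1], 1)
  expect_equal(tp$mean_dwell_s[tp$state == 1], 6)
  expect_equal(unique(tp$n_transitions), 0)
  # state never entered: zero fraction and zero dwell
  expect_equal(tp$fraction_time[tp$state == 3], 0)
  expect_equal(tp$mean_dwell_s[tp$state == 3], 0)
  tp2 <- temporal_properties(list(a = c(1, 2, 1, 2)), spec, k = 2)
  expect_equal(unique(tp2$n_transitions), 3)
  expect_equal(tp2$fraction_time, c(0.5, 0.5))
  expect_equal(tp2$mean_dwell_s, c(2, 2))
  expect_error(temporal_properties(list(integer())),
               class = "dynfc_validation_error")
})

test_that("fraction time sums to one per subject", {
  set.seed(65)
  asg <- lapply(1:20, function(i) sample.int(4, 50, replace = TRUE))
  tp <- temporal_properties(asg, window_spec(), k = 4)
  sums <- tapply(tp$fraction_time, tp$subject, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(tp$n_transitions <= 49))
})

test_that("state-entry percentages count subjects, not windows", {
  asg <- list(a = c(1, 1, 2), b = c(1, 1, 1), c = c(2, 2, 2), d = c(1, 2, 1))
  groups <- c("G1", "G1", "G1", "G2")
  pct <- state_entry_percentage(asg, groups, k = 3)
  expect_equal(pct["G1", ], c(State1 = 100 * 2 / 3, State2 = 100 * 2 / 3,
                              State3 = 0))
  expect_equal(unname(pct["G2", ]), c(100, 100, 0))
  # hand-built 4-subject group where 3 enter state 2 -> 75%
  asg2 <- list(a = c(2, 1), b = c(1, 2), c = c(2, 2), d = c(1, 1))
  pct2 <- state_entry_percentage(asg2, rep("G", 4), k = 2)
  expect_equal(unname(pct2["G", "State2"]), 75)
  expect_error(state_entry_percentage(asg, factor(groups,
                                                  levels = c("G1", "G2", "G3"))),
               class = "dynfc_validation_error")
})

test_that("state model methods print, summarise, predict and plot", {
  set.seed(66)
  ts_list <- lapply(1:3, function(i) conditioned_tc(T = 60, C = 4,
                                                    seed = 70 + i))
  ws <- lapply(ts_list, windowed_connectivity, seed = 1)
  names(ws) <- paste0("S", 1:3)
  fit <- kmeans_manhattan(ws, 2, seed = 5)
  expect_output(print(fit), "k = 2")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.dfnc_states")
  pred <- predict(fit, ws[[1]])
  expect_identical(unname(unlist(pred)), unname(fit$assignments[[1]]))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
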