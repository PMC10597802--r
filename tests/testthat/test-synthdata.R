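# Synthetic cohort, Markov states, time courses, motion and voxel mixing.

test_that("default cohort reproduces the published group sizes and moments", {
  coh <- make_cohort(cohort_spec(), seed = 11)
  expect_equal(unname(table(coh$group)[c("RRMS-F", "RRMS-M", "HC-F", "HC-M")]),
               c(135L, 73L, 123L, 105L), ignore_attr = TRUE)
  expect_false(any(duplicated(coh$subject_id)))
  # RRMS-F age sample mean within 2 SE of 37.55 (n = 135, SD 11.47)
  age_f <- coh$age[coh$group == "RRMS-F"]
  expect_lt(abs(mean(age_f) - 37.55), 2 * 11.47 / sqrt(135))
  # patient-only covariates absent for controls, present for patients
  hc <- coh$group %in% c("HC-F", "HC-M")
  expect_true(all(is.na(coh$lv[hc])) && all(is.na(coh$edss[hc])))
  expect_true(all(!is.na(coh$dd[!hc])))
  expect_true(all(coh$bpf > 0 & coh$bpf <= 1))
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_spec(n = c("RRMS-F" = 0L, "RRMS-M" = 5L,
                                 "HC-F" = 5L, "HC-M" = 5L)),
               class = "dynfc_config_error")
  bad_sd <- cohort_spec
  expect_error(cohort_spec(age = rbind("RRMS-F" = c(37, 0),
                                       "RRMS-M" = c(35, 11),
                                       "HC-F" = c(37, 12),
                                       "HC-M" = c(38, 11))),
               class = "dynfc_config_error")
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- make_cohort(tiny_cohort(), seed = 5)
  b <- make_cohort(tiny_cohort(), seed = 5)
  expect_identical(a, b)
})

test_that("Markov sequences honour degenerate and ergodic regimes", {
  # identity transition + point initial mass -> constant sequence
  sq <- simulate_state_sequence(diag(3), c(0, 1, 0), 50, seed = 2)
  expect_identical(sq$states, rep(2L, 50))
  # n = 1 draws from pi0 alone
  sq1 <- simulate_state_sequence(diag(3), c(0, 0, 1), 1, seed = 3)
  expect_identical(sq1$states, 3L)
  # ergodic chain: occupancy matches the left-eigenvector stationary vector
  P <- matrix(c(0.90, 0.05, 0.05,
                0.10, 0.80, 0.10,
                0.05, 0.15, 0.80), 3, 3, byrow = TRUE)
  e <- eigen(t(P))
  stat <- Re(e$vectors[, which.min(abs(e$values - 1))])
  stat <- stat / sum(stat)
  sq <- simulate_state_sequence(P, stat, 100000, seed = 4)
  occ <- tabulate(sq$states, 3) / 100000
  expect_lt(max(abs(occ - stat)), 0.01)
  # non-stochastic transition matrix is rejected
  expect_error(simulate_state_sequence(matrix(1, 2, 2), c(0.5, 0.5), 10),
               class = "dynfc_validation_error")
})

test_that("state-conditional time courses reproduce planted covariance", {
  sq <- simulate_state_sequence(diag(1), 1, 20000, seed = 6)
  tc <- simulate_subject_timecourse(sq, list(diag(3)), tr = 2,
                                    noise_sd = 0, seed = 6)
  expect_lt(max(abs(cov(unclass(tc)) - diag(3))), 0.05)
  expect_identical(attr(tc, "tr"), 2)
  # non-SPD covariance rejected
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  sq2 <- simulate_state_sequence(diag(1), 1, 10, seed = 1)
  expect_error(simulate_subject_timecourse(sq2, list(bad)),
               class = "dynfc_validation_error")
})

test_that("windows inside a planted segment sit closest to their own state", {
  truth <- synth_truth()
  spec <- window_spec()
  zcor <- function(R) { z <- fisher_z(R); diag(z) <- 0; z }
  cents <- lapply(truth$states, function(R) upper_tri_vec(zcor(R)))
  set.seed(8)
  for (s in 1:3) {
    # one long pure segment per state
    sq <- structure(list(states = rep(s, 200), k = 3,
                         transition_matrix = diag(3),
                         initial_distribution = c(s == 1:3)),
                    class = "state_sequence")
    tc <- simulate_subject_timecourse(sq, truth$states, noise_sd = 0)
    seg <- sliding_windows(tc, spec)$segments[[90]]
    S <- cov(seg)
    f <- upper_tri_vec(zcor(stats::cov2cor(S)))
    d <- vapply(cents, function(cc) sum(abs(f - cc)), numeric(1))
    expect_equal(unname(which.min(d)), s)
  }
})

test_that("motion traces match the FD scaling contract", {
  m0 <- simulate_motion(100, severity = 0, seed = 1)
  expect_true(all(m0$fd == 0))
  expect_identical(m0$mean_fd, 0)
  m <- simulate_motion(200, severity = 1, seed = 2)
  expect_identical(m$fd[1], 0)
  expect_true(all(m$fd >= 0))
  expect_error(simulate_motion(1), class = "dynfc_validation_error")
  # stochastic check: mean of mean FD over 200 subjects near the 0.068 target
  fds <- vapply(1:200, function(s) simulate_motion(200, seed = s)$mean_fd,
                numeric(1))
  expect_lt(abs(mean(fds) - 0.068), 0.02)
})

test_that("voxel mixing is exact linear algebra at zero noise", {
  set.seed(3)
  tcs <- matrix(rnorm(50 * 4), 50, 4)
  maps <- matrix(rnorm(4 * 30), 4, 30)
  X <- mix_to_voxels(tcs, maps, noise_sd = 0)
  expect_equal(dim(X), c(30, 50))
  expect_equal(qr(X)$rank, 4)
  expect_equal(X, t(maps) %*% t(tcs), tolerance = 1e-12)
  expect_error(mix_to_voxels(tcs, maps[1:3, ]),
               class = "dynfc_validation_error")
})

test_that("cohort dataset is reproducible and exports ground truth", {
  truth <- synth_truth()
  a <- simulate_cohort(tiny_cohort(3L), truth, T = 60, seed = 9)
  b <- simulate_cohort(tiny_cohort(3L), truth, T = 60, seed = 9)
  expect_identical(a$cohort, b$cohort)
  expect_identical(lapply(a$timecourses, unclass),
                   lapply(b$timecourses, unclass))
  expect_identical(a$sequences[[1]]$states, b$sequences[[1]]$states)
  expect_s3_class(a$truth, "ground_truth")
  # occupancy rows are simplex vectors, covariances SPD
  expect_true(all(abs(rowSums(truth$occupancy) - 1) < 1e-8))
  for (S in truth$states) {
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("cohort TSV round-trips", {
  coh <- make_cohort(tiny_cohort(), seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$group, coh$group)
  expect_equal(back$age, coh$age, tolerance = 1e-9)
})
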