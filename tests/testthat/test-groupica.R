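# PCA reduction, Infomax, ICASSO stability, GICA3 back-reconstruction and
# template matching.

test_that("PCA matches a direct eigendecomposition and inverts exact-rank data", {
  set.seed(41)
  X <- matrix(rnorm(80 * 12), 80, 12)
  red <- pca_reduce(X, 12)
  ev_oracle <- sort(eigen(cov(X), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(red$eigenvalues, ev_oracle, tolerance = 1e-8)
  expect_true(all(diff(red$eigenvalues) <= 1e-12))
  # rank-3 matrix reconstructs exactly from 3 components
  X3 <- matrix(rnorm(80 * 3), 80, 3) %*% matrix(rnorm(3 * 12), 3, 12)
  red3 <- suppressWarnings(pca_reduce(X3, 3))
  expect_lt(max(abs(pca_reconstruct(red3) - X3)), 1e-8)
  # rank overflow reduces with a warning
  expect_warning(pca_reduce(X3, 10), "rank")
  # whitening: identity covariance of scores
  redw <- pca_reduce(X, 5, whiten = TRUE)
  expect_lt(max(abs(cov(redw$scores) - diag(5))), 1e-8)
})

test_that("Infomax recovers Laplacian sources under rotation mixing", {
  set.seed(42)
  N <- 5000
  S <- matrix(rexp(2 * N) * sign(rnorm(2 * N)), 2, N)
  theta <- 0.7
  A <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  X <- A %*% S
  e <- eigen(cov(t(X)), symmetric = TRUE)
  Xw <- diag(1 / sqrt(e$values)) %*% t(e$vectors) %*% X
  W <- infomax_unmix(Xw, seed = 1)
  rec <- W %*% Xw
  cors <- abs(cor(t(rec), t(S)))
  best <- apply(cors, 1, max)
  expect_true(all(best > 0.95))
  # already-independent sources: unmixing approximately a signed permutation
  Sw <- S / sqrt(rowMeans(S^2))
  W2 <- infomax_unmix(Sw, seed = 2)
  W2n <- W2 / apply(abs(W2), 1, max)
  offpattern <- apply(abs(W2n), 1, function(r) sort(r, decreasing = TRUE)[2])
  expect_true(all(offpattern < 0.1))
})

test_that("Infomax flags Gaussian inputs and diverging learning rates", {
  set.seed(43)
  G <- matrix(rnorm(2 * 3000), 2, 3000)
  expect_warning(infomax_unmix(G, max_iter = 5, seed = 1), "identifiable")
  S <- matrix(rexp(2 * 500) * sign(rnorm(2 * 500)), 2, 500)
  expect_error(suppressWarnings(infomax_unmix(S, learning_rate = 50, seed = 1)),
               "learning_rate", class = "dynfc_validation_error")
})

test_that("ICASSO stability is 1 for identical runs and low for noise runs", {
  # two exactly uncorrelated sources (orthogonal sinusoids over full periods)
  N <- 400
  t <- seq_len(N)
  Xw <- rbind(sqrt(2) * sin(2 * pi * 4 * t / N),
              sqrt(2) * cos(2 * pi * 9 * t / N))
  W <- diag(2)
  ic <- icasso_stability(list(W, W, W), Xw)
  expect_equal(ic$stability_index, c(1, 1), tolerance = 1e-10)
  expect_true(all(diff(ic$stability_index) <= 0))
  # independent random "runs": mean stability below 0.5
  set.seed(44)
  Z <- matrix(rnorm(6 * 500), 6, 500)
  runs <- lapply(1:8, function(i) matrix(rnorm(36), 6, 6))
  icn <- icasso_stability(runs, Z)
  expect_lt(mean(icn$stability_index), 0.5)
  expect_error(icasso_stability(list(W), Xw),
               class = "dynfc_validation_error")
})

test_that("GICA3 identities: degenerate group and subject-map average", {
  set.seed(45)
  C <- 4; V <- 400; T <- 80
  # spatial ICA identifies by map non-Gaussianity: plant Laplacian maps
  maps <- matrix(rexp(C * V) * sign(rnorm(C * V)), C, V)
  mk_subj <- function(seed) {
    set.seed(seed)
    src <- matrix(rnorm(T * C), T, C)
    t(mix_to_voxels(src, maps, noise_sd = 0.05, seed = seed))
  }
  # single-subject "group": back-reconstructed maps equal the group maps
  g1 <- group_ica(list(mk_subj(1)), n_subject_pc = 20, n_group_pc = C,
                  n_runs = 2, seed = 9)
  br <- gica3_backreconstruct(g1, 1)
  expect_lt(max(abs(br$maps - g1$group_maps)), 1e-6)
  # multi-subject: mean of subject maps equals the group maps (algebraic)
  g3 <- group_ica(lapply(1:3, mk_subj), n_subject_pc = 20, n_group_pc = C,
                  n_runs = 3, seed = 10)
  avg <- Reduce(`+`, g3$subject_maps) / 3
  expect_lt(max(abs(avg - g3$group_maps)), 1e-6)
  # subject time courses track the planted sources
  set.seed(2)
  src2 <- matrix(rnorm(T * C), T, C)
  X2 <- t(mix_to_voxels(src2, maps, noise_sd = 0.05, seed = 77))
  g2 <- group_ica(list(X2), n_subject_pc = 20, n_group_pc = C,
                  n_runs = 2, seed = 11)
  m <- match_components(g2$group_maps, maps)
  tc_cor <- abs(cor(g2$subject_timecourses[[1]], src2))
  expect_true(all(apply(tc_cor, 2, max) > 0.95))
  expect_error(gica3_backreconstruct(g2, 5),
               class = "dynfc_validation_error")
})

test_that("component matching is optimal, recovers shuffles, reports surplus", {
  set.seed(46)
  ref <- matrix(rnorm(4 * 200), 4, 200)
  # identity case
  m_id <- match_components(ref, ref)
  expect_identical(m_id$permutation, 1:4)
  expect_true(all(m_id$signs == 1))
  # shuffled, sign-flipped copy is recovered exactly
  perm <- c(3L, 1L, 4L, 2L)
  flips <- c(-1, 1, -1, 1)
  est <- ref[perm, ] * flips
  m <- match_components(est, ref)
  expect_identical(m$permutation, perm)
  expect_identical(m$signs, as.numeric(flips))
  # optimality vs exhaustive permutation search on correlated maps
  est2 <- ref + matrix(rnorm(4 * 200, sd = 1.2), 4, 200)
  m2 <- match_components(est2, ref)
  R <- abs(cor(t(est2), t(ref)))
  perms <- rbind(
    do.call(rbind, lapply(1:4, function(i) {
      do.call(rbind, lapply(setdiff(1:4, i), function(j) {
        rest <- setdiff(1:4, c(i, j))
        rbind(c(i, j, rest), c(i, j, rev(rest)))
      }))
    })))
  best <- max(apply(perms, 1, function(p) sum(R[cbind(1:4, p)])))
  expect_equal(sum(R[cbind(1:4, m2$permutation)]), best, tolerance = 1e-12)
  # more estimates than references: surplus unassigned
  m3 <- match_components(rbind(ref, rnorm(200)), ref)
  expect_equal(sum(is.na(m3$permutation)), 1)
  expect_error(match_components(ref, ref[, 1:50]),
               class = "dynfc_validation_error")
})
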