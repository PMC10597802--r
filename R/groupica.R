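# Compact group ICA front end: PCA reduction, Infomax unmixing, ICASSO
# stability over reseeded runs, GICA3 back-reconstruction, and optimal
# component-to-template matching.

#' PCA reduction
#'
#' Centred SVD-based principal component analysis retaining `n_components`
#' components, with the operators needed to invert the reduction on
#' rank-limited data.
#'
#' @param X `observations x variables` matrix.
#' @param n_components Number of components to retain (default 20).
#' @param whiten Scale scores to unit variance.
#' @return List of class `pca_reduction`: `scores`
#'   (`observations x n_components`), `loadings`, `eigenvalues`
#'   (nonincreasing), `center`, `whiten`, `sdev`.
#' @export
pca_reduce <- function(X, n_components = 20, whiten = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  r <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
  if (n_components > r) {
    warning(sprintf("n_components = %d exceeds rank %d: reduced", n_components, r))
    n_components <- r
  }
  d <- sv$d[seq_len(n_components)]
  scores <- sv$u[, seq_len(n_components), drop = FALSE] %*% diag(d, n_components)
  sdev <- d / sqrt(max(n - 1, 1))
  if (whiten) scores <- sweep(scores, 2, sdev, `/`)
  structure(list(scores = scores,
                 loadings = sv$v[, seq_len(n_components), drop = FALSE],
                 eigenvalues = sdev^2,
                 center = ctr, whiten = whiten, sdev = sdev),
            class = "pca_reduction")
}

#' Invert a PCA reduction
#'
#' @param red A `pca_reduction`.
#' @param scores Optional replacement scores.
#' @return Reconstructed data matrix.
#' @export
pca_reconstruct <- function(red, scores = red$scores) {
  if (red$whiten) scores <- sweep(scores, 2, red$sdev, `*`)
  sweep(scores %*% t(red$loadings), 2, red$center, `+`)
}

excess_kurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2 - 3
}

#' Infomax ICA unmixing
#'
#' Natural-gradient Infomax with the logistic nonlinearity on whitened data
#' (rows = channels, columns = samples). Converges when the natural-gradient
#' update norm falls below `tol`; diverging runs abort with advice to reduce
#' the learning rate. Near-Gaussian inputs (all |excess kurtosis| < 0.5)
#' trigger a non-identifiability warning, as the Infomax objective is
#' rotation-invariant for Gaussian sources.
#'
#' @param Xw `k x N` whitened data.
#' @param learning_rate Step size (default 0.05).
#' @param max_iter Maximum iterations (default 1000).
#' @param tol Convergence tolerance on the update norm (default 1e-6).
#' @param seed Optional seed for the random orthonormal initialisation.
#' @return `k x k` unmixing matrix `W`; estimated sources are `W %*% Xw`.
#' @export
infomax_unmix <- function(Xw, learning_rate = 0.05, max_iter = 1000,
                          tol = 1e-6, seed = NULL) {
  Xw <- as.matrix(Xw)
  k <- nrow(Xw)
  N <- ncol(Xw)
  kurt <- apply(Xw, 1, excess_kurtosis)
  if (all(abs(kurt) < 0.5)) {
    warning(paste("inputs look Gaussian (|excess kurtosis| < 0.5):",
                  "the unmixing is not identifiable up to rotation"))
  }
  if (!is.null(seed)) set.seed(seed)
  W <- qr.Q(qr(matrix(rnorm(k * k), k, k)))
  I_k <- diag(k)
  for (it in seq_len(max_iter)) {
    U <- W %*% Xw
    Y <- 1 / (1 + exp(-U))
    grad <- I_k + ((1 - 2 * Y) %*% t(U)) / N
    W_new <- W + learning_rate * grad %*% W
    if (!all(is.finite(W_new)) || max(abs(W_new)) > 1e8) {
      stop_validation(paste("Infomax diverged: reduce learning_rate",
                            "(currently %g)"), learning_rate)
    }
    delta <- max(abs(grad))
    W <- W_new
    if (delta < tol) break
  }
  W
}

#' ICASSO stability analysis over reseeded ICA runs
#'
#' Components from all runs are pooled, similarity is measured as absolute
#' correlation between source estimates, and the pool is clustered into `k`
#' clusters (average-linkage hierarchical clustering). The stability index of
#' a cluster is its average within-cluster similarity minus its average
#' similarity to out-of-cluster components (clamped to `[0, 1]`); the
#' centrotype (most central member) represents the cluster.
#'
#' @param runs List of unmixing matrices from reseeded runs (>= 2).
#' @param Xw The whitened data the runs were fitted on (`k x N`).
#' @return List of class `icasso_result`, components ordered by stability
#'   descending: `unmixing` (centrotype rows), `stability_index`, `clusters`,
#'   `n_runs`.
#' @export
icasso_stability <- function(runs, Xw) {
  if (length(runs) < 2) stop_validation("need at least 2 runs, got %d",
                                        length(runs))
  k <- nrow(runs[[1]])
  sources <- do.call(rbind, lapply(runs, function(W) W %*% Xw))
  run_of <- rep(seq_along(runs), each = k)
  sim <- abs(cor(t(sources)))
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, k = k)
  stability <- numeric(k)
  centro <- integer(k)
  for (c in seq_len(k)) {
    members <- which(cl == c)
    others <- which(cl != c)
    within <- if (length(members) > 1) {
      sm <- sim[members, members]
      mean(sm[upper.tri(sm)])
    } else 1
    between <- if (length(others)) mean(sim[members, others, drop = FALSE]) else 0
    stability[c] <- min(1, max(0, within - between))
    centro[c] <- members[which.max(rowSums(sim[members, members,
                                               drop = FALSE]))]
  }
  ord <- order(stability, decreasing = TRUE)
  W_out <- do.call(rbind, lapply(centro[ord], function(i) {
    runs[[run_of[i]]][((i - 1) %% k) + 1, , drop = FALSE]
  }))
  structure(list(unmixing = W_out,
                 stability_index = stability[ord],
                 clusters = cl, n_runs = length(runs)),
            class = "icasso_result")
}

#' Group ICA with ICASSO stability and GICA3 back-reconstruction
#'
#' Two-stage reduction (per-subject temporal PCA, concatenation, group PCA),
#' Infomax ICA repeated over reseeded runs with ICASSO stability selection,
#' and GICA3 back-reconstruction of subject-specific spatial maps and time
#' courses. The subject-map average reproduces the group maps exactly (the
#' GICA3 identity).
#'
#' @param X_list List of `T x V` subject data matrices (voxel series in
#'   columns).
#' @param n_subject_pc Subject-level PCA size (default 30).
#' @param n_group_pc Group-level PCA size / number of components (default 20).
#' @param n_runs ICASSO runs (default 100).
#' @param learning_rate,max_iter Infomax settings.
#' @param seed Optional seed.
#' @return List of class `group_ica`: `group_maps` (`n_ic x V`, stability
#'   order), `subject_maps` (list of `n_ic x V`), `subject_timecourses`
#'   (list of `T x n_ic`), `stability_index`, `mixing`, `unmixing`, plus the
#'   reduction operators.
#' @export
group_ica <- function(X_list, n_subject_pc = 30, n_group_pc = 20,
                      n_runs = 100, learning_rate = 0.05, max_iter = 1000,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- length(X_list)
  V <- ncol(X_list[[1]])
  k1 <- min(n_subject_pc, nrow(X_list[[1]]) - 1, V)
  # subject-level temporal reduction: Y_i = F_i' X_i
  F_list <- list()
  Y_list <- list()
  for (i in seq_len(M)) {
    Xi <- as.matrix(X_list[[i]])
    Xi <- sweep(Xi, 2, colMeans(Xi))
    sv <- svd(Xi, nu = k1, nv = 0)
    F_list[[i]] <- sv$u
    Y_list[[i]] <- t(sv$u) %*% Xi
  }
  Y <- do.call(rbind, Y_list)
  k2 <- min(n_group_pc, nrow(Y), V)
  svg <- svd(Y, nu = k2, nv = 0)
  G <- svg$u                        # (M*k1) x k2
  d <- svg$d[seq_len(k2)]
  Z <- t(G) %*% Y                   # k2 x V
  # whiten spatial rows: Zw Zw' / V = I
  K <- sqrt(V) / d
  Zw <- Z * K
  runs <- lapply(seq_len(n_runs), function(r) {
    suppressWarnings(infomax_unmix(Zw, learning_rate = learning_rate,
                                   max_iter = max_iter))
  })
  ic <- if (n_runs >= 2) icasso_stability(runs, Zw) else
    list(unmixing = runs[[1]], stability_index = rep(NA_real_, k2))
  W_ica <- ic$unmixing
  S <- W_ica %*% Zw                 # group maps, k2 x V
  # total mixing: Z = A S
  A <- diag(d / sqrt(V), k2) %*% solve(W_ica)
  A_inv <- solve(A)
  subject_maps <- vector("list", M)
  subject_tcs <- vector("list", M)
  for (i in seq_len(M)) {
    rows_i <- ((i - 1) * k1 + 1):(i * k1)
    G_i <- G[rows_i, , drop = FALSE]
    subject_maps[[i]] <- M * (A_inv %*% t(G_i) %*% Y_list[[i]])
    subject_tcs[[i]] <- F_list[[i]] %*% G_i %*% A
  }
  structure(list(group_maps = S,
                 subject_maps = subject_maps,
                 subject_timecourses = subject_tcs,
                 stability_index = ic$stability_index,
                 mixing = A, unmixing = W_ica,
                 reduction = list(F_list = F_list, G = G, d = d, K = K),
                 n_components = k2),
            class = "group_ica")
}

#' GICA3 back-reconstruction
#'
#' Subject-specific spatial maps and time courses from a fitted group
#' decomposition and the retained reduction operators. The subject-average of
#' the maps equals the group maps (an algebraic identity of the scheme).
#'
#' @param gica A fitted `group_ica`.
#' @param subject Subject index.
#' @return List with `maps` (`n_ic x V`) and `timecourses` (`T x n_ic`).
#' @export
gica3_backreconstruct <- function(gica, subject) {
  if (subject < 1 || subject > length(gica$subject_maps)) {
    stop_validation("subject index %d outside 1..%d", subject,
                    length(gica$subject_maps))
  }
  list(maps = gica$subject_maps[[subject]],
       timecourses = gica$subject_timecourses[[subject]])
}

# Hungarian algorithm (shortest augmenting path, O(n^3)) for the square
# assignment problem: minimise sum of cost[i, perm[i]].
hungarian_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)       # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0 + 0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  perm <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) perm[p[j]] <- j - 1
  perm
}

#' Match estimated components to reference maps
#'
#' Optimal one-to-one assignment (Hungarian algorithm) maximising total
#' absolute correlation between estimated and reference maps, with signs
#' aligned so matched correlations are positive. When there are more
#' estimates than references, the surplus estimates are reported unassigned.
#'
#' @param estimated `n_est x V` matrix of estimated maps.
#' @param reference `n_ref x V` matrix of reference maps.
#' @return List: `permutation` (per estimate, the matched reference index or
#'   `NA`), `signs` (+1/-1 per estimate, `NA` if unmatched), `correlations`
#'   (absolute correlation of each match).
#' @export
match_components <- function(estimated, reference) {
  estimated <- as.matrix(estimated)
  reference <- as.matrix(reference)
  if (ncol(estimated) != ncol(reference)) {
    stop_validation("voxel dimensions differ: %d vs %d",
                    ncol(estimated), ncol(reference))
  }
  n_e <- nrow(estimated)
  n_r <- nrow(reference)
  R <- cor(t(estimated), t(reference))       # n_e x n_r
  n <- max(n_e, n_r)
  cost <- matrix(0, n, n)                    # dummy pads cost 0
  cost[seq_len(n_e), seq_len(n_r)] <- -abs(R)
  perm_full <- hungarian_min(cost)
  permutation <- rep(NA_integer_, n_e)
  signs <- rep(NA_real_, n_e)
  corr <- rep(NA_real_, n_e)
  for (i in seq_len(n_e)) {
    j <- perm_full[i]
    if (j <= n_r && abs(R[i, j]) > 0) {
      permutation[i] <- as.integer(j)
      signs[i] <- sign(R[i, j])
      corr[i] <- abs(R[i, j])
    }
  }
  list(permutation = permutation, signs = signs, correlations = corr)
}
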