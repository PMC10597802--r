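# Dynamic FNC core: tapered sliding windows, per-window sparse-precision
# connectivity (graphical lasso), k-means state clustering under the Manhattan
# distance, elbow-based model-order selection, and state temporal properties.

#' Sliding-window specification
#'
#' @param width_tr Window width in TRs (default 22, i.e. 44 s at TR = 2 s).
#' @param step_tr Step between window starts in TRs (default 1).
#' @param taper_sigma_tr SD of the Gaussian taper kernel in TRs (default 3,
#'   i.e. 6 s at TR = 2 s).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @return List of class `window_spec` with derived `width_seconds`,
#'   `step_seconds` and `taper_seconds` recomputed from the primitives.
#' @export
window_spec <- function(width_tr = 22, step_tr = 1, taper_sigma_tr = 3,
                        tr_seconds = 2) {
  if (width_tr < 2) stop_config("width_tr must be >= 2")
  if (step_tr < 1) stop_config("step_tr must be >= 1")
  if (tr_seconds <= 0) stop_config("tr_seconds must be > 0")
  if (taper_sigma_tr > 0 && width_tr < 3 * taper_sigma_tr) {
    warning(sprintf("width_tr = %d < 3 * taper_sigma_tr = %g (advisory)",
                    width_tr, 3 * taper_sigma_tr))
  }
  structure(list(width_tr = as.integer(width_tr),
                 step_tr = as.integer(step_tr),
                 taper_sigma_tr = taper_sigma_tr,
                 tr_seconds = tr_seconds,
                 width_seconds = width_tr * tr_seconds,
                 step_seconds = step_tr * tr_seconds,
                 taper_seconds = taper_sigma_tr * tr_seconds),
            class = "window_spec")
}

#' Gaussian-tapered window weights
#'
#' A rectangular window of the specified width convolved with a Gaussian
#' kernel of SD `taper_sigma_tr`, truncated to the window width and normalised
#' to sum to one. With `taper_sigma_tr <= 0` a plain rectangle is returned
#' with a warning.
#'
#' @param spec A [window_spec()].
#' @return Numeric weight vector of length `width_tr`, summing to 1.
#' @export
build_taper <- function(spec) {
  w <- spec$width_tr
  if (w < 2) stop_validation("window width must be >= 2")
  sigma <- spec$taper_sigma_tr
  if (sigma <= 0) {
    warning("taper_sigma_tr <= 0: using a plain rectangular window")
    return(rep(1 / w, w))
  }
  half <- max(1L, ceiling(4 * sigma))
  kern <- exp(-((-half:half)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  rect <- rep(1, w)
  full <- convolve(rect, rev(kern), type = "open")
  centre <- (length(full) - w) %/% 2
  weights <- full[(centre + 1):(centre + w)]
  weights / sum(weights)
}

# 0-based window start indices; windows are half-open [start, start + width).
window_starts <- function(T, spec) {
  if (T < spec$width_tr) {
    stop_validation("series length %d is shorter than window width %d",
                    T, spec$width_tr)
  }
  seq(0L, T - spec$width_tr, by = spec$step_tr)
}

#' Sliding-window segmentation
#'
#' Splits a time-course matrix into `W = floor((T - width) / step) + 1`
#' half-open windows `[start, start + width)`, starts 0-based.
#'
#' @param ts A [tc_matrix()] or plain matrix.
#' @param spec A [window_spec()].
#' @return List with `starts` (0-based) and `segments` (list of
#'   `width x C` matrices).
#' @export
sliding_windows <- function(ts, spec) {
  X <- as.matrix(unclass(ts))
  starts <- window_starts(nrow(X), spec)
  segments <- lapply(starts, function(s) {
    X[(s + 1):(s + spec$width_tr), , drop = FALSE]
  })
  list(starts = starts, segments = segments)
}

#' Graphical lasso: L1-penalised inverse covariance
#'
#' Blockwise coordinate descent estimate of the precision matrix under an L1
#' penalty on its off-diagonal entries. At `lambda = 0` the plain inverse is
#' returned (the covariance must then be positive definite).
#'
#' @param S Covariance matrix (SPD, or repaired by ridge jitter upstream).
#' @param lambda Nonnegative penalty.
#' @param max_iter,tol Convergence controls.
#' @return Precision matrix estimate (symmetric).
#' @export
graphical_lasso <- function(S, lambda, max_iter = 100, tol = 1e-6) {
  S <- as.matrix(S)
  if (lambda < 0) stop_config("lambda must be >= 0")
  glasso_fit_cpp(S, lambda, max_iter = max_iter, tol = tol)
}

# Precision -> regularised covariance -> correlations, Fisher-z, zero diag.
regularized_cov_to_z <- function(Theta) {
  S <- solve((Theta + t(Theta)) / 2)
  d <- sqrt(diag(S))
  r <- S / outer(d, d)
  z <- fisher_z(r)
  diag(z) <- 0
  z
}

# Precision -> partial correlations (sign-flipped scaled precision),
# Fisher-z transformed, zero diagonal.
precision_to_z <- function(Theta) {
  d <- sqrt(diag(Theta))
  pc <- -Theta / outer(d, d)
  diag(pc) <- 0
  z <- fisher_z(pc)
  diag(z) <- 0
  z
}

# Taper-weighted covariance of one window segment (weights sum to 1).
weighted_cov <- function(seg, weights) {
  mu <- colSums(seg * weights)
  Xc <- sweep(seg, 2, mu)
  t(Xc * weights) %*% Xc
}

# Gaussian log-likelihood of precision Theta under sample covariance S
# (up to constants): logdet(Theta) - tr(S Theta).
gaussian_loglik <- function(Theta, S) {
  determinant(Theta, logarithm = TRUE)$modulus[1] - sum(S * Theta)
}

default_lambda_grid <- function(n = 10) {
  exp(seq(log(1e-3), log(1), length.out = n))
}

# Select one lambda per subject by repeated random train/test splits of the
# windows: fit the graphical lasso to the pooled covariance of the training
# windows, score by the Gaussian log-likelihood of the held-out windows'
# pooled covariance, and keep the penalty maximising the mean held-out
# likelihood. The pooled training covariance is well conditioned, so the
# selected penalty is typically light; it still guards the occasional
# degenerate window at estimation time.
select_lambda <- function(covs, lambda_grid, cv_repeats = 10,
                          train_frac = 0.75, seed = NULL) {
  if (length(lambda_grid) == 0) stop_config("lambda grid is empty")
  if (!is.null(seed)) set.seed(seed)
  W <- length(covs)
  n_train <- min(W - 1L, max(2L, floor(train_frac * W)))
  scores <- matrix(NA_real_, cv_repeats, length(lambda_grid))
  for (r in seq_len(cv_repeats)) {
    tr_idx <- sample.int(W, n_train)
    S_train <- Reduce(`+`, covs[tr_idx]) / n_train
    S_test <- Reduce(`+`, covs[-tr_idx]) / (W - n_train)
    for (l in seq_along(lambda_grid)) {
      Theta <- graphical_lasso(S_train, lambda_grid[l])
      scores[r, l] <- gaussian_loglik(Theta, S_test)
    }
  }
  mean_scores <- colMeans(scores)
  list(lambda = lambda_grid[which.max(mean_scores)],
       grid = lambda_grid, scores = mean_scores)
}

#' Windowed sparse-precision connectivity for one subject
#'
#' Per tapered sliding window: weighted covariance, graphical-lasso precision
#' estimate at a penalty selected once per subject by repeated random-split
#' cross-validated held-out Gaussian log-likelihood, then Fisher-z
#' connectivity values. On the default `"correlation"` scale the regularised
#' covariance (the inverse of the sparse precision estimate) is converted to
#' correlations; on the `"partial"` scale the precision matrix is converted
#' to partial correlations directly. Non-SPD weighted covariances are
#' repaired by ridge jitter (logged in the result).
#'
#' @param ts A conditioned [tc_matrix()].
#' @param spec A [window_spec()].
#' @param lambda_grid Candidate penalties (default 10 points, log-spaced on
#'   `[1e-3, 1]`).
#' @param cv_repeats Number of random-split repetitions (default 10).
#' @param seed Optional seed for the cross-validation splits.
#' @param scale `"correlation"` (regularised-covariance correlations, the
#'   default) or `"partial"` (partial correlations from the precision
#'   matrix).
#' @param check_provenance Require despike + low-pass provenance.
#' @return List of class `windowed_series`: `z` (`W x C x C` array),
#'   `window_starts` (0-based), `spec`, `lambda_selected`, `lambda_scores`,
#'   `scale`, `n_ridge_repairs`, `subject_id`.
#' @export
windowed_connectivity <- function(ts, spec = window_spec(),
                                  lambda_grid = default_lambda_grid(),
                                  cv_repeats = 10, seed = NULL,
                                  scale = c("correlation", "partial"),
                                  check_provenance = TRUE) {
  scale <- match.arg(scale)
  if (check_provenance) {
    prov <- tc_provenance(ts)
    if (!any(grepl("^despike", prov)) || !any(grepl("^lowpass", prov))) {
      stop_validation("time courses must be conditioned before dFNC")
    }
  }
  X <- as.matrix(unclass(ts))
  C <- ncol(X)
  if (C >= spec$width_tr) {
    warning(sprintf("C = %d >= window width %d: estimates will be heavily
regularised", C, spec$width_tr))
  }
  sw <- sliding_windows(X, spec)
  weights <- build_taper(spec)
  n_repair <- 0L
  covs <- lapply(sw$segments, function(seg) {
    S <- weighted_cov(seg, weights)
    if (!is_spd(S, eps = 1e-10)) {
      n_repair <<- n_repair + 1L
      S <- S + diag(1e-6 * mean(diag(S)), C)
    }
    S
  })
  sel <- select_lambda(covs, lambda_grid, cv_repeats = cv_repeats, seed = seed)
  W <- length(covs)
  S_seq <- array(unlist(covs), dim = c(C, C, W))
  thetas <- glasso_windows_cpp(S_seq, sel$lambda)
  z <- array(0, dim = c(W, C, C))
  for (w in seq_len(W)) {
    Theta <- thetas[, , w]
    z[w, , ] <- if (scale == "partial") precision_to_z(Theta)
                else regularized_cov_to_z(Theta)
  }
  if (n_repair > 0) {
    message(sprintf("windowed_connectivity: %d window covariance(s) repaired
by ridge jitter", n_repair))
  }
  structure(list(z = z, window_starts = sw$starts, spec = spec,
                 lambda_selected = sel$lambda, lambda_scores = sel$scores,
                 scale = scale, n_ridge_repairs = n_repair,
                 subject_id = attr(ts, "subject_id")),
            class = "windowed_series")
}

# Stack all subjects' windows into a samples x features matrix of vectorised
# upper triangles, with a subject index per row.
pool_windows <- function(windowed_list) {
  mats <- lapply(windowed_list, function(ws) {
    W <- dim(ws$z)[1]
    t(vapply(seq_len(W), function(w) upper_tri_vec(ws$z[w, , ]),
             numeric(dim(ws$z)[2] * (dim(ws$z)[2] - 1) / 2)))
  })
  subject <- rep(seq_along(windowed_list), vapply(mats, nrow, integer(1)))
  list(samples = do.call(rbind, mats), subject = subject,
       subject_ids = names(windowed_list) %||%
         vapply(windowed_list, function(w) w$subject_id, character(1)))
}

#' k-means connectivity-state clustering with Manhattan distance
#'
#' Clusters vectorised window connectivity matrices under the L1 (city-block)
#' distance, with coordinate-wise-median centroid updates (the exact L1
#' minimiser), best of `n_replicates` random starts, at most `max_iter`
#' iterations each. States are relabelled in descending pooled frequency, so
#' State 1 is always the most frequent.
#'
#' @param x Either a list of `windowed_series` (one per subject) or a plain
#'   `samples x features` matrix.
#' @param k Number of states.
#' @param n_replicates Random restarts (default 5).
#' @param max_iter Maximum iterations per restart (default 150).
#' @param seed Optional seed for the restarts.
#' @param C Matrix dimension, required only when `x` is a plain matrix and
#'   centroid matrices are wanted.
#' @return Object of class `dfnc_states`: `k`, `centroids` (list of `C x C`
#'   matrices, when dimension known), `centroid_vecs` (`k x features`),
#'   `assignments` (per-subject integer sequences for list input, otherwise a
#'   single vector), `objective` (total within-cluster L1 distance),
#'   `frequency` (pooled state frequencies), `iterations`, `trace`.
#' @export
kmeans_manhattan <- function(x, k, n_replicates = 5, max_iter = 150,
                             seed = NULL, C = NULL) {
  if (!is.null(seed)) set.seed(seed)
  by_subject <- FALSE
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    pooled <- pool_windows(x)
    samples <- pooled$samples
    subject <- pooled$subject
    subject_ids <- pooled$subject_ids
    C <- dim(x[[1]]$z)[2]
    by_subject <- TRUE
  } else {
    samples <- as.matrix(x)
    subject <- rep(1L, nrow(samples))
    subject_ids <- NULL
  }
  n <- nrow(samples)
  if (k < 1) stop_config("k must be >= 1")
  if (n < k) stop_validation("need at least k = %d samples, got %d", k, n)
  init <- t(replicate(n_replicates, sample.int(n, k)))
  if (k == 1) init <- matrix(init, n_replicates, 1)
  fit <- kmeans_l1_cpp(samples, k, init - 1L, max_iter = max_iter)
  assign_vec <- fit$assignments + 1L

  # relabel by descending pooled frequency; ties broken by original label
  freq <- tabulate(assign_vec, nbins = k)
  ord <- order(freq, decreasing = TRUE)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  assign_vec <- relabel[assign_vec]
  centroid_vecs <- fit$centroids[ord, , drop = FALSE]
  freq <- freq[ord]

  centroids <- NULL
  if (!is.null(C)) {
    centroids <- lapply(seq_len(k), function(s) {
      unvec_upper_tri(centroid_vecs[s, ], C)
    })
  }
  assignments <- if (by_subject) {
    split(assign_vec, subject)
  } else {
    assign_vec
  }
  if (by_subject && !is.null(subject_ids)) names(assignments) <- subject_ids
  structure(list(k = k, centroids = centroids,
                 centroid_vecs = centroid_vecs,
                 assignments = assignments,
                 objective = fit$objective,
                 frequency = freq,
                 proportions = freq / sum(freq),
                 iterations = fit$iterations,
                 trace = fit$trace,
                 reseeds = fit$reseeds,
                 C = C),
            class = "dfnc_states")
}

#' Elbow-based selection of the number of states
#'
#' For each candidate `k` the mean within-cluster L1 distance (the cluster
#' dispersion, monotone nonincreasing in `k`) and the within/between validity
#' ratio (mean within-cluster distance over mean pairwise between-centroid
#' distance) are computed. The selected `k` maximises the discrete second
#' difference (curvature) of the dispersion curve over the interior
#' candidates — the classic elbow. The within/between ratio is reported as
#' `validity_curve` but is not used for selection: on realistic data it is
#' non-monotone in `k`, which makes its curvature unstable. A flat dispersion
#' curve returns the smallest candidate with a warning.
#'
#' @param x Input as in [kmeans_manhattan()].
#' @param k_candidates Candidate state counts (default `2:10`).
#' @param n_replicates,max_iter,seed Passed to [kmeans_manhattan()].
#' @return List: `k_selected`, `dispersion_curve` and `validity_curve`
#'   (named by candidate), `models` (the fitted `dfnc_states` per candidate).
#' @export
elbow_select <- function(x, k_candidates = 2:10, n_replicates = 5,
                         max_iter = 150, seed = NULL) {
  if (length(k_candidates) < 2) stop_config("need at least 2 candidate k")
  if (!is.null(seed)) set.seed(seed)
  k_candidates <- sort(unique(as.integer(k_candidates)))
  models <- list()
  validity <- numeric(length(k_candidates))
  dispersion <- numeric(length(k_candidates))
  for (i in seq_along(k_candidates)) {
    k <- k_candidates[i]
    fit <- kmeans_manhattan(x, k, n_replicates = n_replicates,
                            max_iter = max_iter)
    n_samples <- sum(fit$frequency)
    within <- fit$objective / n_samples
    D <- l1_cross_dist_cpp(fit$centroid_vecs, fit$centroid_vecs)
    between <- mean(D[upper.tri(D)])
    dispersion[i] <- within
    validity[i] <- within / between
    models[[as.character(k)]] <- fit
  }
  names(validity) <- names(dispersion) <- k_candidates
  if (diff(range(dispersion)) < 1e-12) {
    warning("flat dispersion curve: returning the smallest candidate k")
    k_sel <- k_candidates[1]
  } else if (length(k_candidates) >= 3) {
    curv <- rep(NA_real_, length(k_candidates))
    for (i in 2:(length(k_candidates) - 1)) {
      curv[i] <- dispersion[i - 1] - 2 * dispersion[i] + dispersion[i + 1]
    }
    k_sel <- k_candidates[which.max(curv)]
  } else {
    k_sel <- k_candidates[which.min(dispersion)]
  }
  list(k_selected = k_sel, dispersion_curve = dispersion,
       validity_curve = validity, models = models)
}

#' Temporal properties of state assignment sequences
#'
#' Per subject and state: fraction time (proportion of windows), mean dwell
#' time (mean consecutive-run length times the step duration, in seconds; 0
#' for states never entered), plus the per-subject transition count (adjacent
#' unequal pairs) and an entered flag.
#'
#' @param assignments Integer vector (one subject) or list of vectors.
#' @param spec A [window_spec()] providing `step_seconds`.
#' @param k Number of states (default: max observed).
#' @return A data.frame with one row per subject x state: `subject`, `state`,
#'   `fraction_time`, `mean_dwell_s`, `mean_dwell_windows`, `entered`,
#'   `n_transitions` (repeated within subject).
#' @export
temporal_properties <- function(assignments, spec = window_spec(), k = NULL) {
  if (!is.list(assignments)) assignments <- list(assignments)
  if (any(vapply(assignments, length, integer(1)) == 0)) {
    stop_validation("assignment sequences must be nonempty")
  }
  if (is.null(k)) k <- max(unlist(assignments))
  ids <- names(assignments) %||% as.character(seq_along(assignments))
  out <- vector("list", length(assignments))
  for (i in seq_along(assignments)) {
    a <- as.integer(assignments[[i]])
    W <- length(a)
    runs <- run_lengths(a)
    frac <- tabulate(a, nbins = k) / W
    dwell_w <- vapply(seq_len(k), function(s) {
      r <- runs$length[runs$state == s]
      if (length(r) == 0) 0 else mean(r)
    }, numeric(1))
    n_trans <- sum(diff(a) != 0)
    out[[i]] <- data.frame(subject = ids[i], state = seq_len(k),
                           fraction_time = frac,
                           mean_dwell_windows = dwell_w,
                           mean_dwell_s = dwell_w * spec$step_seconds,
                           entered = frac > 0,
                           n_transitions = n_trans,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' State-entry percentage per group
#'
#' For each group and state, `100 * (number of subjects with at least one
#' window in the state) / (group size)`.
#'
#' @param assignments Named list of per-subject assignment vectors.
#' @param groups Factor/character vector of group labels aligned with
#'   `assignments`.
#' @param k Number of states (default: max observed).
#' @return `group x state` matrix of percentages.
#' @export
state_entry_percentage <- function(assignments, groups, k = NULL) {
  if (length(assignments) != length(groups)) {
    stop_validation("assignments and groups must be aligned")
  }
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) {
    stop_validation("empty group: %s",
                    paste(levels(groups)[table(groups) == 0], collapse = ", "))
  }
  if (is.null(k)) k <- max(unlist(assignments))
  entered <- t(vapply(assignments, function(a) {
    tabulate(as.integer(a), nbins = k) > 0
  }, logical(k)))
  if (k == 1) entered <- matrix(entered, ncol = 1)
  out <- matrix(NA_real_, nlevels(groups), k,
                dimnames = list(levels(groups), paste0("State", seq_len(k))))
  for (g in levels(groups)) {
    out[g, ] <- 100 * colMeans(entered[groups == g, , drop = FALSE])
  }
  out
}

#' Export state assignments and temporal properties as TSV
#'
#' @param states A `dfnc_states` with per-subject assignments.
#' @param windowed_list The `windowed_series` list used for fitting (for
#'   window starts).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(states, windowed_list, path) {
  rows <- list()
  for (i in seq_along(states$assignments)) {
    a <- states$assignments[[i]]
    id <- names(states$assignments)[i] %||% as.character(i)
    rows[[i]] <- data.frame(subject = id,
                            window_start = windowed_list[[i]]$window_starts,
                            state = a)
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
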