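# Ground-truth generator: latent connectivity states, hidden-Markov state
# switching, state-conditional Gaussian time courses, motion traces and
# optional voxel-space mixtures. Everything downstream (windowing, clustering,
# temporal properties, group statistics) can be validated by parameter
# recovery against the bundle returned here.

# Partition C components into three pseudo-networks of near-equal size.
default_blocks <- function(C) {
  split(seq_len(C), rep(1:3, length.out = C, each = ceiling(C / 3))[seq_len(C)])
}

block_cor <- function(C, blocks, within, between) {
  R <- matrix(between, C, C)
  for (b in blocks) R[b, b] <- within
  diag(R) <- 1
  nearest_spd_cor(R)
}

#' Default connectivity-state correlation profiles
#'
#' Three qualitatively distinct states: a sparse state (weak connectivity
#' everywhere), a segregated middle state (strong within-network coupling with
#' anticorrelated between-network coupling), and a high state (dense positive
#' connectivity within and between networks). This mirrors the sparse /
#' middle / high connected states typically recovered from resting-state
#' cohorts, with the middle state's between-network anticorrelation standing
#' in for the familiar segregation of task-positive and task-negative systems.
#'
#' @param C Number of components.
#' @param blocks List of component index vectors defining pseudo-networks.
#' @return List of three `C x C` SPD correlation matrices.
#' @export
state_profiles <- function(C = 10, blocks = default_blocks(C)) {
  list(
    sparse = block_cor(C, blocks, within = 0.10, between = 0.02),
    middle = block_cor(C, blocks, within = 0.70, between = -0.15),
    high   = block_cor(C, blocks, within = 0.80, between = 0.55)
  )
}

#' Ground truth for a synthetic multi-group dynamic-connectivity cohort
#'
#' Assembles the latent regime a synthetic cohort is generated from: per-state
#' SPD covariance (correlation) matrices, per-group state occupancy vectors
#' (the stationary distribution of each group's sticky Markov chain), a
#' stickiness parameter controlling expected dwell time, an additive static
#' connectivity offset per group (applied on the correlation scale to every
#' state and projected back to SPD), and optional component-to-voxel mixing
#' maps for the group-ICA front end.
#'
#' Default occupancies place healthy females predominantly in the middle
#' connected state and shift female patients toward the sparse state, while the
#' male contrast is planted as a static connectivity reduction — the
#' qualitative pattern of sex-specific static/dynamic dissociation the
#' generator is designed to emulate.
#'
#' @param C Number of components.
#' @param states List of state correlation matrices (default
#'   [state_profiles()]).
#' @param occupancy 4 x k matrix (rows = groups) of planted state occupancies;
#'   rows must sum to 1.
#' @param stickiness Per-step probability of re-drawing the state from the
#'   occupancy vector; expected dwell in state `s` is
#'   `1 / (stickiness * (1 - occupancy_s))` steps.
#' @param static_effects Named list: per group, `list(blocks = c(i, j),
#'   delta = x)` adds `x` to all correlations between pseudo-networks `i` and
#'   `j` in every state for that group.
#' @param blocks Pseudo-network partition used by `static_effects`.
#' @param noise_sd White observation noise SD added on top of the
#'   state-conditional signal (signal scale is unit variance).
#' @param drift List with `order` (polynomial degree), `amplitude` (SD units)
#'   and `period_s` (slow cosine period, seconds); `NULL` disables drift.
#' @param mixing_maps Optional `C x V` component-to-voxel weight matrix.
#' @return A list of class `ground_truth`.
#' @export
synth_truth <- function(C = 10,
                        states = state_profiles(C),
                        occupancy = rbind("RRMS-F" = c(0.55, 0.25, 0.20),
                                          "RRMS-M" = c(0.45, 0.33, 0.22),
                                          "HC-F"   = c(0.25, 0.53, 0.22),
                                          "HC-M"   = c(0.45, 0.33, 0.22)),
                        stickiness = 0.03,
                        static_effects = list(
                          "RRMS-M" = list(blocks = c(1, 2), delta = -0.20)),
                        blocks = default_blocks(C),
                        noise_sd = 0.1,
                        drift = list(order = 2, amplitude = 0.15,
                                     period_s = 128),
                        mixing_maps = NULL) {
  k <- length(states)
  for (S in states) {
    if (!is_spd(S)) stop_validation("state covariance is not positive definite")
    if (nrow(S) != C) stop_validation("state covariance dimension != C")
  }
  if (ncol(occupancy) != k) stop_config("occupancy must have k = %d columns", k)
  if (any(abs(rowSums(occupancy) - 1) > 1e-8)) {
    stop_config("occupancy rows must sum to 1")
  }
  if (stickiness <= 0 || stickiness > 1) {
    stop_config("stickiness must be in (0, 1]")
  }
  group_covs <- list()
  for (g in rownames(occupancy)) {
    covs <- states
    eff <- static_effects[[g]]
    if (!is.null(eff)) {
      b1 <- blocks[[eff$blocks[1]]]
      b2 <- blocks[[eff$blocks[2]]]
      covs <- lapply(covs, function(S) {
        S[b1, b2] <- S[b1, b2] + eff$delta
        S[b2, b1] <- t(S[b1, b2])
        nearest_spd_cor(S)
      })
    }
    group_covs[[g]] <- covs
  }
  structure(list(C = C, k = k, states = states, occupancy = occupancy,
                 stickiness = stickiness, static_effects = static_effects,
                 blocks = blocks, group_covs = group_covs,
                 noise_sd = noise_sd, drift = drift,
                 mixing_maps = mixing_maps),
            class = "ground_truth")
}

# Sticky transition matrix with stationary distribution pi:
# P = (1 - a) I + a 1 pi'.
occupancy_transition <- function(pi, stickiness) {
  k <- length(pi)
  P <- (1 - stickiness) * diag(k) + stickiness * matrix(pi, k, k, byrow = TRUE)
  P
}

#' Simulate a Markov state sequence
#'
#' @param P `k x k` row-stochastic transition matrix.
#' @param pi0 Initial distribution (length-k simplex vector).
#' @param n Sequence length (>= 1).
#' @param seed Optional integer seed.
#' @return List of class `state_sequence` with integer `states` in `1..k`,
#'   `k`, `transition_matrix` and `initial_distribution`.
#' @export
simulate_state_sequence <- function(P, pi0, n, seed = NULL) {
  P <- as.matrix(P)
  k <- nrow(P)
  if (ncol(P) != k) stop_validation("transition matrix must be square")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) {
    stop_validation("transition matrix rows must be nonnegative and sum to 1")
  }
  if (length(pi0) != k || any(pi0 < 0) || abs(sum(pi0) - 1) > 1e-8) {
    stop_validation("pi0 must be a length-%d probability vector", k)
  }
  if (n < 1) stop_validation("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  s <- integer(n)
  s[1] <- sample.int(k, 1, prob = pi0)
  if (n > 1) {
    for (t in 2:n) s[t] <- sample.int(k, 1, prob = P[s[t - 1], ])
  }
  structure(list(states = s, k = k, transition_matrix = P,
                 initial_distribution = pi0),
            class = "state_sequence")
}

#' Simulate one subject's component time courses
#'
#' Each volume is drawn from a zero-mean multivariate Gaussian with the
#' covariance of its current latent state, plus white observation noise and an
#' optional slow drift (low-order polynomial plus slow cosine, per component).
#'
#' @param seq A `state_sequence` (length `T`).
#' @param covs List of `k` SPD `C x C` covariance matrices (one per state), or
#'   a `ground_truth` plus `group` to select the group-adjusted covariances.
#' @param tr Repetition time in seconds (default 2).
#' @param noise_sd White-noise SD.
#' @param drift Drift settings as in [synth_truth()]; `NULL` for none.
#' @param seed Optional integer seed.
#' @return A time-course matrix (see [tc_matrix()]) of dimension `T x C`.
#' @export
simulate_subject_timecourse <- function(seq, covs, tr = 2, noise_sd = 0,
                                        drift = NULL, seed = NULL,
                                        subject_id = "sim") {
  states <- seq$states
  n <- length(states)
  if (!is.list(covs)) stop_validation("covs must be a list of matrices")
  C <- nrow(covs[[1]])
  chols <- lapply(covs, function(S) {
    if (!is_spd(S)) stop_validation("state covariance is not SPD")
    chol(S)
  })
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(0, n, C)
  Z <- matrix(rnorm(n * C), n, C)
  for (s in seq_len(seq$k)) {
    i <- which(states == s)
    if (length(i)) X[i, ] <- Z[i, , drop = FALSE] %*% chols[[s]]
  }
  if (noise_sd > 0) X <- X + matrix(rnorm(n * C, sd = noise_sd), n, C)
  if (!is.null(drift) && drift$amplitude > 0) {
    tt <- seq_len(n) / n
    secs <- (seq_len(n) - 1) * tr
    for (j in seq_len(C)) {
      poly_coef <- rnorm(drift$order, sd = drift$amplitude)
      d <- rep(0, n)
      for (p in seq_len(drift$order)) d <- d + poly_coef[p] * (tt - 0.5)^p
      phase <- runif(1, 0, 2 * pi)
      d <- d + drift$amplitude * cos(2 * pi * secs / drift$period_s + phase)
      X[, j] <- X[, j] + d
    }
  }
  tc_matrix(X, tr = tr, subject_id = subject_id,
            provenance = "simulated")
}

#' Simulate a motion-realignment trace
#'
#' Random-walk traces for three translations (mm) and three rotations
#' (radians), scaled so the expected mean framewise displacement equals
#' `severity * target_fd` (rotational steps contribute through a 50 mm head
#' radius arc length, matching [compute_fd()]).
#'
#' @param T Number of volumes (>= 2).
#' @param severity Nonnegative multiplier on `target_fd`; 0 gives constant
#'   parameters and zero FD.
#' @param target_fd Expected mean FD in mm at severity 1 (default 0.068).
#' @param seed Optional seed.
#' @param head_radius_mm Head radius used for the rotation scaling.
#' @return A `motion_trace` list with `translations` (`T x 3`),
#'   `rotations` (`T x 3`), and FD fields filled by [compute_fd()].
#' @export
simulate_motion <- function(T, severity = 1, target_fd = 0.068, seed = NULL,
                            head_radius_mm = 50) {
  if (T < 2) stop_validation("T must be >= 2, got %d", T)
  if (severity < 0) stop_config("severity must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  fd_target <- severity * target_fd
  # E|N(0, s)| = s * sqrt(2/pi); six parameter streams contribute equally.
  s_t <- fd_target * sqrt(pi / 2) / 6
  s_r <- s_t / head_radius_mm
  trans <- apply(matrix(rnorm(3 * (T - 1), sd = s_t), T - 1, 3), 2, cumsum)
  rot <- apply(matrix(rnorm(3 * (T - 1), sd = s_r), T - 1, 3), 2, cumsum)
  if (severity == 0) {
    trans <- matrix(0, T - 1, 3)
    rot <- matrix(0, T - 1, 3)
  }
  m <- list(translations = rbind(0, matrix(trans, T - 1, 3)),
            rotations = rbind(0, matrix(rot, T - 1, 3)))
  class(m) <- "motion_trace"
  compute_fd(m, head_radius_mm = head_radius_mm)
}

#' Mix component time courses into a voxel-by-time array
#'
#' Linear mixture `X = t(maps) %*% t(tcs)` plus Gaussian noise; the fixture
#' generator for the group-ICA front end.
#'
#' @param tcs `T x C` time-course matrix.
#' @param maps `C x V` component-to-voxel weights.
#' @param noise_sd Gaussian noise SD.
#' @param seed Optional seed.
#' @return `V x T` voxel-by-time matrix.
#' @export
mix_to_voxels <- function(tcs, maps, noise_sd = 0, seed = NULL) {
  tcs <- as.matrix(tcs)
  if (ncol(tcs) != nrow(maps)) {
    stop_validation("component count mismatch: tcs has %d, maps has %d",
                    ncol(tcs), nrow(maps))
  }
  if (!is.null(seed)) set.seed(seed)
  X <- t(maps) %*% t(tcs)
  if (noise_sd > 0) X <- X + matrix(rnorm(length(X), sd = noise_sd), nrow(X))
  X
}

#' Simulate a complete cohort dataset
#'
#' Draws a cohort table, one hidden-Markov state sequence and component
#' time-course matrix per subject (group-specific occupancy and static
#' effects), plus a motion trace targeting each subject's tabulated mean FD.
#' Exports the full ground truth for downstream parameter-recovery checks.
#'
#' @param spec A [cohort_spec()].
#' @param truth A [synth_truth()].
#' @param T Number of volumes per subject.
#' @param tr Repetition time, seconds.
#' @param seed Integer seed; fans out deterministically per subject.
#' @return List of class `cohort_dataset` with elements `cohort`,
#'   `timecourses` (list of `tc_matrix`), `sequences` (list of
#'   `state_sequence`), `motion` (list of `motion_trace`), `truth`, `T`, `tr`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), truth = synth_truth(),
                            T = 150, tr = 2, seed = 1) {
  cohort <- make_cohort(spec, seed = child_seed(seed, "cohort"))
  n <- nrow(cohort)
  timecourses <- vector("list", n)
  sequences <- vector("list", n)
  motion <- vector("list", n)
  for (i in seq_len(n)) {
    g <- as.character(cohort$group[i])
    pi_g <- truth$occupancy[g, ]
    P <- occupancy_transition(pi_g, truth$stickiness)
    sq <- simulate_state_sequence(
      P, pi_g, T, seed = child_seed(seed, paste0("seq", i)))
    timecourses[[i]] <- simulate_subject_timecourse(
      sq, truth$group_covs[[g]], tr = tr, noise_sd = truth$noise_sd,
      drift = truth$drift, seed = child_seed(seed, paste0("tc", i)),
      subject_id = cohort$subject_id[i])
    motion[[i]] <- simulate_motion(
      T, severity = 1, target_fd = max(cohort$mean_fd[i], 1e-4),
      seed = child_seed(seed, paste0("mot", i)))
    sequences[[i]] <- sq
  }
  names(timecourses) <- names(sequences) <- names(motion) <- cohort$subject_id
  structure(list(cohort = cohort, timecourses = timecourses,
                 sequences = sequences, motion = motion, truth = truth,
                 T = T, tr = tr, seed = seed),
            class = "cohort_dataset")
}

#' Ground-truth window labels from a planted state sequence
#'
#' The majority (modal) planted state within each sliding window; used to
#' score clustering recovery against the generator's truth.
#'
#' @param states Integer state sequence (volume level).
#' @param spec A [window_spec()].
#' @return Integer vector, one label per window.
#' @export
window_true_labels <- function(states, spec) {
  starts <- window_starts(length(states), spec)
  vapply(starts, function(s) {
    seg <- states[(s + 1):(s + spec$width_tr)]
    as.integer(names(which.max(table(seg))))
  }, integer(1))
}
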