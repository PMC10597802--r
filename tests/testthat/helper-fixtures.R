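# Shared fixture builders: everything is generated in code at test time.

# White-noise time-course matrix.
raw_tc <- function(T = 120, C = 4, tr = 2, seed = 1) {
  set.seed(seed)
  tc_matrix(matrix(rnorm(T * C), T, C), tr = tr, subject_id = "fix")
}

# A conditioned series carrying the provenance the connectivity stages check.
conditioned_tc <- function(T = 120, C = 4, tr = 2, seed = 1) {
  preprocess_timecourse(raw_tc(T + 10, C, tr, seed))
}

# Tiny four-group cohort spec.
tiny_cohort <- function(n = 5L) {
  cohort_spec(n = c("RRMS-F" = n, "RRMS-M" = n, "HC-F" = n, "HC-M" = n))
}

# Brute-force run-length oracle for temporal properties, written independently
# of the package implementation (explicit loop, no rle()).
brute_temporal <- function(a, step_seconds, k) {
  runs <- list()
  start <- 1
  for (i in seq_along(a)) {
    if (i == length(a) || a[i + 1] != a[i]) {
      runs[[length(runs) + 1]] <- c(state = a[start], len = i - start + 1)
      start <- i + 1
    }
  }
  runs <- do.call(rbind, runs)
  frac <- dwell <- numeric(k)
  for (s in seq_len(k)) {
    lens <- runs[runs[, "state"] == s, "len"]
    frac[s] <- sum(lens) / length(a)
    dwell[s] <- if (length(lens)) mean(lens) * step_seconds else 0
  }
  trans <- 0L
  for (i in seq_len(length(a) - 1)) if (a[i + 1] != a[i]) trans <- trans + 1L
  list(fraction = frac, dwell_s = dwell, transitions = trans)
}

# Literal Benjamini-Hochberg step-up, from the definition.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# Rank-formula AUC oracle via explicit pair counting.
brute_auc <- function(pos, neg) {
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(pos) * length(neg))
}
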