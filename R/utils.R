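# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("dynfc_config_error", "error", "condition")))
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("dynfc_validation_error", "error", "condition")))
}

#' Vectorize the upper triangle of a square matrix
#'
#' Connectivity matrices are symmetric with a zero diagonal, so all information
#' lives in the strict upper triangle (column-major order, the layout assumed
#' everywhere in this package).
#'
#' @param m Square symmetric matrix.
#' @return Numeric vector of length `C*(C-1)/2`.
#' @export
upper_tri_vec <- function(m) {
  m[upper.tri(m)]
}

#' Rebuild a symmetric zero-diagonal matrix from its upper-triangle vector
#'
#' @param v Vector as produced by [upper_tri_vec()].
#' @param C Matrix dimension.
#' @param labels Optional row/column names.
#' @return A `C x C` symmetric matrix with zero diagonal.
#' @export
unvec_upper_tri <- function(v, C, labels = NULL) {
  stopifnot(length(v) == C * (C - 1) / 2)
  m <- matrix(0, C, C)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

#' Fisher z-transform with clipping
#'
#' Correlations are clipped to `[-clip, clip]` before `atanh` so perfectly
#' correlated series yield a large finite value rather than `Inf`.
#'
#' @param r Correlation values.
#' @param clip Clipping bound, default `1 - 1e-7`.
#' @return `atanh` of the clipped values.
#' @export
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

# Project a symmetric matrix to the nearest (in the eigenvalue-clipping sense)
# symmetric positive-definite correlation matrix: clip eigenvalues at eps,
# then rescale to unit diagonal.
nearest_spd_cor <- function(R, eps = 1e-6) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) > eps) {
    d <- sqrt(diag(R))
    return(R / outer(d, d))
  }
  vals <- pmax(e$values, eps)
  S <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(S))
  S / outer(d, d)
}

is_spd <- function(S, eps = 1e-10) {
  S <- (S + t(S)) / 2
  min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > eps
}

# Deterministic fan-out of one master seed into per-stage child seeds.
# Kept below 2^31 - 1 so it is a valid R integer seed.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * (seq_len(nchar(stage)) %% 31 + 1))
  as.integer((as.numeric(seed) * 10007 + h * 97) %% 2147483646 + 1)
}

# Run-length encoding oracle-style helper used by temporal_properties.
run_lengths <- function(x) {
  r <- rle(as.integer(x))
  data.frame(state = r$values, length = r$lengths)
}
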