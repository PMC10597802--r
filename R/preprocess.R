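# Time-course conditioning and motion control: truncation, despiking,
# detrending, zero-phase low-pass filtering, framewise displacement, QC
# exclusion and nuisance regression. Each step appends to an append-only
# provenance record carried with the matrix.

#' Component time-course matrix
#'
#' A plain numeric `T x C` matrix carrying the repetition time, a subject
#' identifier and an append-only provenance record of conditioning steps.
#'
#' @param values `T x C` numeric matrix (rows = volumes, columns = components).
#' @param tr Repetition time in seconds.
#' @param subject_id Subject identifier.
#' @param provenance Character vector of applied steps.
#' @return An object of class `tc_matrix`.
#' @export
tc_matrix <- function(values, tr, subject_id = "subj",
                      provenance = character()) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_validation("values must be numeric")
  structure(values, tr = tr, subject_id = subject_id,
            provenance = provenance,
            class = c("tc_matrix", "matrix", "array"))
}

tc_update <- function(ts, values, step) {
  if (any(!is.finite(values))) {
    stop_validation("step '%s' produced non-finite values", step)
  }
  tc_matrix(values, tr = attr(ts, "tr"),
            subject_id = attr(ts, "subject_id"),
            provenance = c(attr(ts, "provenance"), step))
}

#' @export
print.tc_matrix <- function(x, ...) {
  cat(sprintf("Time-course matrix: %d volumes x %d components, TR = %gs\n",
              nrow(x), ncol(x), attr(x, "tr")))
  cat("subject:", attr(x, "subject_id"), "\n")
  cat("provenance:", paste(attr(x, "provenance"), collapse = " -> "), "\n")
  invisible(x)
}

tc_provenance <- function(ts) attr(ts, "provenance")

#' Discard initial volumes
#'
#' Removes the first `n_discard` volumes (signal-equilibration scans) from a
#' time-course matrix.
#'
#' @param ts A [tc_matrix()].
#' @param n_discard Number of leading volumes to drop (default 10).
#' @return The truncated `tc_matrix` with provenance updated.
#' @export
truncate_initial <- function(ts, n_discard = 10) {
  if (n_discard >= nrow(ts)) {
    stop_validation("cannot discard %d volumes from a %d-volume series",
                    n_discard, nrow(ts))
  }
  if (n_discard == 0) return(ts)
  tc_update(ts, unclass(ts)[-seq_len(n_discard), , drop = FALSE],
            sprintf("truncate(n=%d)", n_discard))
}

#' Despike by robust clipping with smooth compression
#'
#' Per component, samples are centred and scaled by median and MAD; samples
#' beyond `z_threshold` robust SDs are compressed smoothly toward the
#' threshold (`z' = thr + tanh(|z| - thr)`, sign preserved), so no despiked
#' sample deviates by more than `(z_threshold + 1)` robust SDs. Samples inside
#' the threshold are untouched. Constant series (MAD = 0) pass through
#' unchanged.
#'
#' @param ts A [tc_matrix()].
#' @param z_threshold Robust z threshold (default 4).
#' @return Despiked `tc_matrix`.
#' @export
despike <- function(ts, z_threshold = 4) {
  X <- unclass(ts)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ctr <- median(x)
    s <- mad(x)
    if (s <= .Machine$double.eps) next
    z <- (x - ctr) / s
    out <- abs(z) > z_threshold
    if (any(out)) {
      z[out] <- sign(z[out]) * (z_threshold + tanh(abs(z[out]) - z_threshold))
      X[, j] <- ctr + z * s
    }
  }
  tc_update(ts, X, sprintf("despike(z=%g)", z_threshold))
}

#' Polynomial detrend
#'
#' Removes a per-component polynomial trend (least squares), retaining the
#' series mean.
#'
#' @param ts A [tc_matrix()].
#' @param order Polynomial order (default 3).
#' @return Detrended `tc_matrix`.
#' @export
detrend_poly <- function(ts, order = 3) {
  X <- unclass(ts)
  n <- nrow(X)
  B <- cbind(1, stats::poly(seq_len(n), degree = order))
  fit <- lm.fit(B, X)
  res <- X - B %*% fit$coefficients
  res <- sweep(res, 2, colMeans(X), `+`)
  tc_update(ts, res, sprintf("detrend(order=%d)", order))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` digital Butterworth low-pass filter
#' forward-backward (zero phase) per component. The forward-backward pass
#' squares the one-way magnitude response; DC is preserved.
#'
#' @param ts A [tc_matrix()] with known TR.
#' @param order Filter order (default 5).
#' @param cutoff_hz High-frequency cutoff in Hz (default 0.15); must be below
#'   the Nyquist frequency `1 / (2 * tr)`.
#' @return Filtered `tc_matrix`.
#' @export
butterworth_lowpass <- function(ts, order = 5, cutoff_hz = 0.15) {
  tr <- attr(ts, "tr")
  if (is.null(tr) || !is.finite(tr)) stop_validation("TR unknown")
  nyquist <- 1 / (2 * tr)
  if (cutoff_hz >= nyquist) {
    stop_config("cutoff %g Hz must be below the Nyquist frequency %g Hz",
                cutoff_hz, nyquist)
  }
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  X <- unclass(ts)
  n <- nrow(X)
  # odd-reflection padding suppresses the zero-initial-condition edge
  # transient of the forward-backward pass (and keeps DC exact)
  pad <- min(n - 1, max(3 * (order + 1), 50))
  Y <- apply(X, 2, function(x) {
    mu <- mean(x)
    xc <- x - mu
    xp <- c(2 * xc[1] - xc[(pad + 1):2], xc,
            2 * xc[n] - xc[(n - 1):(n - pad)])
    yp <- signal::filtfilt(bf, xp)
    yp[(pad + 1):(pad + n)] + mu
  })
  tc_update(ts, Y, sprintf("lowpass(order=%d,cutoff=%gHz)", order, cutoff_hz))
}

# Squared (forward-backward) magnitude response of the digital Butterworth
# low-pass at frequency f_hz; closed form via the bilinear-transform warping.
butterworth_gain2 <- function(f_hz, cutoff_hz, fs_hz, order = 5) {
  ratio <- tan(pi * f_hz / fs_hz) / tan(pi * cutoff_hz / fs_hz)
  (1 / (1 + ratio^(2 * order)))^2
}

#' Framewise displacement from realignment parameters
#'
#' FD at volume `t` is the sum of absolute backward differences of the three
#' translations (mm) plus the three rotations converted to arc length at the
#' given head radius. The first volume has no predecessor, so `fd[1] = 0`.
#'
#' @param motion A `motion_trace` list with `translations` (`T x 3`, mm) and
#'   `rotations` (`T x 3`, radians).
#' @param head_radius_mm Head radius for the rotation arc length (default 50).
#' @return The `motion_trace` with `fd` and `mean_fd` filled.
#' @export
compute_fd <- function(motion, head_radius_mm = 50) {
  if (is.null(motion$translations) || is.null(motion$rotations)) {
    stop_validation("motion trace must contain translations and rotations")
  }
  tr <- as.matrix(motion$translations)
  ro <- as.matrix(motion$rotations)
  if (ncol(tr) != 3 || ncol(ro) != 3) {
    stop_validation("motion trace needs 3 translation and 3 rotation columns")
  }
  if (nrow(tr) < 2) stop_validation("at least 2 volumes required")
  fd <- c(0, rowSums(abs(diff(tr))) + head_radius_mm * rowSums(abs(diff(ro))))
  motion$fd <- fd
  motion$mean_fd <- mean(fd)
  motion
}

#' Motion quality control decision
#'
#' A subject is excluded when maximum absolute translation exceeds 3 mm or
#' maximum absolute rotation exceeds 3 degrees (strict inequality: a subject
#' at exactly the limit is retained).
#'
#' @param motion A `motion_trace`.
#' @param max_translation_mm,max_rotation_deg QC limits.
#' @param subject_id Identifier carried into the decision.
#' @return List with `subject_id`, `max_translation`, `max_rotation` (deg) and
#'   logical `included`.
#' @export
motion_qc <- function(motion, max_translation_mm = 3, max_rotation_deg = 3,
                      subject_id = "subj") {
  mt <- max(abs(motion$translations))
  mr <- max(abs(motion$rotations)) * 180 / pi
  list(subject_id = subject_id,
       max_translation = mt,
       max_rotation = mr,
       included = !(mt > max_translation_mm || mr > max_rotation_deg))
}

#' Regress nuisance covariates out of outcome values
#'
#' Least-squares residualisation of a vector or matrix of outcomes (rows =
#' observations: subjects, or windows within a subject) on a regressor table.
#' An intercept is always included; the grand mean can be restored.
#'
#' @param y Numeric vector or matrix of outcomes.
#' @param X Regressor matrix or data.frame (rows aligned with `y`).
#' @param keep_intercept Restore each column's mean to the residuals
#'   (default `TRUE`).
#' @return Residualised outcomes, same shape as `y`.
#' @export
regress_nuisance <- function(y, X, keep_intercept = TRUE) {
  y_mat <- as.matrix(y)
  M <- model.matrix(~ ., data = as.data.frame(X))
  if (nrow(M) != nrow(y_mat)) {
    stop_validation("y (%d rows) and X (%d rows) are not aligned",
                    nrow(y_mat), nrow(M))
  }
  q <- qr(M)
  if (q$rank < ncol(M)) {
    bad <- colnames(M)[q$pivot[(q$rank + 1):ncol(M)]]
    stop_validation("regressor matrix is rank deficient; collinear columns: %s",
                    paste(bad, collapse = ", "))
  }
  res <- qr.resid(q, y_mat)
  if (keep_intercept) res <- sweep(res, 2, colMeans(y_mat), `+`)
  if (is.null(dim(y))) res <- drop(res)
  res
}

#' Read / write motion traces as 6-column whitespace-delimited text
#'
#' Columns: three translations (mm) then three rotations (radians), one row
#' per volume.
#'
#' @param motion A `motion_trace`.
#' @param path File path.
#' @return `write_motion` returns `path` invisibly; `read_motion` the
#'   `motion_trace` with FD recomputed.
#' @export
write_motion <- function(motion, path) {
  m <- cbind(motion$translations, motion$rotations)
  write.table(m, path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6) stop_validation("expected 6 columns, got %d", ncol(m))
  compute_fd(structure(list(translations = m[, 1:3], rotations = m[, 4:6]),
                       class = "motion_trace"))
}

#' Standard conditioning chain for one subject
#'
#' truncate -> despike -> detrend -> low-pass, the canonical order assumed by
#' the connectivity stages (which check provenance).
#'
#' @param ts A [tc_matrix()].
#' @param n_discard Leading volumes to drop.
#' @param z_threshold Despike threshold.
#' @param detrend_order Polynomial detrend order.
#' @param order,cutoff_hz Butterworth settings.
#' @return Conditioned `tc_matrix`.
#' @export
preprocess_timecourse <- function(ts, n_discard = 10, z_threshold = 4,
                                  detrend_order = 3, order = 5,
                                  cutoff_hz = 0.15) {
  ts <- truncate_initial(ts, n_discard)
  ts <- despike(ts, z_threshold)
  ts <- detrend_poly(ts, detrend_order)
  butterworth_lowpass(ts, order = order, cutoff_hz = cutoff_hz)
}
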