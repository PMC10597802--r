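# Methods for the fitted connectivity-state model.

#' @export
print.dfnc_states <- function(x, ...) {
  cat(sprintf("Connectivity-state model: k = %d states, %d windows\n",
              x$k, sum(x$frequency)))
  cat(sprintf("pooled occupancy: %s\n",
              paste(sprintf("State %d: %.1f%%", seq_len(x$k),
                            100 * x$proportions), collapse = ", ")))
  cat(sprintf("total within-cluster L1 distance: %.2f (%d iterations)\n",
              x$objective, x$iterations))
  invisible(x)
}

#' @export
summary.dfnc_states <- function(object, spec = window_spec(), ...) {
  tp <- if (is.list(object$assignments)) {
    temporal_properties(object$assignments, spec = spec, k = object$k)
  } else {
    temporal_properties(list(object$assignments), spec = spec, k = object$k)
  }
  out <- list(k = object$k,
              occupancy = object$proportions,
              objective = object$objective,
              n_subjects = if (is.list(object$assignments))
                length(object$assignments) else 1L,
              temporal = tp)
  class(out) <- "summary.dfnc_states"
  out
}

#' @export
print.summary.dfnc_states <- function(x, ...) {
  cat(sprintf("Connectivity-state model, k = %d, %d subject(s)\n",
              x$k, x$n_subjects))
  cat("pooled occupancy:\n")
  print(round(x$occupancy, 3))
  cat("\nper-state mean temporal properties:\n")
  agg <- aggregate(cbind(fraction_time, mean_dwell_s) ~ state,
                   data = x$temporal, FUN = mean)
  print(round(agg, 3))
  invisible(x)
}

#' Assign new windows to fitted states
#'
#' @param object A `dfnc_states`.
#' @param newdata A `windowed_series`, a list of them, or a plain
#'   `samples x features` matrix of vectorised upper triangles.
#' @param ... Unused.
#' @return Integer state assignments (list per subject for list input).
#' @export
predict.dfnc_states <- function(object, newdata, ...) {
  assign_one <- function(samples) {
    D <- l1_cross_dist_cpp(samples, object$centroid_vecs)
    apply(D, 1, which.min)
  }
  if (inherits(newdata, "windowed_series")) newdata <- list(newdata)
  if (is.list(newdata) && !is.matrix(newdata)) {
    pooled <- pool_windows(newdata)
    split(assign_one(pooled$samples), pooled$subject)
  } else {
    assign_one(as.matrix(newdata))
  }
}

#' Plot state centroid connectivity matrices
#'
#' One image panel per state centroid (Fisher-z partial correlations), shared
#' symmetric colour scale.
#'
#' @param x A `dfnc_states` fitted from windowed series (centroids known).
#' @param ... Unused.
#' @export
plot.dfnc_states <- function(x, ...) {
  if (is.null(x$centroids)) {
    stop_validation("no centroid matrices: fit on windowed series or pass C")
  }
  k <- x$k
  old <- par(mfrow = c(1, k), mar = c(2, 2, 3, 1))
  on.exit(par(old))
  lim <- max(abs(unlist(x$centroids)))
  cols <- hcl.colors(64, "Blue-Red 3")
  for (s in seq_len(k)) {
    M <- x$centroids[[s]]
    image(t(M[nrow(M):1, ]), zlim = c(-lim, lim), col = cols, axes = FALSE,
          main = sprintf("State %d (%.0f%%)", s, 100 * x$proportions[s]))
  }
  invisible(x)
}
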