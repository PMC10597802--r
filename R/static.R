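# Static analysis: voxel-wise one-sample t maps for component spatial maps,
# and inter-network static functional network connectivity (Fisher-z Pearson).

#' Voxel-wise one-sample t statistics for a component spatial map
#'
#' One-sample t test per voxel over subjects, BH-FDR correction across voxels,
#' and a high-activation mask: FDR-significant voxels whose t exceeds
#' `mean(t) + 4 * SD(t)` over voxels (the positive tail; the symmetric
#' negative-tail mask is reported alongside). Voxels with zero between-subject
#' variance are excluded and reported rather than propagated as NaN.
#'
#' @param subject_maps `subjects x voxels` matrix for one component.
#' @param fdr_q FDR level (default 0.05).
#' @return List of class `spatial_map_stats`: `tmap`, `pmap`, `qmap`,
#'   `mask` (positive-tail high-activation mask within FDR-significant
#'   voxels), `mask_low` (negative tail), `excluded` (zero-variance voxel
#'   indices), `threshold_rule` (the mean/SD/threshold actually applied).
#' @export
spatial_tmap <- function(subject_maps, fdr_q = 0.05) {
  X <- as.matrix(subject_maps)
  n <- nrow(X)
  if (n < 3) stop_validation("at least 3 subjects required, got %d", n)
  m <- colMeans(X)
  s <- apply(X, 2, sd)
  ok <- s > .Machine$double.eps
  tmap <- rep(NA_real_, ncol(X))
  tmap[ok] <- m[ok] / (s[ok] / sqrt(n))
  pmap <- rep(NA_real_, ncol(X))
  pmap[ok] <- 2 * pt(-abs(tmap[ok]), df = n - 1)
  qmap <- rep(NA_real_, ncol(X))
  qmap[ok] <- p.adjust(pmap[ok], method = "BH")
  t_ok <- tmap[ok]
  thr_hi <- mean(t_ok) + 4 * sd(t_ok)
  thr_lo <- mean(t_ok) - 4 * sd(t_ok)
  sig <- !is.na(qmap) & qmap < fdr_q
  structure(list(
    tmap = tmap, pmap = pmap, qmap = qmap,
    mask = sig & !is.na(tmap) & tmap > thr_hi,
    mask_low = sig & !is.na(tmap) & tmap < thr_lo,
    excluded = which(!ok),
    threshold_rule = list(rule = "mean +/- 4SD of voxelwise t",
                          mean_t = mean(t_ok), sd_t = sd(t_ok),
                          threshold_high = thr_hi, threshold_low = thr_lo,
                          fdr_q = fdr_q)
  ), class = "spatial_map_stats")
}

#' Cluster-extent filter on a voxel mask
#'
#' Removes connected components smaller than `min_size` from a logical mask
#' laid out on a 3D grid (6-neighbourhood connectivity). With `dims = NULL`
#' the mask is treated as 1D (runs of TRUE).
#'
#' @param mask Logical vector.
#' @param dims Optional integer 3-vector of grid dimensions.
#' @param min_size Minimum cluster size in voxels (default 10, i.e. clusters
#'   of volume > 10 survive only if `> min_size` is requested via
#'   `strict = TRUE`; by default `>= min_size` voxels are kept).
#' @param strict Keep clusters strictly larger than `min_size`.
#' @return Filtered logical mask.
#' @export
cluster_filter <- function(mask, dims = NULL, min_size = 10, strict = FALSE) {
  if (is.null(dims)) {
    r <- rle(mask)
    keep <- r$values & (if (strict) r$lengths > min_size
                        else r$lengths >= min_size)
    r$values <- keep
    return(inverse.rle(r))
  }
  stopifnot(length(mask) == prod(dims))
  arr <- array(mask, dim = dims)
  lab <- array(0L, dim = dims)
  cur <- 0L
  idx <- which(arr)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      co <- arrayInd(v, dims)
      for (d in 1:3) {
        for (step in c(-1L, 1L)) {
          nb <- co
          nb[d] <- nb[d] + step
          if (nb[d] < 1 || nb[d] > dims[d]) next
          li <- nb[1] + (nb[2] - 1) * dims[1] + (nb[3] - 1) * dims[1] * dims[2]
          if (arr[li] && lab[li] == 0L) {
            lab[li] <- cur
            queue <- c(queue, li)
          }
        }
      }
    }
  }
  sizes <- tabulate(lab[lab > 0L])
  keep_ids <- which(if (strict) sizes > min_size else sizes >= min_size)
  as.vector(lab %in% keep_ids)
}

#' Static functional network connectivity matrix
#'
#' Pairwise Pearson correlations between conditioned component time courses,
#' Fisher z-transformed with clipping, diagonal zeroed. By default the
#' provenance is checked for despiking and low-pass filtering, the two
#' conditioning steps connectivity estimation assumes.
#'
#' @param ts A conditioned [tc_matrix()].
#' @param check_provenance Require `despike` and `lowpass` in provenance.
#' @return List of class `fnc_matrix`: `z` (`C x C` symmetric Fisher-z,
#'   zero diagonal), `c_labels`, `condition` (`"static"`).
#' @export
sfnc <- function(ts, check_provenance = TRUE) {
  if (check_provenance) {
    prov <- tc_provenance(ts)
    if (!any(grepl("^despike", prov)) || !any(grepl("^lowpass", prov))) {
      stop_validation(paste0("time courses must be despiked and low-pass ",
                             "filtered before sFNC (provenance: %s)"),
                      paste(prov, collapse = " -> "))
    }
  }
  X <- unclass(ts)
  C <- ncol(X)
  s <- apply(X, 2, sd)
  dead <- s <= .Machine$double.eps
  z <- matrix(0, C, C)
  if (any(dead)) {
    warning(sprintf("zero-variance component(s) %s: connectivity set to 0",
                    paste(which(dead), collapse = ", ")))
  }
  live <- which(!dead)
  if (length(live) >= 2) {
    r <- cor(X[, live, drop = FALSE])
    zl <- fisher_z(r)
    diag(zl) <- 0
    z[live, live] <- zl
  }
  labels <- colnames(X) %||% paste0("IC", seq_len(C))
  structure(list(z = z, c_labels = labels, condition = "static",
                 subject_id = attr(ts, "subject_id")),
            class = "fnc_matrix")
}

#' Export a connectivity matrix
#'
#' Square CSV with component labels, or long-form TSV
#' (`component_i`, `component_j`, `z`).
#'
#' @param fnc An `fnc_matrix` (or plain matrix).
#' @param path Output path.
#' @param format `"csv"` (square) or `"tsv"` (long form, upper triangle).
#' @return `path`, invisibly.
#' @export
write_fnc <- function(fnc, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  z <- if (inherits(fnc, "fnc_matrix")) fnc$z else as.matrix(fnc)
  labels <- if (inherits(fnc, "fnc_matrix")) fnc$c_labels
            else colnames(z) %||% paste0("IC", seq_len(ncol(z)))
  dimnames(z) <- list(labels, labels)
  if (format == "csv") {
    write.table(z, path, sep = ",", quote = FALSE, col.names = NA)
  } else {
    ut <- which(upper.tri(z), arr.ind = TRUE)
    long <- data.frame(component_i = labels[ut[, 1]],
                       component_j = labels[ut[, 2]],
                       z = z[ut])
    write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
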