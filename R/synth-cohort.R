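# Synthetic cohort generation: a four-group (patient/control x female/male)
# multi-site cohort with clinical and structural covariates drawn from
# published-style summary statistics.

GROUPS <- c("RRMS-F", "RRMS-M", "HC-F", "HC-M")
PATIENT_GROUPS <- c("RRMS-F", "RRMS-M")

#' Specification of a synthetic cohort
#'
#' Defines group sizes, site structure and the per-group distributions of the
#' clinical/structural covariates. Normally distributed covariates (age, mean
#' framewise displacement, grey-matter volume, white-matter volume, brain
#' parenchymal fraction) are parameterised as mean/SD per group; right-skewed
#' patient-only covariates (lesion volume, disease duration, EDSS) as
#' median/IQR and generated log-normally by moment matching on the log scale.
#' The defaults reproduce the demographic table of a multicenter
#' relapsing-remitting multiple sclerosis cohort (135/73 female/male patients,
#' 123/105 female/male controls over six sites).
#'
#' @param n Named integer vector of group sizes for
#'   `RRMS-F`, `RRMS-M`, `HC-F`, `HC-M`.
#' @param n_sites Number of acquisition sites (subjects assigned uniformly).
#' @param bpf_truncate Logical; brain parenchymal fraction draws outside
#'   `(0, 1]` are resampled when `TRUE`. When `FALSE` such a draw is a
#'   configuration error — truncation must be requested explicitly.
#' @param age,mean_fd,gmv,wmv,bpf 4 x 2 matrices (rows = groups) of
#'   mean and SD.
#' @param lv,dd,edss 2 x 3 matrices (rows = patient groups) of
#'   median, lower quartile, upper quartile.
#' @return A list of class `cohort_spec`.
#' @seealso [make_cohort()]
#' @export
cohort_spec <- function(n = c("RRMS-F" = 135L, "RRMS-M" = 73L,
                              "HC-F" = 123L, "HC-M" = 105L),
                        n_sites = 6L,
                        bpf_truncate = TRUE,
                        age = rbind("RRMS-F" = c(37.55, 11.47),
                                    "RRMS-M" = c(35.42, 10.98),
                                    "HC-F"   = c(36.94, 12.17),
                                    "HC-M"   = c(38.17, 10.87)),
                        mean_fd = rbind("RRMS-F" = c(0.068, 0.107),
                                        "RRMS-M" = c(0.078, 0.117),
                                        "HC-F"   = c(0.069, 0.105),
                                        "HC-M"   = c(0.075, 0.119)),
                        gmv = rbind("RRMS-F" = c(604.20, 58.58),
                                    "RRMS-M" = c(656.31, 61.14),
                                    "HC-F"   = c(653.84, 57.84),
                                    "HC-M"   = c(687.42, 64.19)),
                        wmv = rbind("RRMS-F" = c(453.51, 56.39),
                                    "RRMS-M" = c(512.96, 72.18),
                                    "HC-F"   = c(498.03, 51.67),
                                    "HC-M"   = c(549.67, 51.93)),
                        bpf = rbind("RRMS-F" = c(0.76, 0.05),
                                    "RRMS-M" = c(0.75, 0.04),
                                    "HC-F"   = c(0.80, 0.03),
                                    "HC-M"   = c(0.79, 0.03)),
                        lv = rbind("RRMS-F" = c(5.94, 1.43, 16.70),
                                   "RRMS-M" = c(8.16, 3.36, 19.70)),
                        dd = rbind("RRMS-F" = c(17, 5, 48),
                                   "RRMS-M" = c(24, 5, 72)),
                        edss = rbind("RRMS-F" = c(2, 1, 3.5),
                                     "RRMS-M" = c(2.5, 1.5, 3.5))) {
  spec <- list(n = n, n_sites = as.integer(n_sites),
               bpf_truncate = isTRUE(bpf_truncate),
               age = age, mean_fd = mean_fd, gmv = gmv, wmv = wmv, bpf = bpf,
               lv = lv, dd = dd, edss = edss)
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (length(spec$n) != 4L || is.null(names(spec$n)) ||
      !setequal(names(spec$n), GROUPS)) {
    stop_config("cohort spec requires named sizes for groups %s",
                paste(GROUPS, collapse = ", "))
  }
  if (any(spec$n < 1L) || any(spec$n != round(spec$n))) {
    stop_config("all group sizes must be integers >= 1 (got %s)",
                paste(spec$n, collapse = ", "))
  }
  if (spec$n_sites < 1L) stop_config("n_sites must be >= 1")
  for (v in c("age", "mean_fd", "gmv", "wmv", "bpf")) {
    p <- spec[[v]]
    if (!all(is.finite(p))) stop_config("non-finite parameters for '%s'", v)
    if (any(p[, 2] <= 0)) stop_config("SDs for '%s' must be > 0", v)
  }
  for (v in c("lv", "dd", "edss")) {
    p <- spec[[v]]
    if (!all(is.finite(p)) || any(p <= 0)) {
      stop_config("median/IQR parameters for '%s' must be finite and > 0", v)
    }
    if (any(p[, 2] > p[, 1]) || any(p[, 3] < p[, 1])) {
      stop_config("'%s' quartiles must bracket the median", v)
    }
  }
  if (any(spec$bpf[, 1] <= 0) || any(spec$bpf[, 1] > 1)) {
    stop_config("BPF means must lie in (0, 1]")
  }
  invisible(spec)
}

# Log-normal draw matched to median and quartiles on the log scale.
rlnorm_median_iqr <- function(n, med, q1, q3) {
  mu <- log(med)
  sigma <- (log(q3) - log(q1)) / (2 * qnorm(0.75))
  rlnorm(n, meanlog = mu, sdlog = sigma)
}

#' Generate a synthetic cohort table
#'
#' Draws one row per subject: group, site, age, mean framewise displacement,
#' grey/white-matter volume, brain parenchymal fraction, and (patients only)
#' lesion volume, disease duration and EDSS score. Deterministic under a fixed
#' seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (optional).
#' @return A `data.frame` with one row per subject. Patient-only covariates are
#'   `NA` for healthy controls. EDSS is rounded to the ordinal 0.5-step scale.
#' @examples
#' coh <- make_cohort(cohort_spec(n = c("RRMS-F" = 5, "RRMS-M" = 5,
#'                                      "HC-F" = 5, "HC-M" = 5)), seed = 1)
#' table(coh$group)
#' @export
make_cohort <- function(spec = cohort_spec(), seed = NULL) {
  validate_cohort_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n[GROUPS]
  total <- sum(n)
  group <- factor(rep(GROUPS, times = n), levels = GROUPS)
  out <- data.frame(
    subject_id = sprintf("S%04d", seq_len(total)),
    group = group,
    site = factor(sample.int(spec$n_sites, total, replace = TRUE),
                  levels = seq_len(spec$n_sites)),
    stringsAsFactors = FALSE
  )
  draw_norm <- function(par, lower = -Inf) {
    x <- numeric(total)
    for (g in GROUPS) {
      i <- group == g
      x[i] <- rnorm(sum(i), par[g, 1], par[g, 2])
    }
    if (is.finite(lower)) x <- pmax(x, lower)
    x
  }
  out$age <- draw_norm(spec$age)
  out$mean_fd <- draw_norm(spec$mean_fd, lower = 0)
  out$gmv <- draw_norm(spec$gmv)
  out$wmv <- draw_norm(spec$wmv)

  bpf <- numeric(total)
  for (g in GROUPS) {
    i <- which(group == g)
    x <- rnorm(length(i), spec$bpf[g, 1], spec$bpf[g, 2])
    bad <- x <= 0 | x > 1
    if (any(bad)) {
      if (!spec$bpf_truncate) {
        stop_config(paste0("BPF parameters for group %s produced values ",
                           "outside (0, 1]; set bpf_truncate = TRUE to ",
                           "resample explicitly"), g)
      }
      while (any(bad)) {
        x[bad] <- rnorm(sum(bad), spec$bpf[g, 1], spec$bpf[g, 2])
        bad <- x <= 0 | x > 1
      }
    }
    bpf[i] <- x
  }
  out$bpf <- bpf

  out$lv <- out$dd <- out$edss <- NA_real_
  for (g in PATIENT_GROUPS) {
    i <- which(group == g)
    out$lv[i] <- rlnorm_median_iqr(length(i), spec$lv[g, 1], spec$lv[g, 2],
                                   spec$lv[g, 3])
    out$dd[i] <- rlnorm_median_iqr(length(i), spec$dd[g, 1], spec$dd[g, 2],
                                   spec$dd[g, 3])
    edss <- rlnorm_median_iqr(length(i), spec$edss[g, 1], spec$edss[g, 2],
                              spec$edss[g, 3])
    out$edss[i] <- pmin(10, pmax(0, round(edss * 2) / 2))
  }
  out
}

#' Write / read a cohort table as TSV
#'
#' @param cohort Cohort `data.frame` from [make_cohort()].
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the
#'   reconstructed data.frame with factor columns restored.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  x$group <- factor(x$group, levels = GROUPS)
  x$site <- factor(x$site)
  x
}
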