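# Configuration, orchestration, manifest/serialization and reporting: ties
# the stages into the static and dynamic analyses plus the sensitivity
# re-runs (window width x state count).

#' Pipeline run configuration
#'
#' Collects every tunable of the full analysis. Derived quantities
#' (window/step/taper durations in seconds) are always recomputed from the
#' primitives at validation time, never stored independently.
#'
#' @param seed Master seed; fans out deterministically to per-stage child
#'   seeds.
#' @param n Named group sizes for the synthetic cohort.
#' @param T Volumes per subject (before truncation).
#' @param C Number of components.
#' @param tr Repetition time, seconds.
#' @param n_discard Leading volumes discarded.
#' @param despike_z Despike threshold.
#' @param detrend_order Polynomial detrend order.
#' @param filter_order,cutoff_hz Butterworth low-pass settings.
#' @param width_tr,step_tr,taper_sigma_tr Sliding-window settings.
#' @param k States: a single value, or candidates for elbow selection.
#' @param use_elbow Select k by the elbow criterion over `k` candidates.
#' @param lambda_grid Graphical-lasso penalty grid.
#' @param cv_repeats Penalty-selection repetitions (default 10).
#' @param kmeans_replicates,kmeans_max_iter Clustering restarts/iterations.
#' @param fdr_alpha FDR-corrected significance level (default 0.05).
#' @param mwu_alpha Mann-Whitney threshold for temporal features
#'   (default 0.01).
#' @param nuisance_level Motion nuisance regression mode: `"subject"`
#'   (per-subject summaries across subjects), `"window"` (per-window means
#'   within subject) or `"none"`.
#' @param use_groupica Run the voxel-level group-ICA front end (requires
#'   mixing maps in the truth); otherwise component time courses are taken
#'   directly from the generator.
#' @param truth A [synth_truth()] ground-truth regime.
#' @param cohort A [cohort_spec()].
#' @param sensitivity_widths,sensitivity_k Sensitivity grid (defaults
#'   `c(22, 30)` TR widths and `k in {3, 4}`).
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return List of class `run_config`, validated.
#' @export
run_config <- function(seed = 1,
                       n = c("RRMS-F" = 12L, "RRMS-M" = 12L,
                             "HC-F" = 12L, "HC-M" = 12L),
                       T = 160, C = 10, tr = 2,
                       n_discard = 10, despike_z = 4, detrend_order = 3,
                       filter_order = 5, cutoff_hz = 0.15,
                       width_tr = 22, step_tr = 1, taper_sigma_tr = 3,
                       k = 3, use_elbow = FALSE,
                       lambda_grid = default_lambda_grid(),
                       cv_repeats = 10,
                       kmeans_replicates = 5, kmeans_max_iter = 150,
                       fdr_alpha = 0.05, mwu_alpha = 0.01,
                       nuisance_level = c("subject", "window", "none"),
                       use_groupica = FALSE,
                       truth = synth_truth(C = C),
                       cohort = NULL,
                       sensitivity_widths = c(22, 30),
                       sensitivity_k = c(3, 4),
                       out_dir = NULL) {
  cfg <- list(seed = seed, n = n, T = T, C = C, tr = tr,
              n_discard = n_discard, despike_z = despike_z,
              detrend_order = detrend_order, filter_order = filter_order,
              cutoff_hz = cutoff_hz, width_tr = width_tr, step_tr = step_tr,
              taper_sigma_tr = taper_sigma_tr, k = k, use_elbow = use_elbow,
              lambda_grid = lambda_grid, cv_repeats = cv_repeats,
              kmeans_replicates = kmeans_replicates,
              kmeans_max_iter = kmeans_max_iter,
              fdr_alpha = fdr_alpha, mwu_alpha = mwu_alpha,
              nuisance_level = match.arg(nuisance_level),
              use_groupica = use_groupica, truth = truth,
              cohort = cohort %||% cohort_spec(n = n),
              sensitivity_widths = sensitivity_widths,
              sensitivity_k = sensitivity_k,
              out_dir = out_dir)
  class(cfg) <- "run_config"
  validate_config(cfg)$config
}

#' Validate a run configuration
#'
#' Rejects inconsistent entries (cutoff at or above Nyquist, window longer
#' than the post-truncation series, empty penalty grid) and reports the
#' derived quantities recomputed from the primitives.
#'
#' @param config A `run_config`.
#' @return List: `config` (validated) and `derived` (width/step/taper
#'   durations in seconds, windows per subject, Nyquist frequency).
#' @export
validate_config <- function(config) {
  cfg <- config
  nyquist <- 1 / (2 * cfg$tr)
  if (cfg$cutoff_hz >= nyquist) {
    stop_config("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                cfg$cutoff_hz, nyquist)
  }
  T_eff <- cfg$T - cfg$n_discard
  if (cfg$width_tr > T_eff) {
    stop_config("window width %d TR exceeds post-truncation length %d",
                cfg$width_tr, T_eff)
  }
  if (length(cfg$lambda_grid) == 0) stop_config("lambda grid is empty")
  if (any(cfg$k < 1)) stop_config("k must be >= 1")
  spec <- window_spec(cfg$width_tr, cfg$step_tr, cfg$taper_sigma_tr, cfg$tr)
  derived <- list(width_seconds = spec$width_seconds,
                  step_seconds = spec$step_seconds,
                  taper_seconds = spec$taper_seconds,
                  n_windows = floor((T_eff - cfg$width_tr) / cfg$step_tr) + 1,
                  nyquist_hz = nyquist)
  list(config = cfg, derived = derived)
}

config_hash <- function(config) {
  cfg <- config
  cfg$truth <- lapply(cfg$truth[c("C", "k", "occupancy", "stickiness",
                                  "noise_sd")], unclass)
  cfg$out_dir <- NULL
  js <- jsonlite::toJSON(cfg, digits = 10, auto_unbox = TRUE, force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(js), tmp)
  unname(tools::md5sum(tmp))
}

object_checksum <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # canonical text serialisation keeps checksums platform independent
  dput(x, file = tmp, control = c("keepNA", "keepInteger", "digits17"))
  unname(tools::md5sum(tmp))
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[dynfc] ", fmt), ...))
}

#' Run the full analysis pipeline
#'
#' Synthesis -> preprocessing/QC -> (optional group ICA) -> static FNC ->
#' dynamic FNC (windowing, glasso, clustering, temporal properties) ->
#' statistics. Writes a manifest (seed, config hash, per-stage checksums,
#' timings, record counts) and stage outputs when `out_dir` is set.
#'
#' @param config A [run_config()].
#' @param verbose Log per-stage progress to stderr.
#' @return List of class `dynfc_run` with elements `config`, `derived`,
#'   `cohort`, `qc`, `static` (per-subject z matrices and group tests),
#'   `dynamic` (`windowed`, `states`, `temporal`, `entry_pct`, `k_selected`,
#'   `validity_curve`), `stats` (temporal MWU table, dFNC/sFNC adjusted tests,
#'   ROC results, correlations), `manifest`.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  t0 <- Sys.time()
  val <- validate_config(config)
  cfg <- val$config
  manifest <- list(seed = cfg$seed, config_hash = config_hash(cfg),
                   derived = val$derived, stages = list())
  stamp <- function(name, obj, n_records) {
    manifest$stages[[name]] <<- list(
      checksum = object_checksum(obj), n_records = n_records,
      elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  }

  # --- synthesis ------------------------------------------------------------
  log_stage(verbose, "synthesis: %d subjects, T = %d, C = %d",
            sum(cfg$n), cfg$T, cfg$C)
  ds <- simulate_cohort(cfg$cohort, cfg$truth, T = cfg$T, tr = cfg$tr,
                        seed = child_seed(cfg$seed, "synth"))
  stamp("synth", ds$cohort, nrow(ds$cohort))

  # --- preprocessing and QC -------------------------------------------------
  qc <- lapply(seq_along(ds$motion), function(i) {
    motion_qc(ds$motion[[i]], subject_id = ds$cohort$subject_id[i])
  })
  included <- vapply(qc, `[[`, logical(1), "included")
  log_stage(verbose, "QC: %d/%d subjects retained", sum(included),
            length(included))
  if (sum(included) < length(included)) {
    ds$cohort <- ds$cohort[included, ]
    ds$timecourses <- ds$timecourses[included]
    ds$sequences <- ds$sequences[included]
    ds$motion <- ds$motion[included]
  }
  conditioned <- lapply(ds$timecourses, preprocess_timecourse,
                        n_discard = cfg$n_discard,
                        z_threshold = cfg$despike_z,
                        detrend_order = cfg$detrend_order,
                        order = cfg$filter_order, cutoff_hz = cfg$cutoff_hz)
  stamp("preprocess", vapply(conditioned, nrow, integer(1)),
        length(conditioned))

  # --- optional group ICA ---------------------------------------------------
  if (cfg$use_groupica) {
    if (is.null(cfg$truth$mixing_maps)) {
      stop_config("use_groupica = TRUE requires mixing maps in the truth")
    }
    log_stage(verbose, "group ICA front end")
    vox <- lapply(seq_along(conditioned), function(i) {
      t(mix_to_voxels(unclass(conditioned[[i]]), cfg$truth$mixing_maps,
                      noise_sd = cfg$truth$noise_sd,
                      seed = child_seed(cfg$seed, paste0("vox", i))))
    })
    gica <- group_ica(vox, n_group_pc = cfg$C, n_runs = 10,
                      seed = child_seed(cfg$seed, "ica"))
    conditioned <- lapply(seq_along(gica$subject_timecourses), function(i) {
      tc_matrix(gica$subject_timecourses[[i]], tr = cfg$tr,
                subject_id = ds$cohort$subject_id[i],
                provenance = c(tc_provenance(conditioned[[i]]), "groupica"))
    })
    names(conditioned) <- ds$cohort$subject_id
  }

  # --- static FNC -----------------------------------------------------------
  log_stage(verbose, "static FNC")
  sfnc_list <- lapply(conditioned, sfnc)
  s_mat <- t(vapply(sfnc_list, function(f) upper_tri_vec(f$z),
                    numeric(cfg$C * (cfg$C - 1) / 2)))
  colnames(s_mat) <- pair_labels(cfg$C)
  if (cfg$nuisance_level == "subject") {
    mot_sum <- t(vapply(ds$motion, function(m) {
      c(colMeans(abs(m$translations)), colMeans(abs(m$rotations)))
    }, numeric(6)))
    s_mat <- regress_nuisance(s_mat, as.data.frame(mot_sum))
  }
  covars <- data.frame(age = ds$cohort$age, mean_fd = ds$cohort$mean_fd,
                       site = ds$cohort$site)
  static_tests <- adjusted_group_test(s_mat, ds$cohort$group, covars,
                                      alpha = cfg$fdr_alpha)
  stamp("static", s_mat, nrow(s_mat))

  # --- dynamic FNC ----------------------------------------------------------
  log_stage(verbose, "dynamic FNC: windowing + graphical lasso")
  spec <- window_spec(cfg$width_tr, cfg$step_tr, cfg$taper_sigma_tr, cfg$tr)
  windowed <- lapply(seq_along(conditioned), function(i) {
    windowed_connectivity(conditioned[[i]], spec,
                          lambda_grid = cfg$lambda_grid,
                          cv_repeats = cfg$cv_repeats,
                          seed = child_seed(cfg$seed, paste0("cv", i)))
  })
  names(windowed) <- ds$cohort$subject_id
  if (cfg$nuisance_level == "window") {
    for (i in seq_along(windowed)) {
      z <- windowed[[i]]$z
      W <- dim(z)[1]
      mot <- ds$motion[[i]]
      par6 <- cbind(mot$translations, mot$rotations)[-seq_len(cfg$n_discard), ]
      Xw <- t(vapply(windowed[[i]]$window_starts, function(s) {
        colMeans(par6[(s + 1):(s + spec$width_tr), , drop = FALSE])
      }, numeric(6)))
      flat <- t(vapply(seq_len(W), function(w) upper_tri_vec(z[w, , ]),
                       numeric(cfg$C * (cfg$C - 1) / 2)))
      flat <- regress_nuisance(flat, as.data.frame(Xw))
      for (w in seq_len(W)) z[w, , ] <- unvec_upper_tri(flat[w, ], cfg$C)
      windowed[[i]]$z <- z
    }
  }
  log_stage(verbose, "dynamic FNC: state clustering")
  validity_curve <- NULL
  if (cfg$use_elbow) {
    el <- elbow_select(windowed, k_candidates = cfg$k,
                       n_replicates = cfg$kmeans_replicates,
                       max_iter = cfg$kmeans_max_iter,
                       seed = child_seed(cfg$seed, "elbow"))
    k_sel <- el$k_selected
    states <- el$models[[as.character(k_sel)]]
    validity_curve <- el$validity_curve
  } else {
    k_sel <- cfg$k[1]
    states <- kmeans_manhattan(windowed, k_sel,
                               n_replicates = cfg$kmeans_replicates,
                               max_iter = cfg$kmeans_max_iter,
                               seed = child_seed(cfg$seed, "kmeans"))
  }
  temporal <- temporal_properties(states$assignments, spec, k = k_sel)
  entry_pct <- state_entry_percentage(states$assignments, ds$cohort$group,
                                      k = k_sel)
  stamp("dynamic", states$centroid_vecs, sum(states$frequency))

  # --- statistics -----------------------------------------------------------
  log_stage(verbose, "statistics")
  group_of <- setNames(as.character(ds$cohort$group), ds$cohort$subject_id)
  temporal$group <- group_of[temporal$subject]
  mwu_rows <- list()
  for (ct in default_contrasts()) {
    for (s in seq_len(k_sel)) {
      for (feat in c("fraction_time", "mean_dwell_s")) {
        v1 <- temporal[temporal$group == ct[1] & temporal$state == s, feat]
        v2 <- temporal[temporal$group == ct[2] & temporal$state == s, feat]
        mw <- mann_whitney(v1, v2)
        mwu_rows[[length(mwu_rows) + 1]] <- data.frame(
          feature = feat, state = s, contrast = paste(ct, collapse = " vs "),
          median_1 = median(v1), median_2 = median(v2),
          U = mw$U, p = mw$p, significant = mw$p < cfg$mwu_alpha)
      }
    }
    tr1 <- unique(temporal[temporal$group == ct[1], c("subject", "n_transitions")])
    tr2 <- unique(temporal[temporal$group == ct[2], c("subject", "n_transitions")])
    mw <- mann_whitney(tr1$n_transitions, tr2$n_transitions)
    mwu_rows[[length(mwu_rows) + 1]] <- data.frame(
      feature = "n_transitions", state = NA_integer_,
      contrast = paste(ct, collapse = " vs "),
      median_1 = median(tr1$n_transitions), median_2 = median(tr2$n_transitions),
      U = mw$U, p = mw$p, significant = mw$p < cfg$mwu_alpha)
  }
  mwu_table <- do.call(rbind, mwu_rows)

  # per-state mean dFNC per subject, tested across groups
  dfnc_tests <- list()
  for (s in seq_len(k_sel)) {
    mat_s <- t(vapply(seq_along(windowed), function(i) {
      a <- states$assignments[[i]]
      z <- windowed[[i]]$z
      if (!any(a == s)) return(rep(NA_real_, cfg$C * (cfg$C - 1) / 2))
      w_idx <- which(a == s)
      colMeans(t(vapply(w_idx, function(w) upper_tri_vec(z[w, , ]),
                        numeric(cfg$C * (cfg$C - 1) / 2))))
    }, numeric(cfg$C * (cfg$C - 1) / 2)))
    colnames(mat_s) <- pair_labels(cfg$C)
    seen <- !is.na(mat_s[, 1])
    if (all(table(ds$cohort$group[seen]) >= 3)) {
      dfnc_tests[[paste0("State", s)]] <- adjusted_group_test(
        mat_s[seen, , drop = FALSE], ds$cohort$group[seen],
        covars[seen, , drop = FALSE], alpha = cfg$fdr_alpha)
    }
  }

  # ROC: State-1 temporal features, female patient vs female control
  roc_results <- list()
  for (feat in c("fraction_time", "mean_dwell_s")) {
    sub <- temporal[temporal$state == 1 &
                      temporal$group %in% c("RRMS-F", "HC-F"), ]
    if (length(unique(sub$group)) == 2) {
      roc_results[[feat]] <- roc_auc(sub[[feat]],
                                     factor(sub$group,
                                            levels = c("HC-F", "RRMS-F")),
                                     positive = "RRMS-F", ci_bootstrap = 500,
                                     seed = child_seed(cfg$seed, "roc"))
    }
  }

  # structural associations in patients: State-1 temporal metrics vs GMV
  corr_rows <- list()
  pat <- ds$cohort$group %in% PATIENT_GROUPS
  t1 <- temporal[temporal$state == 1, ]
  t1 <- t1[match(ds$cohort$subject_id, t1$subject), ]
  ctrl <- data.frame(age = ds$cohort$age, mean_fd = ds$cohort$mean_fd,
                     site = ds$cohort$site)[pat, ]
  ctrl$site <- droplevels(ctrl$site)
  # keep enough residual degrees of freedom for the partial correlation:
  # drop site dummies first, then all controls, on very small cohorts
  if (nlevels(ctrl$site) < 2 || sum(pat) < nlevels(ctrl$site) + 7) {
    ctrl$site <- NULL
  }
  if (sum(pat) < ncol(ctrl) + 5) ctrl <- NULL
  for (feat in c("fraction_time", "mean_dwell_s")) {
    ar <- tryCatch(
      partial_spearman(t1[[feat]][pat], ds$cohort$gmv[pat], ctrl),
      error = function(e) list(rho = NA_real_, p = NA_real_))
    corr_rows[[length(corr_rows) + 1]] <- data.frame(
      x = feat, y = "gmv", rho = ar$rho, p = ar$p)
  }
  correlations <- do.call(rbind, corr_rows)
  stamp("stats", mwu_table, nrow(mwu_table))

  bundle <- structure(list(
    config = cfg, derived = val$derived,
    cohort = ds$cohort, truth = ds$truth, sequences = ds$sequences,
    qc = qc,
    static = list(z = s_mat, tests = static_tests),
    dynamic = list(windowed = windowed, states = states,
                   temporal = temporal, entry_pct = entry_pct,
                   k_selected = k_sel, validity_curve = validity_curve),
    stats = list(temporal_mwu = mwu_table, dfnc_tests = dfnc_tests,
                 roc = roc_results, correlations = correlations),
    manifest = manifest), class = "dynfc_run")
  if (!is.null(cfg$out_dir)) export_outputs(bundle, cfg$out_dir)
  log_stage(verbose, "done in %.1f s",
            as.numeric(Sys.time() - t0, units = "secs"))
  bundle
}

pair_labels <- function(C) {
  idx <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  sprintf("IC%d-IC%d", idx[, 1], idx[, 2])
}

#' @export
print.dynfc_run <- function(x, ...) {
  cat(sprintf("dynfc pipeline run (seed %d): %d subjects, k = %d states\n",
              x$config$seed, nrow(x$cohort), x$dynamic$k_selected))
  cat(sprintf("pooled state occupancy: %s\n",
              paste(sprintf("%.0f%%", 100 * x$dynamic$states$proportions),
                    collapse = " / ")))
  n_sig_static <- sum(x$static$tests$significant)
  cat(sprintf("significant static FNC pairs (FDR %.2f): %d\n",
              x$config$fdr_alpha, n_sig_static))
  n_sig_mwu <- sum(x$stats$temporal_mwu$significant)
  cat(sprintf("significant temporal-property comparisons (P<%.2g): %d\n",
              x$config$mwu_alpha, n_sig_mwu))
  invisible(x)
}

export_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(bundle$cohort, file.path(out_dir, "cohort.tsv"))
  write_stats(bundle$static$tests, file.path(out_dir, "static_tests.tsv"))
  write_stats(bundle$stats$temporal_mwu,
              file.path(out_dir, "temporal_mwu.tsv"))
  write_assignments(bundle$dynamic$states, bundle$dynamic$windowed,
                    file.path(out_dir, "assignments.tsv"))
  tp <- bundle$dynamic$temporal
  write.table(tp, file.path(out_dir, "temporal_properties.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (s in seq_len(bundle$dynamic$k_selected)) {
    write_fnc(bundle$dynamic$states$centroids[[s]],
              file.path(out_dir, sprintf("centroid_state%d.csv", s)))
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(out_dir)
}

#' Human-readable summary report of a pipeline run
#'
#' Four tables mirroring the standard reporting shapes: a cohort summary
#' (mean (SD) / median (IQR) per group and variable), the per-contrast
#' significant FNC differences, the temporal-property comparison, and the ROC
#' summary.
#'
#' @param bundle A `dynfc_run`.
#' @return List of class `dynfc_report` with `cohort_summary`,
#'   `fnc_differences`, `temporal_comparison`, `roc_summary` and `text`
#'   (rendered lines, byte-stable for identical bundles).
#' @export
export_report <- function(bundle) {
  required <- c("cohort", "static", "dynamic", "stats")
  missing <- required[!required %in% names(bundle)]
  if (length(missing)) {
    stop_validation("incomplete bundle: missing stage(s) %s",
                    paste(missing, collapse = ", "))
  }
  coh <- bundle$cohort
  norm_vars <- c("age", "mean_fd", "gmv", "wmv", "bpf")
  skew_vars <- c("dd", "edss", "lv")
  rows <- list()
  for (v in norm_vars) {
    m <- tapply(coh[[v]], coh$group, mean)
    s <- tapply(coh[[v]], coh$group, sd)
    rows[[v]] <- data.frame(variable = v, t(sprintf("%.2f (%.2f)", m, s)))
  }
  for (v in skew_vars) {
    cells <- vapply(levels(coh$group), function(g) {
      x <- coh[[v]][coh$group == g]
      if (all(is.na(x))) return("-")
      sprintf("%.2f (%.2f-%.2f)", median(x, na.rm = TRUE),
              quantile(x, 0.25, na.rm = TRUE), quantile(x, 0.75, na.rm = TRUE))
    }, character(1))
    rows[[v]] <- data.frame(variable = v, t(unname(cells)))
  }
  cohort_summary <- do.call(rbind, rows)
  names(cohort_summary) <- c("variable", levels(coh$group))
  rownames(cohort_summary) <- NULL

  sig_static <- bundle$static$tests[bundle$static$tests$significant, ,
                                    drop = FALSE]
  fnc_differences <- sig_static[, c("outcome", "contrast", "estimate",
                                    "statistic", "p", "q")]
  temporal_comparison <- bundle$stats$temporal_mwu
  roc_summary <- if (length(bundle$stats$roc)) {
    data.frame(feature = names(bundle$stats$roc),
               auc = vapply(bundle$stats$roc, `[[`, numeric(1), "auc"),
               row.names = NULL)
  } else data.frame(feature = character(), auc = numeric())

  fmt_tab <- function(df) {
    c(paste(names(df), collapse = "\t"),
      apply(df, 1, function(r) paste(format(r, trim = TRUE, digits = 6),
                                     collapse = "\t")))
  }
  text <- c("== Cohort summary ==", fmt_tab(cohort_summary), "",
            "== Significant FNC differences ==",
            if (nrow(fnc_differences)) fmt_tab(fnc_differences) else "(none)",
            "", "== Temporal properties ==", fmt_tab(temporal_comparison),
            "", "== ROC summary ==",
            if (nrow(roc_summary)) fmt_tab(roc_summary) else "(none)")
  structure(list(cohort_summary = cohort_summary,
                 fnc_differences = fnc_differences,
                 temporal_comparison = temporal_comparison,
                 roc_summary = roc_summary,
                 text = unname(text)),
            class = "dynfc_report")
}

#' @export
print.dynfc_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' Sensitivity re-runs over window width and state count
#'
#' Re-executes the pipeline over the 2 x 2 grid of window widths and state
#' counts and cross-tabulates the sign and significance of the key planted
#' group differences, to check that conclusions do not hinge on the window or
#' model-order choice.
#'
#' @param config A [run_config()]; its `sensitivity_widths` and
#'   `sensitivity_k` define the grid.
#' @param verbose Log progress.
#' @return data.frame: one row per variant with the State-1 fraction-time
#'   difference (female patient contrast), its MWU p, and the most significant
#'   static pair of the male contrast.
#' @export
run_sensitivity <- function(config = run_config(), verbose = TRUE) {
  rows <- list()
  for (w in config$sensitivity_widths) {
    for (k in config$sensitivity_k) {
      cfg <- config
      cfg$width_tr <- w
      cfg$k <- k
      cfg$use_elbow <- FALSE
      res <- run_pipeline(cfg, verbose = verbose)
      mwu <- res$stats$temporal_mwu
      row <- mwu[mwu$feature == "fraction_time" & mwu$state == 1 &
                   mwu$contrast == "RRMS-F vs HC-F", ]
      rows[[sprintf("w%d_k%d", w, k)]] <- data.frame(
        width_tr = w, k = k,
        frac_diff = row$median_1 - row$median_2,
        frac_p = row$p,
        n_sig_static_male = sum(
          res$static$tests$significant &
            res$static$tests$contrast == "RRMS-M vs HC-M"))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
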