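# Group-difference, discrimination and association statistics with covariate
# adjustment and multiplicity control.

# The four group contrasts evaluated throughout.
default_contrasts <- function() {
  list(c("HC-F", "HC-M"),
       c("RRMS-F", "HC-F"),
       c("RRMS-M", "HC-M"),
       c("RRMS-F", "RRMS-M"))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wraps `stats::p.adjust(method = "BH")` after range
#' validation).
#'
#' @param pvals p-values in `[0, 1]`.
#' @return Adjusted q-values, monotone in p-rank.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples: U statistic with midrank tie handling,
#' exact two-sided p by enumeration when both samples have at most
#' `exact_max` observations and no ties, otherwise the tie-corrected normal
#' approximation (via `stats::wilcox.test`).
#'
#' @param x,y Numeric samples (nonempty).
#' @param exact_max Largest per-sample size for exact enumeration (default 8).
#' @return List: `U`, `p`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0) {
    stop_validation("both samples must be nonempty")
  }
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (length(unique(c(x, y))) == 1) {
    return(list(U = U, p = 1, method = "degenerate (all values identical)"))
  }
  exact <- !ties && n1 <= exact_max && n2 <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  list(U = U, p = wt$p.value,
       method = if (exact) "exact enumeration"
                else "normal approximation with tie correction")
}

#' ROC curve and AUC by the rank formula
#'
#' AUC computed as `U / (n1 * n2)` from the Mann-Whitney U of the positive
#' class scores over the negative class (ties count one half). Sensitivity and
#' specificity are reported over the threshold grid of observed scores, plus a
#' percentile bootstrap confidence interval. When the raw AUC is below 0.5 an
#' oriented AUC (`1 - auc`) and direction flag are also reported.
#'
#' @param scores Numeric scores.
#' @param labels Two-class labels.
#' @param positive Label treated as positive (default: second level).
#' @param ci_bootstrap Bootstrap replicates for the percentile CI (0 skips).
#' @param seed Optional seed for the bootstrap.
#' @return List of class `roc_result`: `auc` (raw, positive-label), `auc_oriented`,
#'   `direction`, `thresholds`, `sensitivity`, `specificity`, `ci`,
#'   `positive_label`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = NULL, ci_bootstrap = 2000,
                    seed = NULL) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2) {
    stop_validation("exactly two classes required (got %d)",
                    nlevels(droplevels(labels)))
  }
  labels <- droplevels(labels)
  positive <- positive %||% levels(labels)[2]
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  if (length(pos) == 0 || length(neg) == 0) {
    stop_validation("one class is absent")
  }
  auc_of <- function(p, n) {
    r <- rank(c(p, n))
    U <- sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2
    U / (length(p) * length(n))
  }
  auc <- auc_of(pos, neg)
  thr <- sort(unique(scores))
  thresholds <- c(-Inf, thr)
  sens <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg < t), numeric(1))
  ci <- NULL
  if (ci_bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    boots <- vapply(seq_len(ci_bootstrap), function(i) {
      auc_of(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    }, numeric(1))
    ci <- unname(quantile(boots, c(0.025, 0.975)))
  }
  structure(list(auc = auc,
                 auc_oriented = max(auc, 1 - auc),
                 direction = if (auc >= 0.5) ">" else "<",
                 thresholds = thresholds,
                 sensitivity = sens, specificity = spec,
                 ci = ci, positive_label = positive,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (positive = %s, n = %d vs %d)\n",
              x$auc, x$positive_label, x$n_pos, x$n_neg))
  if (!is.null(x$ci)) {
    cat(sprintf("95%% bootstrap CI: [%.3f, %.3f]\n", x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' Spearman or partial Spearman correlation
#'
#' Both variables are rank-transformed; with controls, both rank vectors are
#' residualised on the control design (categorical controls become dummies)
#' and the Pearson correlation of the residuals is reported, with a
#' t-approximation p-value on `n - 2 - q` degrees of freedom (`q` = number of
#' control columns). With no controls this is exactly the Spearman rho.
#'
#' @param x,y Aligned numeric vectors.
#' @param controls Optional data.frame/matrix of control variables.
#' @return List of class `assoc_result`: `rho`, `p`, `n`, `df`, `controls`.
#' @export
partial_spearman <- function(x, y, controls = NULL) {
  if (length(x) != length(y)) stop_validation("x and y must be aligned")
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  q <- 0
  if (!is.null(controls)) {
    Cdf <- as.data.frame(controls)
    if (nrow(Cdf) != n) stop_validation("controls must be aligned with x, y")
    for (nm in names(Cdf)) {
      col <- Cdf[[nm]]
      if (is.numeric(col) &&
          (all(rank(col) == rx) || all(rank(col) == rank(-x)) ||
           all(rank(col) == ry) || all(rank(col) == rank(-y)))) {
        stop_validation("control '%s' is degenerate with x or y", nm)
      }
    }
    M <- model.matrix(~ ., data = Cdf)
    qr_M <- qr(M)
    if (qr_M$rank < ncol(M)) {
      stop_validation("control design is rank deficient")
    }
    q <- ncol(M) - 1
    rx_res <- qr.resid(qr_M, rx)
    ry_res <- qr.resid(qr_M, ry)
    if (sd(rx_res) < 1e-12 || sd(ry_res) < 1e-12) {
      stop_validation("a control variable is degenerate with x or y")
    }
    rho <- cor(rx_res, ry_res)
  } else {
    rho <- cor(rx, ry)
  }
  df <- n - 2 - q
  if (df < 1) stop_validation("not enough observations for the control set")
  tstat <- rho * sqrt(df / max(1 - rho^2, 1e-15))
  p <- 2 * pt(-abs(tstat), df = df)
  structure(list(rho = rho, p = p, n = n, df = df,
                 controls = if (is.null(controls)) character()
                            else colnames(as.data.frame(controls))),
            class = "assoc_result")
}

#' Covariate-adjusted group comparison with FDR control
#'
#' For each outcome column: residualise on the covariate design (site as
#' categorical dummies), run the omnibus one-way ANOVA F across the four
#' groups on the residuals, and Welch t post hoc tests for the enumerated
#' group contrasts. Benjamini-Hochberg FDR is applied across the family of
#' outcomes within each contrast.
#'
#' @param values Numeric vector (one outcome) or `subjects x outcomes` matrix.
#' @param groups Group factor aligned with rows of `values`.
#' @param covariates data.frame of covariates (e.g. age, mean FD, site,
#'   optionally GMV); may be `NULL` for an unadjusted comparison.
#' @param contrasts List of group-label pairs (default: the four standard
#'   contrasts).
#' @param alpha Significance level recorded in the metadata (default 0.05).
#' @param pooled_variance Use pooled-variance t tests instead of per-pair
#'   Welch (default `FALSE`).
#' @return A data.frame of class `group_test_result` with one row per
#'   outcome x contrast: `outcome`, `contrast`, `estimate` (difference of
#'   adjusted means, first minus second group), `statistic`, `p`, `q`,
#'   `significant`, plus omnibus columns `f_statistic` and `f_p`. Metadata
#'   (alpha, covariates used, FDR family definition) in attributes.
#' @export
adjusted_group_test <- function(values, groups, covariates = NULL,
                                contrasts = default_contrasts(),
                                alpha = 0.05, pooled_variance = FALSE) {
  y <- as.matrix(values)
  groups <- factor(groups)
  if (nrow(y) != length(groups)) {
    stop_validation("values and groups must be aligned")
  }
  if (any(table(droplevels(groups)) < 3)) {
    stop_validation("every group needs at least 3 subjects")
  }
  cov_names <- character()
  if (!is.null(covariates)) {
    Cdf <- as.data.frame(covariates)
    if (anyNA(Cdf)) {
      bad <- which(!complete.cases(Cdf))
      stop_validation("missing covariate values for rows: %s",
                      paste(bad, collapse = ", "))
    }
    cov_names <- names(Cdf)
    Cdf[] <- lapply(Cdf, function(col) {
      if (is.factor(col)) droplevels(col) else col
    })
    keep <- vapply(Cdf, function(col) length(unique(col)) > 1, logical(1))
    Cdf <- Cdf[, keep, drop = FALSE]
    if (ncol(Cdf) > 0) {
      M <- model.matrix(~ ., data = Cdf)
      qr_M <- qr(M)
      if (qr_M$rank < ncol(M)) {
        bad <- colnames(M)[qr_M$pivot[(qr_M$rank + 1):ncol(M)]]
        stop_validation("collinear covariates: %s", paste(bad, collapse = ", "))
      }
      y <- qr.resid(qr_M, y)
    }
  }
  n_out <- ncol(y)
  outcome_ids <- colnames(y) %||% paste0("outcome", seq_len(n_out))
  rows <- list()
  for (o in seq_len(n_out)) {
    yo <- y[, o]
    fit <- aov(yo ~ groups)
    an <- anova(fit)
    f_stat <- an[["F value"]][1]
    f_p <- an[["Pr(>F)"]][1]
    adj_means <- tapply(yo, groups, mean)
    for (ct in contrasts) {
      g1 <- yo[groups == ct[1]]
      g2 <- yo[groups == ct[2]]
      tt <- stats::t.test(g1, g2, var.equal = pooled_variance)
      rows[[length(rows) + 1]] <- data.frame(
        outcome = outcome_ids[o],
        contrast = paste(ct, collapse = " vs "),
        estimate = mean(g1) - mean(g2),
        statistic = unname(tt$statistic),
        p = tt$p.value,
        f_statistic = f_stat,
        f_p = f_p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  for (ctn in unique(res$contrast)) {
    i <- res$contrast == ctn
    res$q[i] <- bh_fdr(res$p[i])
  }
  res$significant <- res$q < alpha
  attr(res, "alpha") <- alpha
  attr(res, "covariates_used") <- cov_names
  attr(res, "fdr") <- sprintf(
    "Benjamini-Hochberg across %d outcomes within each contrast (P<%g)",
    n_out, alpha)
  attr(res, "adjusted_means") <- NULL
  class(res) <- c("group_test_result", "data.frame")
  res
}

#' Write tidy statistical results as TSV
#'
#' @param res A `group_test_result` (or any data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats <- function(res, path) {
  write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
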