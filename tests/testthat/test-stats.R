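# Covariate-adjusted group tests, FDR, Mann-Whitney, ROC and partial
# Spearman association.

test_that("BH adjustment equals the literal step-up definition", {
  expect_equal(bh_fdr(rep(0.001, 100)), rep(0.001, 100))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(71)
  for (i in 1:20) {
    p <- runif(sample(5:80, 1))
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-14)
  }
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))   # monotone in p-rank
  expect_error(bh_fdr(c(0.5, 1.2)), class = "dynfc_validation_error")
})

test_that("Mann-Whitney matches exact enumeration and degenerate cases", {
  # complete separation, n1 = n2 = 5: U = 25, exact two-sided p = 2/252
  mw <- mann_whitney(6:10, 1:5)
  expect_equal(mw$U, 25)
  expect_equal(mw$p, 2 / 252, tolerance = 1e-12)
  # identical samples under ties: U = n^2/2, p = 1
  mw2 <- mann_whitney(rep(1, 4), rep(1, 4))
  expect_equal(mw2$U, 8)
  expect_equal(mw2$p, 1)
  x <- c(1.2, 3.4, 2.2); y <- c(0.5, 2.9)
  expect_equal(mann_whitney(x, y)$U, sum(outer(x, y, ">")))
  expect_error(mann_whitney(numeric(), 1:3),
               class = "dynfc_validation_error")
})

test_that("AUC equals the rank identity and flips under relabelling", {
  set.seed(72)
  scores <- c(rnorm(8, 1), rnorm(10))
  labels <- rep(c("case", "ctrl"), c(8, 10))
  roc <- roc_auc(scores, labels, positive = "case", ci_bootstrap = 200,
                 seed = 1)
  expect_equal(roc$auc, brute_auc(scores[1:8], scores[9:18]),
               tolerance = 1e-12)
  flipped <- roc_auc(scores, labels, positive = "ctrl", ci_bootstrap = 0)
  expect_equal(flipped$auc, 1 - roc$auc, tolerance = 1e-12)
  # perfect separation
  expect_equal(roc_auc(c(5, 6, 7, 1, 2), c("a", "a", "a", "b", "b"),
                       positive = "a", ci_bootstrap = 0)$auc, 1)
  expect_true(!is.null(roc$ci) && roc$ci[1] <= roc$auc & roc$auc <= roc$ci[2])
  expect_error(roc_auc(1:5, rep("a", 5)), class = "dynfc_validation_error")
})

test_that("partial Spearman reduces to Spearman and respects monotonicity", {
  set.seed(73)
  x <- rnorm(40); y <- rnorm(40)
  ar <- partial_spearman(x, y)
  expect_equal(ar$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  # monotone transform: rho = 1
  expect_equal(partial_spearman(x, exp(x))$rho, 1, tolerance = 1e-12)
  # degenerate control
  expect_error(partial_spearman(x, y, controls = data.frame(c1 = x)),
               class = "dynfc_validation_error")
})

test_that("partial Spearman recovers a planted association under confounding", {
  set.seed(74)
  hits <- vapply(1:100, function(i) {
    site <- factor(sample(1:3, 60, replace = TRUE))
    site_eff <- c(-2, 0, 2)[site]
    x <- rnorm(60) + site_eff
    y <- 0.5 * (x - site_eff) + rnorm(60) - site_eff   # true positive partial
    ar <- partial_spearman(x, y, controls = data.frame(site = site))
    ar$rho > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("adjusted group test reduces to plain ANOVA for constant covariates", {
  set.seed(75)
  groups <- factor(rep(c("RRMS-F", "RRMS-M", "HC-F", "HC-M"), each = 10))
  y <- rnorm(40) + (groups == "RRMS-F") * 1.5
  covars <- data.frame(age = rep(50, 40), mean_fd = rep(0.1, 40))
  res <- adjusted_group_test(y, groups, covars)
  f_oracle <- anova(aov(y ~ groups))[["F value"]][1]
  expect_equal(unique(res$f_statistic), f_oracle, tolerance = 1e-10)
  # the four enumerated contrasts, each once
  expect_setequal(res$contrast,
                  c("HC-F vs HC-M", "RRMS-F vs HC-F",
                    "RRMS-M vs HC-M", "RRMS-F vs RRMS-M"))
  expect_true(all(res$q >= res$p - 1e-15))
})

test_that("a pure age confound is removed by adjustment", {
  set.seed(76)
  groups <- factor(rep(c("RRMS-F", "HC-F", "RRMS-M", "HC-M"), each = 15))
  rejected <- vapply(1:100, function(i) {
    age <- rnorm(60, 40, 5) + (groups == "RRMS-F") * 10  # age drives the gap
    y <- 0.3 * age + rnorm(60, sd = 1)
    covars <- data.frame(age = age, mean_fd = runif(60, 0, 0.2))
    res <- adjusted_group_test(y, groups, covars)
    res$p[res$contrast == "RRMS-F vs HC-F"] < 0.05
  }, logical(1))
  expect_gte(mean(!rejected), 0.9)
})

test_that("covariate errors are informative", {
  groups <- factor(rep(c("RRMS-F", "HC-F", "RRMS-M", "HC-M"), each = 5))
  y <- rnorm(20)
  expect_error(adjusted_group_test(y, groups,
                                   data.frame(a = rnorm(20), b = NA)),
               "missing", class = "dynfc_validation_error")
  x <- rnorm(20)
  expect_error(adjusted_group_test(y, groups,
                                   data.frame(a = x, b = 2 * x)),
               "collinear", class = "dynfc_validation_error")
})

test_that("rank-formula AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(78)
  for (i in 1:20) {
    n1 <- sample(5:25, 1); n2 <- sample(5:25, 1)
    scores <- c(rnorm(n1, 0.8), rnorm(n2))
    labels <- rep(c(1, 0), c(n1, n2))
    ours <- roc_auc(scores, factor(labels, levels = c(0, 1)), positive = "1",
                    ci_bootstrap = 0)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("AUC/U identity holds across random datasets", {
  set.seed(77)
  errs <- vapply(1:200, function(i) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    x <- sample(1:8, n1, replace = TRUE)   # force ties
    y <- sample(1:8, n2, replace = TRUE)
    mw <- mann_whitney(x, y)
    roc <- roc_auc(c(x, y), rep(c("p", "n"), c(n1, n2)), positive = "p",
                   ci_bootstrap = 0)
    abs(roc$auc - mw$U / (n1 * n2))
  }, numeric(1))
  expect_lt(max(errs), 1e-12)
})
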