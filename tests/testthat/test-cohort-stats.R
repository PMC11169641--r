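# Cohort statistics: normalization, effect sizes, ranking, partial
# correlation, FDR, stage ANOVA, regression, naive Bayes CV, ROC.

small_cohort <- function() {
  tibble::tibble(
    subject_id = sprintf("S%02d", 1:8),
    group = c(rep("HC", 4), rep("PD", 4)),
    sex = rep(c("M", "F"), 4),
    F0 = c(3, 5, 3, 7, 9, 9, 5, 5),
    NSR = c(1, 2, 3, 4, 2, 3, 4, 5)
  )
}

test_that("z-normalization uses same-sex healthy-control statistics", {
  co <- synth_cohort(40, 80, seed = 601)
  z <- znormalize(co)
  for (sx in c("M", "F")) {
    hc <- z[z$group == "HC" & z$sex == sx, ]
    expect_lt(abs(mean(hc$DDKavr)), 1e-9)
    expect_lt(abs(sd(hc$DDKavr) - 1), 1e-9)
  }

  # HC(F) mean 5, SD 2; a PD(F) raw value of 9 scores z = 2
  co2 <- tibble::tibble(
    subject_id = as.character(1:4),
    group = c("HC", "HC", "HC", "PD"),
    sex = "F",
    F0 = c(3, 5, 7, 9)
  )
  z2 <- znormalize(co2, features = "F0")
  expect_equal(z2$F0[4], 2)
  expect_equal(znormalize(co2, features = "F0")$F0[2], 0)

  co2$F0 <- c(5, 5, 5, 9)
  expect_error(znormalize(co2, features = "F0"), "zero")
})

test_that("Hedges' g reproduces published group statistics", {
  expect_equal(hedges_g(5, 1, 10, 5, 1, 10), 0)
  expect_lt(abs(hedges_g(5.63, 0.62, 40, 4.99, 0.77, 80) - 0.875), 0.02)
  expect_lt(abs(hedges_g(405882.13, 222362.83, 40,
                         238256.90, 148346.25, 80) - 0.945), 0.01)
  expect_error(hedges_g(1, 0, 10, 1, 0, 10), "degenerate")
  expect_error(hedges_g(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("group comparison is a pooled two-sample t-test", {
  co <- tibble::tibble(
    subject_id = as.character(1:6),
    group = rep(c("HC", "PD"), each = 3),
    sex = "M",
    F0 = c(1, 2, 3, 1, 2, 3)
  )
  same <- compare_groups(co, features = "F0")
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$hedges_g, 0)

  co$F0 <- c(1, 2, 3, 4, 5, 6)
  diff <- compare_groups(co, features = "F0")
  expect_equal(diff$t_statistic, -3.674, tolerance = 1e-3)
  expect_equal(diff$p_value, 0.0213, tolerance = 1e-2)
})

test_that("group separation at reference effect sizes matches analytic power", {
  hits <- 0
  n_rep <- 400
  for (s in seq_len(n_rep)) {
    with_seed(700 + s, {
      hc <- rnorm(40, 5.63, 0.62)
      pd <- rnorm(80, 4.99, 0.77)
    })
    if (stats::t.test(hc, pd, var.equal = TRUE)$p.value < 0.001) {
      hits <- hits + 1
    }
  }
  # closed-form power oracle for the pooled t-test at alpha = 0.001
  sp <- sqrt((39 * 0.62^2 + 79 * 0.77^2) / 118)
  ncp <- (5.63 - 4.99) / sp * sqrt(40 * 80 / 120)
  crit <- qt(1 - 0.001 / 2, 118)
  power <- 1 - pt(crit, 118, ncp) + pt(-crit, 118, ncp)
  expect_gt(power, 0.8)
  expect_lt(abs(hits / n_rep - power), 0.05)
})

test_that("effect-size recovery is unbiased at the study group sizes", {
  delta <- 0.8
  gs <- numeric(500)
  for (s in seq_along(gs)) {
    with_seed(1000 + s, {
      x <- rnorm(40, delta, 1)
      y <- rnorm(80, 0, 1)
    })
    gs[s] <- hedges_g(mean(x), sd(x), 40, mean(y), sd(y), 80)
  }
  expect_lt(abs(mean(gs) - delta), 0.05)
})

test_that("feature ranking orders by |g| and demotes redundant features", {
  with_seed(610, {
    n <- 120
    grp <- rep(c("HC", "PD"), c(40, 80))
    a <- rnorm(n) + (grp == "PD") * 2
    b <- a + rnorm(n, 0, 0.01)           # near-copy of a, weaker by noise
    c_ <- rnorm(n) + (grp == "PD") * 0.7 # independent, weaker effect
    co <- tibble::tibble(subject_id = as.character(1:n), group = grp,
                         sex = "M", F0 = a, F0std = b, NSR = c_)
  })
  cmp <- compare_groups(co, features = c("F0", "F0std", "NSR"))
  rk <- rank_features(cmp, co, max_abs_corr = 0.8)
  expect_true(rk$demoted[rk$feature == "F0std"] ||
                rk$demoted[rk$feature == "F0"])
  expect_false(rk$demoted[rk$feature == "NSR"])
  expect_equal(which(rk$feature == "NSR"), 2L)

  # uncorrelated features keep the pure |g| order
  with_seed(611, {
    co2 <- tibble::tibble(subject_id = as.character(1:n), group = grp,
                          sex = "M",
                          F0 = rnorm(n) + (grp == "PD") * 2,
                          NSR = rnorm(n) + (grp == "PD") * 1)
  })
  cmp2 <- compare_groups(co2, features = c("F0", "NSR"))
  rk2 <- rank_features(cmp2, co2)
  expect_equal(rk2$feature, cmp2$feature[order(-abs(cmp2$hedges_g))])

  # at the bundled reference parameters, the empirical large-n ranking
  # matches the ranking implied analytically by the preset itself
  params <- cohort_reference_params()
  implied <- vapply(seq_len(nrow(params)), function(i) {
    abs(hedges_g(params$hc_mean[i], params$hc_sd[i], 40,
                 params$pd_mean[i], params$pd_sd[i], 80))
  }, numeric(1))
  big <- synth_cohort(4000, 8000, seed = 612)
  cmpb <- compare_groups(big)
  top_implied <- params$feature[order(-implied)][1:3]
  top_emp <- cmpb$feature[order(-abs(cmpb$hedges_g))][1:3]
  expect_equal(top_emp[1], top_implied[1])
  expect_setequal(top_emp, top_implied)
  expect_true("VowelArea" %in% top_emp)
})

test_that("partial correlation residualizes on covariates", {
  with_seed(620, x <- rnorm(50))
  pc <- partial_correlation(x, x, NULL)
  expect_equal(pc$r, 1)

  with_seed(621, {
    y <- rnorm(50)
  })
  plain <- stats::cor.test(x, y)
  pc2 <- partial_correlation(x, y, NULL)
  expect_equal(pc2$r, unname(plain$estimate), tolerance = 1e-12)
  expect_equal(pc2$p, plain$p.value, tolerance = 1e-12)

  # x and y driven by the same covariate: adjusted r collapses
  with_seed(622, {
    z <- rnorm(200)
    x2 <- 2 * z + rnorm(200, 0, 0.5)
    y2 <- -3 * z + rnorm(200, 0, 0.5)
  })
  adj <- partial_correlation(x2, y2, cbind(z))
  expect_lt(abs(adj$r), 0.2)
  expect_lt(abs(stats::cor(x2, y2)), 1) # raw correlation is strong
  expect_gt(abs(stats::cor(x2, y2)), 0.8)

  expect_error(partial_correlation(x2, y2, cbind(z, z)), "collinearity")
})

test_that("FDR adjustment equals the Benjamini-Hochberg step-up", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  for (s in 1:25) {
    with_seed(630 + s, p <- runif(sample(2:100, 1))^2)
    expect_equal(fdr_adjust(p), brute_bh(p), tolerance = 1e-12)
    expect_true(all(fdr_adjust(p) >= p))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("stage comparison detects separation and degenerates gracefully", {
  co <- tibble::tibble(
    subject_id = as.character(1:40),
    group = rep(c("HC", "PD"), each = 20),
    sex = "M",
    HY_stage = c(rep(NA, 20), rep(3, 20)),
    F0 = c(rnorm(20, 0, 1), rnorm(20, 2, 1))
  )
  with_seed(640, co$F0 <- c(rnorm(20, 0, 1), rnorm(20, 2, 1)))
  s <- stage_comparison(co, "F0")
  expect_lt(s$anova$p, 0.001)

  co$F0 <- rep(1, 40)
  s2 <- stage_comparison(co, "F0")
  expect_equal(s2$anova$F, 0)

  co$HY_stage[21] <- 5 # a singleton stage gets dropped
  co$F0 <- seq_len(40) / 10
  expect_warning(stage_comparison(co, "F0"), "dropping")
})

test_that("the linear severity model behaves like OLS", {
  with_seed(650, X <- matrix(rnorm(200 * 3), 200))
  y <- 2 * X[, 1] - X[, 2] + 0.5 * X[, 3]
  fit <- linear_updrs_model(X, y)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients[2]), 2, tolerance = 1e-9)

  with_seed(651, {
    X0 <- matrix(rnorm(500 * 6), 500)
    y0 <- rnorm(500)
  })
  expect_lt(linear_updrs_model(X0, y0)$r_squared, 0.05)

  expect_error(linear_updrs_model(cbind(X[, 1], X[, 1]), y), "collinearity")
})

test_that("ROC AUC equals the Mann-Whitney pair count", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  for (s in 1:100) {
    with_seed(660 + s, {
      n <- sample(4:50, 1)
      labs <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
      sc <- round(stats::runif(n), 2) # rounding forces ties
    })
    expect_equal(roc_auc(sc, labs), brute_auc(sc, labs), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("ROC curve starts at (0,0), ends at (1,1), and matches pROC", {
  with_seed(670, {
    sc <- stats::rnorm(60)
    labs <- stats::rbinom(60, 1, 0.5)
  })
  rc <- roc_curve(sc, labs)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)
  ref <- pROC::auc(pROC::roc(labs, sc, quiet = TRUE, direction = "<"))
  expect_equal(roc_auc(sc, labs), as.numeric(ref), tolerance = 1e-12)
})

test_that("naive Bayes CV separates separable classes and is reproducible", {
  with_seed(680, {
    X <- rbind(matrix(rnorm(40 * 3), 40), matrix(rnorm(60 * 3, 10), 60))
    y <- factor(rep(c("HC", "PD"), c(40, 60)), c("HC", "PD"))
  })
  rep1 <- nb_classify_cv(X, y, seed = 5)
  expect_equal(rep1$auc, 1)
  rep2 <- nb_classify_cv(X, y, seed = 5)
  expect_identical(rep1$scores, rep2$scores)
  expect_identical(rep1$folds, rep2$folds)
  rep3 <- nb_classify_cv(X, y, seed = 6)
  expect_false(identical(rep1$folds, rep3$folds))

  tab <- table(rep1$folds, y)
  expect_true(all(tab > 0)) # stratification: both classes in every fold

  expect_error(nb_classify_cv(X, factor(rep("PD", 100))), "two classes")
  expect_error(nb_classify_cv(X[1:10, ], y[c(1:7, 41:43)], k = 5),
               "stratification")
})

test_that("naive Bayes posteriors agree with an independent implementation", {
  with_seed(690, {
    X <- rbind(matrix(rnorm(30 * 2), 30), matrix(rnorm(30 * 2, 1.5), 30))
    y <- rep(c("HC", "PD"), each = 30)
    Xt <- matrix(rnorm(20 * 2, 0.7), 20)
  })
  m <- pdspeech:::.gnb_fit(X, y, var_floor_frac = 0)
  lp <- pdspeech:::.gnb_log_post(m, Xt)
  lp <- lp - apply(lp, 1, max)
  ours <- exp(lp)[, "PD"] / rowSums(exp(lp))
  ref <- e1071::naiveBayes(data.frame(a = X[, 1], b = X[, 2]), factor(y))
  theirs <- stats::predict(ref, data.frame(a = Xt[, 1], b = Xt[, 2]),
                           type = "raw")[, "PD"]
  expect_equal(ours, unname(theirs), tolerance = 1e-6)
})
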