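# Cohort-level statistics: gender-stratified normalization, group
# comparisons with Hedges' g, feature ranking, partial correlations, FDR,
# stage ANOVA, linear severity models, and the Gaussian naive Bayes
# cross-validated classifier with ROC/AUC.

.feature_cols <- function(cohort, features = NULL) {
  if (is.null(features)) {
    features <- intersect(acoustic_feature_names(), names(cohort))
  }
  if (length(features) == 0) stop("no feature columns found in cohort")
  features
}

#' Gender-stratified z-normalization against healthy controls
#'
#' Every subject's features are z-scored using the healthy-control mean and
#' SD of the matching sex: `z = (x - mean_HC_sex) / sd_HC_sex`. This removes
#' physiological sex differences (e.g. F0) before statistics and
#' classification.
#'
#' @param cohort A `CohortTable` tibble with `group` (`"HC"`/`"PD"`),
#'   `sex` (`"M"`/`"F"`) and feature columns.
#' @param features Feature columns to normalize (default: all 29 known
#'   acoustic features present).
#' @return The cohort with the feature columns replaced by z-scores.
#' @export
znormalize <- function(cohort, features = NULL) {
  features <- .feature_cols(cohort, features)
  if (any(is.na(cohort$sex)) || any(is.na(cohort$group))) {
    stop("sex and group must be non-missing")
  }
  out <- cohort
  for (sx in unique(cohort$sex)) {
    hc <- cohort$group == "HC" & cohort$sex == sx
    if (sum(hc) < 2) {
      stop("normalization error: fewer than 2 HC subjects in sex stratum ",
           sx)
    }
    rows <- cohort$sex == sx
    for (f in features) {
      m <- mean(cohort[[f]][hc], na.rm = TRUE)
      s <- stats::sd(cohort[[f]][hc], na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        stop("normalization error: zero/undefined HC SD for feature ", f,
             " in sex stratum ", sx)
      }
      out[[f]][rows] <- (cohort[[f]][rows] - m) / s
    }
  }
  out
}

#' Hedges' g standardized mean difference
#'
#' `g = J * (m1 - m2) / s_pooled` with the pooled SD over both groups and
#' the small-sample correction `J = 1 - 3 / (4*(n1 + n2 - 2) - 1)`.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return Hedges' g (scalar).
#' @export
hedges_g <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (s1 < 0 || s2 < 0 || (s1 == 0 && s2 == 0)) {
    stop("undefined effect: degenerate pooled SD")
  }
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
  J <- 1 - 3 / (4 * df - 1)
  J * (m1 - m2) / sp
}

#' Feature-wise PD/HC group comparison
#'
#' Pooled-variance two-sample t-test (two-tailed) and Hedges' g per
#' feature, HC minus PD. A Welch test is available behind `welch = TRUE`.
#'
#' @inheritParams znormalize
#' @param welch Use Welch's unequal-variance t-test instead of the pooled
#'   test.
#' @return A tibble with one row per feature: group means/SDs,
#'   `t_statistic`, `p_value`, `hedges_g`.
#' @export
compare_groups <- function(cohort, features = NULL, welch = FALSE) {
  features <- .feature_cols(cohort, features)
  hc <- cohort$group == "HC"
  pd <- cohort$group == "PD"
  rows <- lapply(features, function(f) {
    x <- cohort[[f]][hc]
    y <- cohort[[f]][pd]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      warning("feature ", f, " skipped: fewer than 2 values per group")
      return(NULL)
    }
    tt <- stats::t.test(x, y, var.equal = !welch)
    tibble::tibble(
      feature = f,
      mean_HC = mean(x), sd_HC = stats::sd(x), n_HC = length(x),
      mean_PD = mean(y), sd_PD = stats::sd(y), n_PD = length(y),
      t_statistic = unname(tt$statistic),
      p_value = tt$p.value,
      hedges_g = hedges_g(mean(x), stats::sd(x), length(x),
                          mean(y), stats::sd(y), length(y))
    )
  })
  dplyr::bind_rows(rows)
}

#' Rank features by effect size with correlation demotion
#'
#' Features are ordered by absolute Hedges' g, descending; walking down
#' that order, any feature whose absolute Pearson correlation with an
#' already-accepted feature exceeds `max_abs_corr` is demoted below all
#' accepted features. This is the automatable part of a selection that in
#' practice also weighs clinical interpretability.
#'
#' @param comparison Output of [compare_groups()].
#' @param cohort The cohort table (for pairwise feature correlations).
#' @param max_abs_corr Redundancy threshold on |r|.
#' @return A tibble: `feature`, `hedges_g`, `rank`, `demoted`.
#' @seealso [selected_feature_preset()] for the six-feature preset.
#' @export
rank_features <- function(comparison, cohort, max_abs_corr = 0.8) {
  ord <- comparison[order(-abs(comparison$hedges_g)), ]
  accepted <- character(0)
  demoted <- character(0)
  X <- as.data.frame(cohort[, ord$feature])
  for (f in ord$feature) {
    if (length(accepted) == 0) {
      accepted <- f
      next
    }
    r <- vapply(accepted, function(a) {
      abs(stats::cor(X[[f]], X[[a]], use = "pairwise.complete.obs"))
    }, numeric(1))
    if (any(r > max_abs_corr, na.rm = TRUE)) {
      demoted <- c(demoted, f)
    } else {
      accepted <- c(accepted, f)
    }
  }
  final <- c(accepted, demoted)
  tibble::tibble(
    feature = final,
    hedges_g = comparison$hedges_g[match(final, comparison$feature)],
    rank = seq_along(final),
    demoted = final %in% demoted
  )
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on
#' `[1, covariates]`; the p-value uses a t reference distribution with
#' `n - n_covariates - 2` degrees of freedom. With no covariates this
#' reduces exactly to the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix/data frame of covariates (may have zero
#'   columns).
#' @return A list with `r`, `p`, `n`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) covariates <- matrix(numeric(0), length(x), 0)
  covariates <- as.matrix(covariates)
  keep <- stats::complete.cases(x, y, covariates)
  x <- x[keep]; y <- y[keep]
  Z <- covariates[keep, , drop = FALSE]
  n <- length(x)
  k <- ncol(Z)
  if (n <= k + 2) stop("too few complete observations for the covariate set")
  D <- cbind(1, Z)
  if (qr(D)$rank < ncol(D)) stop("collinearity error: rank-deficient covariates")
  rx <- stats::lm.fit(D, x)$residuals
  ry <- stats::lm.fit(D, y)$residuals
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), n = n, df = df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in sorted order and capped at 1.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

# map an HY stage value to the analysis bins
.hy_bin <- function(hy) {
  ifelse(is.na(hy), NA_character_,
         ifelse(hy <= 2, "HY1.5-2.0",
                ifelse(hy <= 2.5, "HY2.5",
                       ifelse(hy <= 3, "HY3.0", "HY4-5"))))
}

#' Compare a feature across HC and Hoehn-Yahr stage groups
#'
#' One-way ANOVA across `{HC, HY1.5-2.0, HY2.5, HY3.0, HY4-5}`, with
#' Bonferroni-adjusted pairwise stage-vs-HC t-tests and unadjusted (least
#' significant difference) pairwise tests between patient stages. Stages
#' with fewer than 2 subjects are dropped with a warning.
#'
#' @param cohort A `CohortTable` with `HY_stage` for PD rows.
#' @param feature Feature column name.
#' @return A list with `anova` (`F`, `p`, `df`), `vs_hc` (Bonferroni
#'   stage-vs-HC table) and `between_stages` (LSD pairwise table).
#' @export
stage_comparison <- function(cohort, feature) {
  stopifnot(feature %in% names(cohort))
  grp <- ifelse(cohort$group == "HC", "HC", .hy_bin(cohort$HY_stage))
  ok <- !is.na(grp) & !is.na(cohort[[feature]])
  d <- data.frame(y = cohort[[feature]][ok], g = grp[ok])
  counts <- table(d$g)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning("dropping stage(s) with < 2 subjects: ",
            paste(small, collapse = ", "))
    d <- d[!(d$g %in% small), ]
  }
  if (length(unique(d$g)) < 2) stop("fewer than 2 usable groups")
  d$g <- factor(d$g)
  fit <- stats::aov(y ~ g, data = d)
  s <- summary(fit)[[1]]
  anova_row <- list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
                    df = unname(s[["Df"]]))
  if (all(d$y == d$y[1])) anova_row <- list(F = 0, p = 1, df = anova_row$df)

  stages <- setdiff(levels(d$g), "HC")
  vs_hc <- NULL
  safe_t <- function(a, b) {
    tryCatch(stats::t.test(a, b, var.equal = TRUE),
             error = function(e) list(statistic = c(t = 0), p.value = 1))
  }
  if ("HC" %in% d$g && length(stages) > 0) {
    vs_hc <- dplyr::bind_rows(lapply(stages, function(st) {
      tt <- safe_t(d$y[d$g == st], d$y[d$g == "HC"])
      tibble::tibble(stage = st, t = unname(tt$statistic),
                     p_raw = tt$p.value,
                     p_bonferroni = min(1, tt$p.value * length(stages)))
    }))
  }
  between <- NULL
  if (length(stages) >= 2) {
    pairs <- utils::combn(stages, 2)
    between <- dplyr::bind_rows(apply(pairs, 2, function(pr) {
      tt <- safe_t(d$y[d$g == pr[1]], d$y[d$g == pr[2]])
      tibble::tibble(stage_a = pr[1], stage_b = pr[2],
                     t = unname(tt$statistic), p_lsd = tt$p.value)
    }))
  }
  list(anova = anova_row, vs_hc = vs_hc, between_stages = between)
}

#' Linear model of a clinical severity score on acoustic features
#'
#' Ordinary least squares with intercept; reports coefficients, in-sample
#' R-squared and per-subject predictions. Rows with missing values are
#' dropped.
#'
#' @param features Numeric matrix/data frame of predictors.
#' @param target Numeric response (e.g. MDS-UPDRS III).
#' @return A list with `coefficients`, `r_squared`, `predictions`, `n`.
#' @export
linear_updrs_model <- function(features, target) {
  X <- as.matrix(features)
  keep <- stats::complete.cases(X, target)
  X <- X[keep, , drop = FALSE]
  y <- target[keep]
  if (length(y) <= ncol(X) + 1) stop("too few observations for the model")
  D <- cbind(`(Intercept)` = 1, X)
  if (qr(D)$rank < ncol(D)) stop("collinearity error: rank-deficient design")
  fit <- stats::lm.fit(D, y)
  pred <- D %*% fit$coefficients
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(coefficients = fit$coefficients, r_squared = r2,
       predictions = as.numeric(pred), n = length(y))
}

#' Area under the ROC curve
#'
#' The Mann-Whitney probability: the fraction of (negative, positive)
#' pairs where the positive scores higher, counting ties as 1/2.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels (0/1, logical, or a 2-level factor).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) != 2) stop("labels must contain both classes")
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  r <- rank(scores)
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return A tibble with `threshold`, `fpr`, `tpr` (thresholds descending;
#'   a point is "predict positive when score >= threshold").
#' @export
roc_curve <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) != 2) stop("labels must contain both classes")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tab <- t(vapply(th, function(t0) {
    pred <- scores >= t0
    c(fpr = sum(pred & y == 0) / sum(y == 0),
      tpr = sum(pred & y == 1) / sum(y == 1))
  }, numeric(2)))
  tibble::tibble(threshold = th, fpr = tab[, "fpr"], tpr = tab[, "tpr"])
}

# fit a Gaussian naive Bayes model: class priors and per-feature normal
# parameters, with a variance floor against constant features in a fold
.gnb_fit <- function(X, y, var_floor_frac = 1e-9) {
  classes <- sort(unique(y))
  floor_v <- var_floor_frac * max(apply(X, 2, stats::var), 1e-12)
  models <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    list(prior = nrow(Xi) / nrow(X),
         mean = colMeans(Xi),
         var = pmax(apply(Xi, 2, stats::var), floor_v))
  })
  names(models) <- classes
  models
}

# log posterior (up to a constant) of each class for rows of X
.gnb_log_post <- function(models, X) {
  vapply(models, function(m) {
    log(m$prior) + rowSums(vapply(seq_len(ncol(X)), function(j) {
      stats::dnorm(X[, j], m$mean[j], sqrt(m$var[j]), log = TRUE)
    }, numeric(nrow(X))))
  }, numeric(nrow(X)))
}

#' Gaussian naive Bayes PD/HC classification with stratified k-fold CV
#'
#' Per fold, class priors and per-feature Gaussians are fitted on the
#' training subjects only; held-out subjects are scored by the posterior
#' probability of the positive class. Out-of-fold scores are pooled for
#' the primary ROC/AUC; per-fold AUCs are reported alongside. Folds are
#' stratified by class and shuffled by `seed`, so the report is fully
#' reproducible.
#'
#' @param features Numeric matrix/data frame (subjects x features).
#' @param labels Binary class labels; the second factor level (e.g. `"PD"`
#'   against `"HC"`) is the positive class.
#' @param k Number of folds.
#' @param seed RNG seed for the fold shuffle.
#' @return A `ClassifierReport` list: `folds`, `scores` (posterior
#'   probability of positive), `roc` (curve points), `auc` (pooled),
#'   `fold_auc`, `seed`.
#' @export
nb_classify_cv <- function(features, labels, k = 5, seed = 1) {
  X <- as.matrix(features)
  y <- as.factor(labels)
  if (nlevels(y) != 2) stop("labels must contain exactly two classes")
  if (nrow(X) < k) stop("need at least k subjects")
  pos <- levels(y)[2]
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      if (length(idx) < k) {
        stop("stratification error: class ", cl, " has fewer than k subjects")
      }
      folds[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  scores <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) {
      stop("stratification error: single-class training fold")
    }
    m <- .gnb_fit(X[tr, , drop = FALSE], as.character(y[tr]))
    lp <- .gnb_log_post(m, X[!tr, , drop = FALSE])
    # posterior probability of the positive class
    lp <- lp - apply(lp, 1, max)
    p <- exp(lp)
    scores[!tr] <- p[, pos] / rowSums(p)
  }
  fold_auc <- vapply(seq_len(k), function(f) {
    roc_auc(scores[folds == f], y[folds == f])
  }, numeric(1))
  structure(
    list(folds = folds, scores = scores, labels = y,
         roc = roc_curve(scores, y), auc = roc_auc(scores, y),
         fold_auc = fold_auc, k = k, seed = seed),
    class = "ClassifierReport"
  )
}

#' @export
print.ClassifierReport <- function(x, ...) {
  cat(sprintf("<ClassifierReport> %d-fold GNB: pooled AUC %.3f (folds %s)\n",
              x$k, x$auc, paste(sprintf("%.2f", x$fold_auc), collapse = ", ")))
  invisible(x)
}
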