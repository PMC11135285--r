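#' Forecast metrics over observed target cells
#'
#' MAE, MAPE and R-squared between predictions and truth, restricted to
#' cells with mask = 1. MAPE excludes cells with |truth| <= eps (count
#' reported) because several scores normalize near zero; R-squared uses the
#' observed-cell mean for its total sum of squares and is \code{NA} for a
#' zero-variance truth.
#'
#' @param pred,truth,mask numeric arrays/vectors of identical shape.
#' @param eps MAPE guard (default 1e-8).
#' @return list: \code{mae}, \code{mape}, \code{r2},
#'   \code{n} observed cells, \code{n_mape_excluded}.
#' @export
predictionMetrics <- function(pred, truth, mask, eps = 1e-8) {
  obs <- which(mask == 1)
  if (length(obs) == 0) stop("no observed cells")
  e <- pred[obs] - truth[obs]
  tv <- truth[obs]
  keep <- abs(tv) > eps
  mape <- if (any(keep)) mean(abs(e[keep]) / abs(tv[keep])) else NA_real_
  sst <- sum((tv - mean(tv))^2)
  r2 <- if (length(obs) >= 2 && sst > 0) 1 - sum(e^2) / sst else NA_real_
  list(mae = mean(abs(e)), mape = mape, r2 = r2,
       n = length(obs), n_mape_excluded = sum(!keep))
}

#' Per-feature forecast metrics on a subject subset
#'
#' Runs the teacher-forced forward pass on the given subjects and scores
#' each MRI marker and cognitive feature on its observed next-visit targets
#' in normalized space.
#'
#' @param model a trained \linkS4class{TrajectoryModel}.
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param subjects subject names to evaluate (e.g. a test split).
#' @return data.frame: feature, role, mae, mape, r2, n.
#' @export
regressionMetrics <- function(model, cohort, subjects) {
  sub <- subsetSubjects(cohort, subjects)
  fw <- forwardSequence(model, sub)
  inp <- fw$inputs
  rows <- list()
  feats <- c(inp$features$mri, inp$features$cog)
  for (f in feats) {
    is_mri <- f %in% inp$features$mri
    i <- if (is_mri) match(f, inp$features$mri) else match(f, inp$features$cog)
    pred <- if (is_mri) fw$mhat[i, , ] else fw$chat[i, , ]
    tru <- if (is_mri) inp$target_m[i, , ] else inp$target_c[i, , ]
    msk <- if (is_mri) inp$target_m_mask[i, , ] else inp$target_c_mask[i, , ]
    pm <- tryCatch(predictionMetrics(pred, tru, msk),
                   error = function(e) list(mae = NA, mape = NA, r2 = NA,
                                            n = 0, n_mape_excluded = 0))
    rows[[f]] <- data.frame(feature = f,
                            role = if (is_mri) "mri" else "cognitive",
                            mae = pm$mae, mape = pm$mape, r2 = pm$r2,
                            n = pm$n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon convention) and tied absolute
#' differences are mid-ranked. For n <= 25 retained pairs the two-sided p
#' comes from the exact null distribution of the positive-rank sum
#' (enumerated by convolution over the 2^n sign assignments); above that, a
#' normal approximation with continuity and tie correction is used.
#'
#' @param a,b equal-length numeric vectors of paired per-fold metrics.
#' @return list: \code{statistic} (positive-rank sum V), \code{p.value},
#'   \code{n} retained pairs, \code{method}.
#' @export
pairedWilcoxon <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5)
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) stop("degenerate test: all differences are zero")
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25) {
    # exact: distribution of 2*V by subset-sum convolution over ranks
    r2 <- round(2 * r)
    maxs <- sum(r2)
    f <- numeric(maxs + 1); f[1] <- 1      # f[w+1] = #assignments with sum w
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(maxs + 1 - ri)])
      f <- f + shifted
    }
    f <- f / 2^n
    w2 <- round(2 * V)
    p_le <- sum(f[seq_len(w2 + 1)])
    p_ge <- sum(f[(w2 + 1):(maxs + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    corr <- sign(V - mu) * 0.5
    z <- (V - mu - corr) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with continuity correction"
  }
  list(statistic = V, p.value = p, n = n, method = method)
}

#' Rank-based AUC
#'
#' Mann-Whitney AUC of decision scores for the positive class; invariant to
#' strictly monotone transforms of the scores, ties handled by mid-ranks.
#'
#' @param scores numeric decision values.
#' @param positive logical or 0/1, TRUE for the positive class.
#' @return scalar AUC in [0, 1].
#' @export
rankAUC <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("metric error: single-class sample")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-subject SVM feature vectors for a classification scenario
#'
#' \code{baseline_only}: first-visit features only. \code{longitudinal_missing}:
#' all visits, missing cells filled with the training mean at classification
#' time. \code{longitudinal_imputed}: decay-imputed observations plus the
#' model's next-visit predictions appended as extra features. All scenarios
#' include the demographics and use the model's training normalization.
#'
#' @param model a trained \linkS4class{TrajectoryModel}.
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param scenario one of \code{"baseline_only"},
#'   \code{"longitudinal_missing"}, \code{"longitudinal_imputed"}.
#' @return numeric matrix subjects x features.
#' @export
scenarioFeatures <- function(model, cohort,
                             scenario = c("baseline_only",
                                          "longitudinal_missing",
                                          "longitudinal_imputed")) {
  scenario <- match.arg(scenario)
  ncoh <- applyNormalizer(cohort, model@normalizer)
  means <- model@config$train_means_norm
  v <- cohortValues(ncoh); m <- cohortMask(ncoh)
  schema <- cohortSchema(cohort)
  att <- attendedFeatures(schema); dem <- demographicFeatures(schema)
  N <- dim(v)[2]; Tt <- dim(v)[3]
  dem_base <- t(matrix(v[dem, , 1], length(dem), N))
  if (scenario == "baseline_only") {
    X <- cbind(t(matrix(v[att, , 1], length(att), N)), dem_base)
  } else if (scenario == "longitudinal_missing") {
    imp <- imputeCohort(ncoh, means, method = "mean")
    X <- cbind(do.call(cbind, lapply(seq_len(Tt), function(t)
      t(matrix(imp$values[att, , t], length(att), N)))), dem_base)
  } else {
    imp <- imputeCohort(ncoh, means, w = model@config$impute_w %||% 1,
                        method = "decay")
    fw <- forwardSequence(model, cohort)
    obs_block <- do.call(cbind, lapply(seq_len(Tt), function(t)
      t(matrix(imp$values[att, , t], length(att), N))))
    pred_block <- do.call(cbind, lapply(seq_len(Tt - 1), function(t)
      cbind(t(matrix(fw$mhat[, , t], dim(fw$mhat)[1], N)),
            t(matrix(fw$chat[, , t], dim(fw$chat)[1], N)))))
    X <- cbind(obs_block, pred_block, dem_base)
  }
  rownames(X) <- colnames(cohort)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

#' Downstream amyloid-positivity classification
#'
#' Stratified k-fold SVM classification of the amyloid group from
#' scenario-specific feature vectors (RBF kernel; the cost parameter is
#' selected per fold by inner 3-fold validation accuracy). Sensitivity is
#' the recall of the amyloid-positive class; AUC is computed from the SVM
#' decision values by the rank statistic.
#'
#' @inheritParams scenarioFeatures
#' @param n_folds outer folds (default 5).
#' @param C_grid SVM cost candidates (default 0.1, 1, 10).
#' @param seed integer seed for the fold assignment.
#' @param labels per-subject labels; defaults to the cohort's (override to
#'   run permutation diagnostics).
#' @return list: \code{report} one-row data.frame (scenario, mean and sd of
#'   accuracy/sensitivity/specificity/auc), \code{folds} per-fold metrics.
#' @export
downstreamClassification <- function(model, cohort,
                                     scenario = "longitudinal_imputed",
                                     n_folds = 5, C_grid = c(0.1, 1, 10),
                                     seed = 1,
                                     labels = abetaGroup(cohort)) {
  X <- scenarioFeatures(model, cohort, scenario)
  y <- factor(labels, levels = c("abeta_neg", "abeta_pos"))
  chunk <- .stratifiedChunks(as.character(y), n_folds,
                             stageSeed(seed, paste0("svmcv_", scenario)))
  rows <- list()
  for (k in seq_len(n_folds)) {
    tr <- chunk != k; te <- chunk == k
    if (length(unique(y[te])) < 2) stop("metric error: single-class test fold")
    bestC <- .selectCost(X[tr, , drop = FALSE], y[tr], C_grid,
                         stageSeed(seed, paste0("svminner", k)))
    fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = bestC, scale = FALSE)
    pr <- stats::predict(fit, X[te, , drop = FALSE], decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    # orient decision values so larger = more amyloid-positive
    if (grepl("abeta_neg/abeta_pos", colnames(attr(pr, "decision.values"))[1]))
      dv <- -dv
    truth <- y[te]
    tp <- sum(pr == "abeta_pos" & truth == "abeta_pos")
    tn <- sum(pr == "abeta_neg" & truth == "abeta_neg")
    fp <- sum(pr == "abeta_pos" & truth == "abeta_neg")
    fn <- sum(pr == "abeta_neg" & truth == "abeta_pos")
    rows[[k]] <- data.frame(
      fold = k, cost = bestC,
      accuracy = (tp + tn) / length(truth),
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      auc = rankAUC(dv, truth == "abeta_pos"))
  }
  folds <- do.call(rbind, rows)
  report <- data.frame(
    scenario = scenario,
    accuracy = mean(folds$accuracy), accuracy_sd = sd(folds$accuracy),
    sensitivity = mean(folds$sensitivity), sensitivity_sd = sd(folds$sensitivity),
    specificity = mean(folds$specificity), specificity_sd = sd(folds$specificity),
    auc = mean(folds$auc), auc_sd = sd(folds$auc))
  list(report = report, folds = folds)
}

.selectCost <- function(X, y, C_grid, seed) {
  if (length(C_grid) == 1) return(C_grid)
  chunk <- .stratifiedChunks(as.character(y), 3, seed)
  acc <- sapply(C_grid, function(C) {
    mean(sapply(1:3, function(k) {
      fit <- e1071::svm(X[chunk != k, , drop = FALSE], y[chunk != k],
                        kernel = "radial", cost = C, scale = FALSE)
      mean(stats::predict(fit, X[chunk == k, , drop = FALSE]) == y[chunk == k])
    }))
  })
  C_grid[which.max(acc)]
}
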