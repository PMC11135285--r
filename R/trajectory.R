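#' Relative change of markers from baseline
#'
#' \code{s[f, i, t] = (y[f, i, t] - y0[f, i]) / y0[f, i]} for every marker
#' f, subject i and time t, plus a sign-preserving normalization to [-1, 1]:
#' positive values are divided by the tensor maximum and negative values by
#' the magnitude of the tensor minimum, so both extremes map exactly to
#' +/-1 (when both signs are present) while increase/decrease keeps its
#' sign.
#'
#' @param y numeric array markers x subjects x times.
#' @param y0 numeric matrix markers x subjects of baseline values (nonzero).
#' @return list: \code{s} raw relative change, \code{s_norm} normalized to
#'   [-1, 1].
#' @export
relativeChange <- function(y, y0) {
  stopifnot(length(dim(y)) == 3, all(dim(y)[1:2] == dim(y0)))
  if (any(y0 == 0)) {
    bad <- which(y0 == 0, arr.ind = TRUE)[1, ]
    stop("division error: zero baseline for marker ", bad[1],
         ", subject ", bad[2])
  }
  s <- sweep(y, c(1, 2), y0, "-")
  s <- sweep(s, c(1, 2), y0, "/")
  list(s = s, s_norm = normalizeSigned(s))
}

#' Sign-preserving [-1, 1] normalization
#'
#' @param s numeric array.
#' @return array of the same shape with positives scaled by the maximum and
#'   negatives by |minimum|; all-zero input is returned unchanged.
#' @export
normalizeSigned <- function(s) {
  hi <- max(s, na.rm = TRUE); lo <- min(s, na.rm = TRUE)
  out <- s
  if (hi > 0) { idx <- which(s > 0); out[idx] <- s[idx] / hi }
  if (lo < 0) { idx <- which(s < 0); out[idx] <- s[idx] / (-lo) }
  out
}

#' Threshold map of normalized relative changes
#'
#' @param s_norm array of normalized relative changes in [-1, 1].
#' @param tau threshold (default 0.25); cells with |s| >= tau flag 1
#'   (boundary values are flagged).
#' @return binary array of the same shape.
#' @export
thresholdMap <- function(s_norm, tau = 0.25) {
  (abs(s_norm) >= tau) * 1
}

#' Group mean curves and per-subject trajectory agreement
#'
#' For each feature and amyloid group: the mean observed and mean predicted
#' curve across subjects (observed target cells only), and the group mean of
#' per-subject Pearson correlations between the observed and predicted
#' series (subjects with fewer than 2 observed points, or a constant series,
#' are excluded and counted).
#'
#' @param obs,pred,mask numeric arrays features x subjects x times, aligned
#'   (e.g. next-visit targets and teacher-forced predictions for visits
#'   2..T).
#' @param labels per-subject group labels.
#' @return list: \code{curves} data.frame (feature, group, time,
#'   observed_mean, predicted_mean, n), \code{rho} data.frame (feature,
#'   group, rho_bar, n_subjects, n_excluded).
#' @export
groupTrajectories <- function(obs, pred, mask, labels) {
  feats <- dimnames(obs)[[1]] %||% as.character(seq_len(dim(obs)[1]))
  groups <- unique(labels)
  if (length(groups) < 2) stop("group error: both amyloid groups required")
  curves <- list(); rho <- list()
  for (f in seq_along(feats)) for (g in groups) {
    gi <- which(labels == g)
    for (t in seq_len(dim(obs)[3])) {
      ok <- mask[f, gi, t] == 1
      curves[[length(curves) + 1]] <- data.frame(
        feature = feats[f], group = g, time = t,
        observed_mean = if (any(ok)) mean(obs[f, gi, t][ok]) else NA_real_,
        predicted_mean = if (any(ok)) mean(pred[f, gi, t][ok]) else NA_real_,
        n = sum(ok))
    }
    rs <- sapply(gi, function(i) {
      ok <- mask[f, i, ] == 1
      if (sum(ok) < 2) return(NA_real_)
      o <- obs[f, i, ok]; p <- pred[f, i, ok]
      if (sd(o) == 0 || sd(p) == 0) return(NA_real_)
      stats::cor(o, p)
    })
    rho[[length(rho) + 1]] <- data.frame(
      feature = feats[f], group = g,
      rho_bar = mean(rs, na.rm = TRUE),
      n_subjects = sum(!is.na(rs)), n_excluded = sum(is.na(rs)))
  }
  list(curves = do.call(rbind, curves), rho = do.call(rbind, rho))
}

#' Group trajectories from a trained model
#'
#' Convenience wrapper running the teacher-forced forward pass and scoring
#' next-visit targets (normalized space) with \code{\link{groupTrajectories}}.
#'
#' @param model a trained \linkS4class{TrajectoryModel}.
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param subjects optional subject subset.
#' @return see \code{\link{groupTrajectories}}.
#' @export
modelGroupTrajectories <- function(model, cohort, subjects = colnames(cohort)) {
  sub <- subsetSubjects(cohort, subjects)
  fw <- forwardSequence(model, sub)
  inp <- fw$inputs
  obs <- abind3(inp$target_m, inp$target_c)
  pred <- abind3(fw$mhat, fw$chat)
  mask <- abind3(inp$target_m_mask, inp$target_c_mask)
  dimnames(obs)[[1]] <- dimnames(pred)[[1]] <- dimnames(mask)[[1]] <-
    c(inp$features$mri, inp$features$cog)
  groupTrajectories(obs, pred, mask, abetaGroup(sub))
}

#' Group-level attention summary with change flags
#'
#' Attention maps are averaged within each group at every time step, then
#' min-max normalized to [0, 1] per time slice. For every cell, the
#' normalized series over time is compared with its first observation:
#' an \emph{orange} flag marks times where the value has fallen more than
#' 0.05 below the first observation while the series decreases over time
#' (last <= first with at least one strict drop); a \emph{red} flag marks
#' times where it has risen more than 0.2 above the first observation
#' while the series increases (last >= first with at least one strict
#' rise).
#'
#' @param attention array B x B x subjects x times of per-subject attention
#'   maps (e.g. from \code{\link{forwardSequence}}).
#' @param labels per-subject group labels.
#' @param thresholds length-2 numeric: orange (decrease) and red (increase)
#'   thresholds, default \code{c(0.05, 0.2)}.
#' @return named list per group: \code{mean} (B x B x times normalized
#'   averages) and \code{flags} (character array, values \code{"none"},
#'   \code{"orange"}, \code{"red"}; first time slice is all \code{"none"}).
#' @export
attentionSummary <- function(attention, labels, thresholds = c(0.05, 0.2)) {
  stopifnot(length(dim(attention)) == 4)
  Tn <- dim(attention)[4]
  if (Tn < 2) stop("insufficient sequence: need at least 2 time points")
  B <- dim(attention)[1]
  out <- list()
  for (g in unique(labels)) {
    gi <- which(labels == g)
    if (!length(gi)) stop("group '", g, "' has no subjects")
    avg <- array(NA_real_, c(B, B, Tn))
    for (t in seq_len(Tn)) {
      m <- apply(attention[, , gi, t, drop = FALSE], c(1, 2), mean)
      rng <- range(m)
      avg[, , t] <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
    }
    flags <- array("none", c(B, B, Tn))
    for (i in seq_len(B)) for (j in seq_len(B)) {
      v <- avg[i, j, ]
      decreasing <- v[Tn] <= v[1] && any(diff(v) < 0)
      increasing <- v[Tn] >= v[1] && any(diff(v) > 0)
      for (t in 2:Tn) {
        if (decreasing && (v[1] - v[t]) > thresholds[1])
          flags[i, j, t] <- "orange"
        if (increasing && (v[t] - v[1]) > thresholds[2])
          flags[i, j, t] <- "red"
      }
    }
    out[[g]] <- list(mean = avg, flags = flags)
  }
  out
}

#' Amyloid-positivity cutoff by exact one-dimensional 2-means
#'
#' Partitions Centiloid values into two clusters by the split (over sorted
#' values) minimizing total within-cluster sum of squares — the exact 1-D
#' k-means solution, deterministic with no random initialization. The
#' cutoff is the mean + 2 sd (sample sd) of the lower cluster.
#'
#' @param centiloid numeric vector (>= 2 values).
#' @return list: \code{cutoff}, \code{assignment} (1 = lower cluster,
#'   2 = upper), \code{centers}, \code{split_value}.
#' @export
deriveAmyloidCutoff <- function(centiloid) {
  stopifnot(length(centiloid) >= 2)
  x <- sort(centiloid)
  n <- length(x)
  if (length(unique(x)) < 2) {
    warning("degenerate single-cluster data; cutoff at midpoint")
    return(list(cutoff = x[1], assignment = rep(1L, n),
                centers = c(x[1], NA), split_value = x[1]))
  }
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(lo, hi) {          # within-SSE of x[lo..hi]
    s <- cs[hi] - if (lo > 1) cs[lo - 1] else 0
    s2 <- cs2[hi] - if (lo > 1) cs2[lo - 1] else 0
    s2 - s^2 / (hi - lo + 1)
  }
  tot <- sapply(seq_len(n - 1), function(k) sse(1, k) + sse(k + 1, n))
  k <- which.min(tot)
  lower <- x[seq_len(k)]; upper <- x[(k + 1):n]
  sdl <- if (length(lower) > 1) sd(lower) else 0
  assignment <- ifelse(centiloid <= x[k], 1L, 2L)
  list(cutoff = mean(lower) + 2 * sdl,
       assignment = assignment,
       centers = c(mean(lower), mean(upper)),
       split_value = x[k])
}

#' Relative MRI change summary for a cohort and model
#'
#' Computes ground-truth and predicted relative changes of the six MRI
#' markers from baseline (native units), their joint sign-preserving
#' normalization, and the 0.25 threshold exceedance maps, per the group
#' trajectory analysis.
#'
#' @param model a trained \linkS4class{TrajectoryModel}.
#' @param cohort the observed \linkS4class{LongitudinalCohort} fed to the
#'   model.
#' @param truth cohort supplying the ground-truth values (defaults to
#'   \code{cohort}; pass the complete simulated cohort when available —
#'   unobserved ground-truth cells otherwise stay NA).
#' @param tau threshold (default 0.25).
#' @return list: \code{s_g}, \code{s_p} raw relative changes (markers x
#'   subjects x visits 2..T), \code{s_g_norm}, \code{s_p_norm},
#'   \code{exceed_g}, \code{exceed_p} threshold maps, \code{labels}.
#' @export
relativeChangeSummary <- function(model, cohort, truth = cohort, tau = 0.25) {
  fw <- forwardSequence(model, cohort)
  inp <- fw$inputs
  mri <- inp$features$mri
  v <- cohortValues(truth)[mri, , , drop = FALSE]
  y0 <- matrix(v[, , 1], length(mri), dim(v)[2])
  y_g <- v[, , -1, drop = FALSE]
  # predictions back on the native scale for visits 2..T
  y_p <- denormalizeArray(fw$mhat, model@normalizer, mri)
  rc_g <- relativeChange(y_g, y0)
  rc_p <- relativeChange(y_p, y0)
  # joint normalization so both tensors share one scale
  joint <- normalizeSigned(abind3(rc_g$s, rc_p$s))
  Tn <- dim(rc_g$s)[3]
  sgn <- joint[seq_along(mri), , , drop = FALSE]
  spn <- joint[length(mri) + seq_along(mri), , , drop = FALSE]
  list(s_g = rc_g$s, s_p = rc_p$s, s_g_norm = sgn, s_p_norm = spn,
       exceed_g = thresholdMap(sgn, tau), exceed_p = thresholdMap(spn, tau),
       labels = abetaGroup(cohort))
}
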