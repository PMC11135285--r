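#' Temporal decay factor
#'
#' \code{exp(-max(0, w * delta + b))}, elementwise. Guarantees values in
#' (0, 1], equals 1 at delta = 0 whenever b <= 0, and is monotone
#' nonincreasing in delta for w >= 0. Used at the input level to blend the
#' last observation with the training mean, and (with a learned projection)
#' at the hidden level to attenuate the recurrent state.
#'
#' @param delta nonnegative numeric (any shape).
#' @param w,b decay weight and bias, recycled elementwise.
#' @return numeric of the same shape as \code{delta}, in (0, 1].
#' @export
computeDecay <- function(delta, w = 1, b = 0) {
  stopifnot(all(delta >= 0, na.rm = TRUE))
  exp(-pmax(0, w * delta + b))
}

#' Per-feature training means from observed cells
#'
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param train_ids subjects of the training split.
#' @return named numeric vector, one mean per feature.
#' @export
trainMeans <- function(cohort, train_ids) {
  v <- cohortValues(cohort)[, train_ids, , drop = FALSE]
  m <- cohortMask(cohort)[, train_ids, , drop = FALSE]
  feats <- cohortSchema(cohort)@names
  out <- setNames(numeric(length(feats)), feats)
  for (f in seq_along(feats)) {
    obs <- v[f, , ][m[f, , ] == 1]
    if (!length(obs))
      stop("degenerate feature '", feats[f],
           "': no observed training cells")
    out[f] <- mean(obs)
  }
  out
}

#' Fit per-feature imputation decay rates on the training split
#'
#' Data-driven calibration of the input-level decay: for every feature, the
#' decay rate w is chosen to minimize the mean squared error of
#' reconstructing observed training cells from their own last observation,
#' \code{gamma * last + (1 - gamma) * train_mean} with
#' \code{gamma = exp(-w * delta)}. Only cells with a prior observation
#' contribute; the candidate grid spans pure carry-forward (w = 0) to
#' near-mean fill (large w) and the search is deterministic.
#'
#' @param cohort a \linkS4class{LongitudinalCohort} (normalized or native
#'   scale; the fit is scale-covariant per feature).
#' @param train_ids subjects of the training split.
#' @param means per-feature training means on the same scale.
#' @param w_grid candidate decay rates per year.
#' @return named numeric vector of per-feature decay rates.
#' @export
fitImputationDecay <- function(cohort, train_ids, means,
                               w_grid = c(0, 2^seq(-4, 3, by = 0.5))) {
  v <- cohortValues(cohort)[, train_ids, , drop = FALSE]
  m <- cohortMask(cohort)[, train_ids, , drop = FALSE]
  d <- cohortDelta(cohort)[, train_ids, , drop = FALSE]
  feats <- cohortSchema(cohort)@names
  Tt <- dim(v)[3]; N <- dim(v)[2]
  w_out <- setNames(rep(1, length(feats)), feats)
  for (f in seq_along(feats)) {
    last <- rep(NA_real_, N)
    tgt <- prev <- dl <- numeric(0)
    for (t in seq_len(Tt)) {
      obs <- m[f, , t] == 1
      with_prior <- obs & is.finite(last)
      if (t > 1 && any(with_prior)) {
        tgt <- c(tgt, v[f, with_prior, t])
        prev <- c(prev, last[with_prior])
        dl <- c(dl, d[f, with_prior, t])
      }
      last[obs] <- v[f, obs, t]
    }
    if (length(tgt) < 3) next                 # keep default w = 1
    mse <- sapply(w_grid, function(w) {
      g <- exp(-w * dl)
      mean((g * prev + (1 - g) * means[f] - tgt)^2)
    })
    w_out[f] <- w_grid[which.min(mse)]
  }
  w_out
}

#' Decay-weighted imputation of missing observations
#'
#' Observed cells pass through unchanged. A missing cell is replaced by the
#' convex combination \code{gamma * last_observed + (1 - gamma) * train_mean}
#' where \code{gamma = computeDecay(delta, w, b)} is evaluated at the cell's
#' time-since-last-observation; with no prior observation the training mean
#' is used. The mask is returned unchanged — imputed cells keep mask 0 so
#' the recurrent module knows which inputs were directly observed.
#'
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param means per-feature training means (see \code{\link{trainMeans}};
#'   computed from the training split only).
#' @param w,b input-level decay parameters (default fixed w=1, b=0).
#' @param method \code{"decay"} (default) or \code{"mean"} (plain
#'   training-mean fill, the mean-imputation baseline).
#' @return list: \code{values} completed array (no NA), \code{mask}
#'   passthrough.
#' @export
imputeCohort <- function(cohort, means, w = 1, b = 0, method = c("decay", "mean")) {
  method <- match.arg(method)
  v <- cohortValues(cohort); m <- cohortMask(cohort)
  d <- cohortDelta(cohort)
  B <- dim(v)[1]; N <- dim(v)[2]; Tt <- dim(v)[3]
  stopifnot(length(means) == B)
  out <- v
  if (method == "mean") {
    fill <- array(rep(means, N * Tt), dim(v))
    out[m == 0] <- fill[m == 0]
    return(list(values = out, mask = m))
  }
  last <- matrix(NA_real_, B, N)   # no prior observation before baseline
  for (t in seq_len(Tt)) {
    vt <- v[, , t]; mt <- m[, , t]
    gam <- computeDecay(d[, , t], w, b)
    hasprior <- is.finite(last)
    imp <- ifelse(hasprior, gam * last + (1 - gam) * means, means)
    filled <- ifelse(mt == 1, vt, imp)
    out[, , t] <- filled
    last <- ifelse(mt == 1, vt, last)
  }
  dimnames(out) <- dimnames(v)
  list(values = out, mask = m)
}
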