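#' Default simulation configuration
#'
#' Parameters of the synthetic amyloid-stratified aMCI cohort generator.
#' Baseline means/sds, APOE carrier probabilities, demographics and Centiloid
#' distributions follow the published baseline characteristics of the two
#' amyloid groups; annual decline slopes and the latent-severity loadings are
#' the package's own choices of clinically plausible magnitudes (steeper
#' decline in the amyloid-positive group for every progressing feature,
#' CDR-SB increasing while all other scores and MRI markers decrease).
#'
#' The generative model per subject i, feature f, visit time t (years):
#' \deqn{x_{ift} = \mu_{gf} + b_{if} + \beta_{gf} t + \lambda_f s_i + \epsilon_{ift}}
#' with group g, subject-level baseline deviation b ~ N(0, sd_gf^2), latent
#' severity s_i ~ N(0,1), loading \eqn{\lambda_f}, and observation noise
#' \eqn{\epsilon} ~ N(0, (noise_scale * sd_f)^2). APOE and Centiloid are
#' static subject-level features; demographics follow the cohort table.
#'
#' @param n_subjects subjects per group (default 200).
#' @param T number of annual visits (default 4).
#' @param p_miss intermittent missing-cell probability at non-baseline visits
#'   (default 0.2).
#' @param p_drop per-visit dropout hazard from visit 2 on (default 0; once
#'   dropped, all later visits are missing).
#' @param noise_scale observation noise sd as a fraction of the feature's
#'   baseline sd (default 0.25).
#' @param severity_loading latent-severity loading as a fraction of the
#'   feature's baseline sd (default 0.3).
#' @return named list with per-feature parameter tables.
#' @export
defaultSimulationConfig <- function(n_subjects = 200, T = 4, p_miss = 0.2,
                                    p_drop = 0, noise_scale = 0.25,
                                    severity_loading = 0.3) {
  # feature, mean_neg, mean_pos, sd_neg, sd_pos, slope_neg, slope_pos, direction
  tab <- rbind(
    cingulate       = c(2.90, 2.85, 0.15, 0.15, -0.012, -0.035, -1),
    frontal         = c(2.85, 2.80, 0.15, 0.15, -0.012, -0.035, -1),
    parietal        = c(2.75, 2.70, 0.15, 0.15, -0.012, -0.035, -1),
    temporal        = c(3.00, 2.92, 0.15, 0.15, -0.015, -0.045, -1),
    occipital       = c(2.60, 2.57, 0.15, 0.15, -0.010, -0.030, -1),
    hippocampus_icv = c(4.4e-3, 4.1e-3, 4e-4, 4e-4, -4e-5, -1.2e-4, -1),
    dsf             = c(5.9,  5.9,  1.4,  1.4,  -0.05, -0.15, -1),
    kbnt            = c(43.2, 42.3, 9.3,  9.4,  -0.5,  -1.5,  -1),
    rcft_copy       = c(30.8, 29.1, 5.7,  7.5,  -0.4,  -1.2,  -1),
    svlt_delayed    = c(3.4,  1.6,  2.5,  2.1,  -0.15, -0.40, -1),
    rcft_delayed    = c(9.0,  4.7,  6.1,  4.3,  -0.35, -0.95, -1),
    cowat           = c(22.2, 22.7, 10.0, 12.0, -0.5,  -1.3,  -1),
    stroop_color    = c(72.5, 63.2, 26.4, 28.4, -2.0,  -5.0,  -1),
    kmmse           = c(26.8, 25.1, 2.4,  3.3,  -0.30, -0.90, -1),
    cdrsb           = c(1.3,  1.9,  0.9,  1.2,   0.25,  0.70, +1),
    centiloid       = c(7.5,  90.9, 18.8, 31.1,  0,     0,     0))
  colnames(tab) <- c("mean_neg", "mean_pos", "sd_neg", "sd_pos",
                     "slope_neg", "slope_pos", "direction")
  stopifnot(n_subjects >= 0, T >= 2, p_miss >= 0, p_miss < 1,
            p_drop >= 0, p_drop <= 1, noise_scale >= 0)
  list(n_subjects = n_subjects, T = T, p_miss = p_miss, p_drop = p_drop,
       noise_scale = noise_scale, severity_loading = severity_loading,
       features = tab,
       apoe_prob = c(abeta_neg = 0.17, abeta_pos = 0.646),
       female_prob = c(abeta_neg = 0.506, abeta_pos = 0.609),
       age_mean = c(abeta_neg = 71.0, abeta_pos = 72.0),
       age_sd = c(abeta_neg = 8.3, abeta_pos = 8.2),
       edu_mean = c(abeta_neg = 12.4, abeta_pos = 11.8),
       edu_sd = c(abeta_neg = 4.5, abeta_pos = 4.4))
}

#' Simulate a complete (ground-truth) cohort
#'
#' Generates noiseless-of-missingness trajectories for both amyloid groups
#' under the linear mixed model of \code{\link{defaultSimulationConfig}}.
#'
#' @param config a simulation configuration list.
#' @param seed integer RNG seed; runs are bit-reproducible under a fixed seed.
#' @return list with elements \code{cohort} (complete
#'   \linkS4class{LongitudinalCohort}, mask all 1), \code{severity}
#'   (per-subject latent severity), \code{slopes} (per-feature, per-group
#'   slopes used).
#' @export
simulateCohort <- function(config = defaultSimulationConfig(), seed = 1) {
  if (config$n_subjects < 2)
    stop("config error: need at least 2 subjects per group")
  set.seed(seed)
  schema <- defaultFeatureSchema()
  tab <- config$features
  N <- 2 * config$n_subjects; Tt <- config$T
  groups <- rep(c("abeta_neg", "abeta_pos"), each = config$n_subjects)
  B <- length(schema@names)
  values <- array(NA_real_, c(B, N, Tt),
                  dimnames = list(schema@names,
                                  sprintf("S%04d", seq_len(N)), NULL))
  severity <- stats::rnorm(N)
  times <- seq_len(Tt) - 1
  pooled_sd <- (tab[, "sd_neg"] + tab[, "sd_pos"]) / 2
  for (i in seq_len(N)) {
    g <- if (groups[i] == "abeta_neg") "neg" else "pos"
    mu <- tab[, paste0("mean_", g)]
    sdv <- tab[, paste0("sd_", g)]
    slope <- tab[, paste0("slope_", g)]
    lam <- config$severity_loading * pooled_sd * tab[, "direction"]
    base_dev <- stats::rnorm(nrow(tab), 0, sdv)
    for (f in rownames(tab)) {
      if (f == "centiloid") {
        values[f, i, ] <- mu[f] + base_dev[match(f, rownames(tab))]
      } else {
        noise <- stats::rnorm(Tt, 0, config$noise_scale * pooled_sd[f])
        values[f, i, ] <- mu[f] + base_dev[match(f, rownames(tab))] +
          slope[f] * times + lam[f] * severity[i] + noise
      }
    }
    values["apoe4", i, ] <- stats::rbinom(1, 1, config$apoe_prob[groups[i]])
    values["age", i, ] <- stats::rnorm(1, config$age_mean[groups[i]],
                                       config$age_sd[groups[i]]) + times
    values["education", i, ] <- max(0, stats::rnorm(
      1, config$edu_mean[groups[i]], config$edu_sd[groups[i]]))
    values["gender", i, ] <- stats::rbinom(1, 1,
                                           config$female_prob[groups[i]])
  }
  vt <- matrix(rep(times, each = N), N, Tt)
  cohort <- makeCohort(values, array(1, dim(values)), vt, groups, schema)
  list(cohort = cohort, severity = severity,
       slopes = tab[, c("slope_neg", "slope_pos")])
}

#' Overlay missingness on a complete cohort
#'
#' Two mechanisms, both missing-completely-at-random: intermittent cell-level
#' masking at rate \code{p_miss} (visits 2..T), and monotone dropout with
#' per-visit hazard \code{p_drop} (once a subject drops out, all later visits
#' are missing entirely). The baseline visit is never masked.
#'
#' @param cohort a complete \linkS4class{LongitudinalCohort}.
#' @param p_miss,p_drop probabilities in [0,1).
#' @param seed integer RNG seed.
#' @return a \linkS4class{LongitudinalCohort} with unobserved cells set to
#'   \code{NA} and mask/delta rebuilt.
#' @export
applyMissingness <- function(cohort, p_miss = 0.2, p_drop = 0, seed = 1) {
  stopifnot(p_miss >= 0, p_miss <= 1, p_drop >= 0, p_drop <= 1)
  set.seed(seed)
  v <- cohortValues(cohort)
  B <- dim(v)[1]; N <- dim(v)[2]; Tt <- dim(v)[3]
  # demographics are duplicated from baseline and always known
  maskable <- match(attendedFeatures(cohortSchema(cohort)),
                    cohortSchema(cohort)@names)
  mask <- array(1, dim(v))
  for (i in seq_len(N)) {
    dropped <- FALSE
    for (t in seq_len(Tt)[-1]) {
      if (!dropped && stats::runif(1) < p_drop) dropped <- TRUE
      if (dropped) {
        mask[maskable, i, t] <- 0
      } else {
        mask[maskable, i, t] <-
          as.numeric(stats::runif(length(maskable)) >= p_miss)
      }
    }
  }
  v[mask == 0] <- NA_real_
  makeCohort(v, mask, visitTimes(cohort), abetaGroup(cohort),
             cohortSchema(cohort))
}

#' Simulate an observed cohort in one call
#'
#' Convenience wrapper: \code{\link{simulateCohort}} then
#' \code{\link{applyMissingness}} with stage-derived seeds.
#'
#' @inheritParams simulateCohort
#' @return list with \code{observed} (masked cohort), \code{complete}
#'   (ground truth), \code{severity}, \code{slopes}.
#' @export
simulateObservedCohort <- function(config = defaultSimulationConfig(),
                                   seed = 1) {
  truth <- simulateCohort(config, seed = seed)
  obs <- applyMissingness(truth$cohort, config$p_miss, config$p_drop,
                          seed = seed + 104729L)
  list(observed = obs, complete = truth$cohort,
       severity = truth$severity, slopes = truth$slopes)
}
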