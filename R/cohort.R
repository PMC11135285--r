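#' Default feature schema
#'
#' The 17-feature attended panel (6 MRI markers, 9 cognitive scores, APOE e4
#' carrier status, global Centiloid) plus 3 demographic features.
#' MRI markers are mean regional cortical thicknesses (mm) and hippocampal
#' volume normalized by intracranial volume; cognitive scores are the SNSB-II
#' numeric tests plus K-MMSE and CDR-SB.
#'
#' @return a \linkS4class{FeatureSchema}.
#' @export
defaultFeatureSchema <- function() {
  new("FeatureSchema",
    names = c("cingulate", "frontal", "parietal", "temporal", "occipital",
              "hippocampus_icv",
              "dsf", "kbnt", "rcft_copy", "svlt_delayed", "rcft_delayed",
              "cowat", "stroop_color", "kmmse", "cdrsb",
              "apoe4", "centiloid", "age", "education", "gender"),
    roles = c(rep("mri", 6), rep("cognitive", 9), "apoe", "centiloid",
              "demographic_age", "demographic_edu", "demographic_gender"),
    units = c(rep("mm", 5), "ratio",
              rep("score", 9), "carrier(0/1)", "CL", "years", "years",
              "female(0/1)"))
}

#' @rdname featureSchema-accessors
#' @param schema a \linkS4class{FeatureSchema}.
#' @param role role tag to select.
#' @return \code{schemaFeatures} returns the feature names with the given
#'   role(s); \code{attendedFeatures} the MRI + cognitive + APOE + Centiloid
#'   block (the attention input); \code{demographicFeatures} the rest.
#' @export
schemaFeatures <- function(schema, role) schema@names[schema@roles %in% role]

#' @rdname featureSchema-accessors
#' @export
attendedFeatures <- function(schema)
  schemaFeatures(schema, c("mri", "cognitive", "apoe", "centiloid"))

#' Accessors for schema feature blocks
#' @name featureSchema-accessors
#' @export
demographicFeatures <- function(schema)
  schemaFeatures(schema, c("demographic_age", "demographic_edu",
                           "demographic_gender"))

#' Construct a LongitudinalCohort from aligned arrays
#'
#' @param values numeric array features x subjects x visits; \code{NA} marks
#'   unobserved cells.
#' @param mask binary array of the same shape (defaults to
#'   \code{!is.na(values)}).
#' @param visit_times numeric matrix subjects x visits of offsets in years
#'   from baseline (default annual visits).
#' @param labels character vector of per-subject amyloid groups
#'   (\code{"abeta_neg"}/\code{"abeta_pos"}).
#' @param schema a \linkS4class{FeatureSchema}.
#' @return a \linkS4class{LongitudinalCohort} with the delta assay derived
#'   from mask and visit times via \code{\link{buildDelta}}.
#' @export
makeCohort <- function(values, mask = NULL, visit_times = NULL, labels,
                       schema = defaultFeatureSchema()) {
  stopifnot(length(dim(values)) == 3)
  B <- dim(values)[1]; N <- dim(values)[2]; T <- dim(values)[3]
  if (is.null(mask)) mask <- array(as.numeric(is.finite(values)), dim(values))
  if (is.null(visit_times))
    visit_times <- matrix(rep(seq_len(T) - 1, each = N), N, T)
  subj <- dimnames(values)[[2]]
  if (is.null(subj)) subj <- sprintf("S%04d", seq_len(N))
  delta <- buildDelta(mask, visit_times)
  rownames(visit_times) <- subj
  dn <- list(schema@names, subj, NULL)
  dimnames(values) <- dimnames(mask) <- dimnames(delta) <- dn
  cd <- S4Vectors::DataFrame(label = labels, row.names = subj)
  cd$visitTimes <- visit_times
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values, mask = mask, delta = delta),
    colData = cd)
  rownames(se) <- schema@names
  new("LongitudinalCohort", se, schema = schema)
}

#' Time-delay tensor from the observation mask
#'
#' For every feature and subject, the delay at the baseline visit is 0; at a
#' later visit it is the gap to the previous visit if the feature was
#' observed there, otherwise the gap plus the previous delay — i.e. the time
#' elapsed since the feature was last directly observed.
#'
#' @param mask binary array features x subjects x visits.
#' @param visit_times numeric matrix subjects x visits, nondecreasing per row.
#' @return numeric array of the same shape as \code{mask}.
#' @export
buildDelta <- function(mask, visit_times) {
  stopifnot(length(dim(mask)) == 3)
  B <- dim(mask)[1]; N <- dim(mask)[2]; T <- dim(mask)[3]
  stopifnot(nrow(visit_times) == N, ncol(visit_times) == T)
  gaps <- visit_times[, -1, drop = FALSE] - visit_times[, -T, drop = FALSE]
  if (any(gaps < 0)) stop("visit times must be nondecreasing per subject")
  delta <- array(0, dim(mask))
  for (t in seq_len(T)[-1]) {
    g <- matrix(rep(gaps[, t - 1], each = B), B, N)
    carry <- delta[, , t - 1] * (1 - mask[, , t - 1])
    delta[, , t] <- g + carry
  }
  delta
}

#' Accessors for LongitudinalCohort
#'
#' @param x a \linkS4class{LongitudinalCohort}.
#' @return \code{cohortValues}, \code{cohortMask}, \code{cohortDelta}: the
#'   corresponding features x subjects x visits array; \code{visitTimes}: the
#'   subjects x visits offset matrix; \code{abetaGroup}: per-subject labels;
#'   \code{cohortSchema}: the \linkS4class{FeatureSchema}.
#' @name cohort-accessors
#' @export
cohortValues <- function(x) SummarizedExperiment::assay(x, "values")

#' @rdname cohort-accessors
#' @export
cohortMask <- function(x) SummarizedExperiment::assay(x, "mask")

#' @rdname cohort-accessors
#' @export
cohortDelta <- function(x) SummarizedExperiment::assay(x, "delta")

#' @rdname cohort-accessors
#' @export
visitTimes <- function(x) SummarizedExperiment::colData(x)$visitTimes

#' @rdname cohort-accessors
#' @export
abetaGroup <- function(x) {
  g <- SummarizedExperiment::colData(x)$label
  names(g) <- colnames(x)
  g
}

#' @rdname cohort-accessors
#' @export
cohortSchema <- function(x) x@schema

#' Subset a cohort to a set of subjects
#' @param x a \linkS4class{LongitudinalCohort}.
#' @param subjects character or integer subject index.
#' @return a \linkS4class{LongitudinalCohort}.
#' @export
subsetSubjects <- function(x, subjects) {
  makeCohort(cohortValues(x)[, subjects, , drop = FALSE],
             cohortMask(x)[, subjects, , drop = FALSE],
             visitTimes(x)[subjects, , drop = FALSE],
             abetaGroup(x)[subjects],
             cohortSchema(x))
}

#' Read a long-format cohort CSV
#'
#' Expects one row per subject-visit with columns \code{subject_id},
#' \code{visit_year}, \code{label}, and one column per schema feature. Blank
#' cells become mask=0. Demographic values other than age are replicated
#' forward from baseline across visits; age is incremented by the visit
#' offset. Every subject must have a baseline (visit_year 0) row with all
#' demographics observed.
#'
#' @param path CSV file path.
#' @param schema a \linkS4class{FeatureSchema}.
#' @return a \linkS4class{LongitudinalCohort}.
#' @export
loadCohort <- function(path, schema = defaultFeatureSchema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "visit_year", "label", schema@names)
  unknown <- setdiff(colnames(df), required)
  if (length(unknown))
    stop("schema error: unknown column(s): ", paste(unknown, collapse = ", "))
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df[c("subject_id", "visit_year")]))
    stop("integrity error: duplicate (subject, visit) rows")
  if (any(df$visit_year < 0)) stop("integrity error: negative visit_year")
  df <- df[order(df$subject_id, df$visit_year), ]
  subj <- unique(df$subject_id)
  N <- length(subj)
  T <- max(table(df$subject_id))
  T <- max(T, 2L)
  B <- length(schema@names)
  values <- array(NA_real_, c(B, N, T))
  obs <- array(0, c(B, N, T))
  vt <- matrix(NA_real_, N, T)
  labels <- character(N)
  dem <- demographicFeatures(schema)
  age_f <- schemaFeatures(schema, "demographic_age")
  for (i in seq_len(N)) {
    rows <- df[df$subject_id == subj[i], , drop = FALSE]
    if (rows$visit_year[1] != 0)
      stop("integrity error: subject ", subj[i], " has no baseline visit")
    labels[i] <- rows$label[1]
    nv <- nrow(rows)
    vt[i, seq_len(nv)] <- rows$visit_year
    if (nv < T) vt[i, (nv + 1):T] <- rows$visit_year[nv] + seq_len(T - nv)
    for (f in seq_len(B)) {
      v <- as.numeric(rows[[schema@names[f]]])
      values[f, i, seq_len(nv)] <- v
      obs[f, i, seq_len(nv)] <- as.numeric(is.finite(v))
    }
    # demographics: duplicated across visits from baseline, age advances
    for (d in dem) {
      f <- match(d, schema@names)
      base <- values[f, i, 1]
      if (!is.finite(base))
        stop("integrity error: subject ", subj[i],
             " missing baseline demographic '", d, "'")
      if (d == age_f) values[f, i, ] <- base + vt[i, ]
      else values[f, i, ] <- base
      obs[f, i, ] <- 1
    }
  }
  dimnames(values) <- list(schema@names, subj, NULL)
  makeCohort(values, obs, vt, labels, schema)
}

#' Write a cohort to a long-format CSV
#'
#' Inverse of \code{\link{loadCohort}} up to row order and float formatting;
#' unobserved cells are written blank.
#'
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param path output CSV path.
#' @return invisibly, the written data.frame.
#' @export
writeCohort <- function(cohort, path) {
  v <- cohortValues(cohort); m <- cohortMask(cohort)
  vt <- visitTimes(cohort); lab <- abetaGroup(cohort)
  subj <- colnames(cohort)
  B <- dim(v)[1]; N <- dim(v)[2]; T <- dim(v)[3]
  out <- do.call(rbind, lapply(seq_len(N), function(i) {
    block <- t(v[, i, , drop = TRUE])
    block[t(m[, i, ]) == 0] <- NA
    data.frame(subject_id = subj[i], visit_year = vt[i, ],
               label = unname(lab[i]), block, check.names = FALSE)
  }))
  colnames(out) <- c("subject_id", "visit_year", "label",
                     cohortSchema(cohort)@names)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(out)
}

#' Fit a per-feature min-max normalizer on the training split
#'
#' Statistics come from observed training cells only, so validation/test
#' values never leak into the scaling. Out-of-range values in other splits
#' simply map outside [0,1].
#'
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param train_ids subject names (or indices) of the training split.
#' @return a \linkS4class{NormalizationState}.
#' @export
fitNormalizer <- function(cohort, train_ids) {
  if (!length(train_ids)) stop("training subset is empty")
  v <- cohortValues(cohort)[, train_ids, , drop = FALSE]
  m <- cohortMask(cohort)[, train_ids, , drop = FALSE]
  feats <- cohortSchema(cohort)@names
  mins <- maxs <- setNames(numeric(length(feats)), feats)
  for (f in seq_along(feats)) {
    obs <- v[f, , ][m[f, , ] == 1]
    if (length(unique(obs)) < 2)
      stop("degenerate feature '", feats[f],
           "': fewer than 2 distinct observed training values")
    mins[f] <- min(obs); maxs[f] <- max(obs)
  }
  new("NormalizationState", minimum = mins, maximum = maxs, method = "minmax")
}

#' Apply / invert min-max normalization
#'
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param state a \linkS4class{NormalizationState}.
#' @return \code{applyNormalizer}: the cohort with values mapped to the
#'   training [0,1] scale; \code{invertNormalizer}: back to native units.
#' @export
applyNormalizer <- function(cohort, state) {
  v <- cohortValues(cohort)
  rng <- state@maximum - state@minimum
  v <- (v - state@minimum) / rng   # arrays recycle over dim 1 = features
  makeCohort(v, cohortMask(cohort), visitTimes(cohort), abetaGroup(cohort),
             cohortSchema(cohort))
}

#' @rdname applyNormalizer
#' @export
invertNormalizer <- function(cohort, state) {
  v <- cohortValues(cohort)
  v <- v * (state@maximum - state@minimum) + state@minimum
  makeCohort(v, cohortMask(cohort), visitTimes(cohort), abetaGroup(cohort),
             cohortSchema(cohort))
}

#' Normalize / denormalize a plain array on a fitted state
#' @param x numeric array with features on dimension 1.
#' @param state a \linkS4class{NormalizationState}.
#' @param features optional feature subset (names) giving the rows of x.
#' @return array of the same shape.
#' @export
normalizeArray <- function(x, state, features = names(state@minimum)) {
  mn <- state@minimum[features]; rng <- state@maximum[features] - mn
  (x - mn) / rng
}

#' @rdname normalizeArray
#' @export
denormalizeArray <- function(x, state, features = names(state@minimum)) {
  mn <- state@minimum[features]; rng <- state@maximum[features] - mn
  x * rng + mn
}

#' Serialize / restore a normalization state
#' @param state a \linkS4class{NormalizationState}.
#' @param path JSON file path.
#' @export
writeNormalizer <- function(state, path) {
  jsonlite::write_json(
    list(method = state@method,
         features = names(state@minimum),
         minimum = unname(state@minimum),
         maximum = unname(state@maximum)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNormalizer
#' @export
readNormalizer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("NormalizationState",
      minimum = setNames(x$minimum, x$features),
      maximum = setNames(x$maximum, x$features),
      method = x$method)
}
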