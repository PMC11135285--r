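#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats rnorm rbinom runif sd cor quantile predict pnorm setNames
#' @importFrom utils read.csv write.csv head tail
NULL

#' Feature schema for a longitudinal cohort
#'
#' Describes the per-visit feature panel: which columns are MRI markers,
#' cognitive test scores, APOE carrier status, global Centiloid, and
#' demographics. The model contract requires exactly 6 MRI and 9 cognitive
#' features; the attention module operates on the MRI + cognitive + APOE +
#' Centiloid block, demographics bypass attention.
#'
#' @slot names character, unique feature identifiers (column names in files).
#' @slot roles character, one of \code{mri}, \code{cognitive}, \code{apoe},
#'   \code{centiloid}, \code{demographic_age}, \code{demographic_edu},
#'   \code{demographic_gender}, parallel to \code{names}.
#' @slot units character, free-text unit per feature.
#' @export
setClass("FeatureSchema",
  representation(names = "character", roles = "character", units = "character"))

setValidity("FeatureSchema", function(object) {
  msg <- character()
  ok_roles <- c("mri", "cognitive", "apoe", "centiloid",
                "demographic_age", "demographic_edu", "demographic_gender")
  if (anyDuplicated(object@names)) msg <- c(msg, "feature names must be unique")
  if (length(object@roles) != length(object@names) ||
      length(object@units) != length(object@names))
    msg <- c(msg, "names, roles, units must have equal length")
  if (!all(object@roles %in% ok_roles))
    msg <- c(msg, paste("unknown role(s):",
                        paste(setdiff(object@roles, ok_roles), collapse = ", ")))
  if (sum(object@roles == "mri") != 6) msg <- c(msg, "exactly 6 features must be tagged 'mri'")
  if (sum(object@roles == "cognitive") != 9) msg <- c(msg, "exactly 9 features must be tagged 'cognitive'")
  if (length(msg)) msg else TRUE
})

#' Longitudinal cohort container
#'
#' Extends \linkS4class{SummarizedExperiment} with three-dimensional assays of
#' shape features x subjects x visits:
#' \describe{
#'   \item{values}{observed measurements; unobserved cells hold \code{NA}
#'     (code must consult the mask, never the sentinel)}
#'   \item{mask}{1 where the cell was directly observed, 0 otherwise}
#'   \item{delta}{years since the feature was last observed (0 at baseline)}
#' }
#' \code{colData} carries the per-subject amyloid group label
#' (\code{abeta_neg}/\code{abeta_pos}) and a matrix column \code{visitTimes}
#' of visit offsets in years from baseline. Visits are indexed 1..T.
#'
#' @slot schema a \linkS4class{FeatureSchema}.
#' @export
setClass("LongitudinalCohort",
  contains = "SummarizedExperiment",
  representation(schema = "FeatureSchema"))

setValidity("LongitudinalCohort", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("values", "mask", "delta") %in% an))
    return("assays 'values', 'mask', 'delta' are required")
  v <- SummarizedExperiment::assay(object, "values")
  m <- SummarizedExperiment::assay(object, "mask")
  d <- SummarizedExperiment::assay(object, "delta")
  if (length(dim(v)) != 3) return("assays must be 3-dimensional (features x subjects x visits)")
  if (!identical(dim(v), dim(m)) || !identical(dim(v), dim(d)))
    msg <- c(msg, "assay dimensions must agree")
  if (dim(v)[3] < 2) msg <- c(msg, "at least 2 visits are required")
  if (!identical(rownames(object), object@schema@names))
    msg <- c(msg, "rownames must equal schema feature names")
  if (!all(m %in% c(0, 1))) msg <- c(msg, "mask must be binary")
  if (any(m == 1 & !is.finite(v)))
    msg <- c(msg, "mask=1 cells must hold finite values")
  if (any(d < 0, na.rm = TRUE)) msg <- c(msg, "delta must be nonnegative")
  if (any(d[, , 1] != 0)) msg <- c(msg, "delta at the baseline visit must be 0")
  cd <- SummarizedExperiment::colData(object)
  if (!"label" %in% colnames(cd)) msg <- c(msg, "colData needs a 'label' column")
  else if (!all(cd$label %in% c("abeta_neg", "abeta_pos")))
    msg <- c(msg, "labels must be 'abeta_neg' or 'abeta_pos'")
  if (!"visitTimes" %in% colnames(cd)) msg <- c(msg, "colData needs a 'visitTimes' matrix column")
  if (length(msg)) msg else TRUE
})

#' Min-max normalization state
#'
#' Per-feature minimum and maximum fitted on observed training-split cells
#' only; applying then inverting recovers the input to numerical precision.
#'
#' @slot minimum,maximum named numeric vectors, one entry per feature.
#' @slot method normalization tag, always \code{"minmax"}.
#' @export
setClass("NormalizationState",
  representation(minimum = "numeric", maximum = "numeric", method = "character"))

setValidity("NormalizationState", function(object) {
  if (any(object@maximum < object@minimum)) "max must be >= min per feature" else TRUE
})

#' Trained trajectory model
#'
#' Wraps the parameter blocks of the three network modules — attention
#' feature fusion (query/key/value projections + feed-forward refinement),
#' the decay/mask-modified GRU, and the two linear prediction heads — plus
#' the decay parameters, the dimension record, and the normalization state
#' used at training time.
#'
#' @slot params named list of numeric matrices/vectors (see
#'   \code{\link{initModelParams}}).
#' @slot dims named list: \code{B} attended features, \code{D} demographics,
#'   \code{H} hidden units, \code{n_mri}, \code{n_cog}, \code{ffn_depth}.
#' @slot config named list of model options (\code{use_attention},
#'   \code{use_decay}, \code{imputation} method).
#' @slot normalizer the \linkS4class{NormalizationState} fitted on the
#'   training split (or NULL-prototype when unset).
#' @slot history data.frame of per-epoch train/validation losses.
#' @export
setClass("TrajectoryModel",
  representation(params = "list", dims = "list", config = "list",
                 normalizer = "ANY", history = "data.frame"))

setMethod("show", "FeatureSchema", function(object) {
  cat("FeatureSchema with", length(object@names), "features\n")
  for (r in unique(object@roles))
    cat(sprintf("  %-18s %s\n", r,
                paste(object@names[object@roles == r], collapse = ", ")))
})

setMethod("show", "LongitudinalCohort", function(object) {
  d <- dim(SummarizedExperiment::assay(object, "values"))
  lab <- table(SummarizedExperiment::colData(object)$label)
  cat(sprintf("LongitudinalCohort: %d features x %d subjects x %d visits\n",
              d[1], d[2], d[3]))
  cat("  groups:", paste(sprintf("%s=%d", names(lab), lab), collapse = ", "), "\n")
  m <- SummarizedExperiment::assay(object, "mask")
  cat(sprintf("  observed cells: %.1f%%\n", 100 * mean(m)))
})

setMethod("show", "TrajectoryModel", function(object) {
  cat(sprintf("TrajectoryModel (B=%d attended + %d demographic, H=%d)\n",
              object@dims$B, object@dims$D, object@dims$H))
  cat(sprintf("  attention: %s, temporal decay: %s, imputation: %s\n",
              object@config$use_attention, object@config$use_decay,
              object@config$imputation))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs, best val loss %.5g\n",
                nrow(object@history), min(object@history$val_loss)))
})
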