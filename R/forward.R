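# Assemble normalized, imputed network inputs and targets from a cohort.
# Normalization and imputation means must come from the training split.
.assembleInputs <- function(cohort, normalizer, means_norm, config) {
  schema <- cohortSchema(cohort)
  att <- attendedFeatures(schema)
  dem <- demographicFeatures(schema)
  mri <- schemaFeatures(schema, "mri")
  cog <- schemaFeatures(schema, "cognitive")
  ncoh <- applyNormalizer(cohort, normalizer)
  imp <- imputeCohort(ncoh, means_norm, w = config$impute_w %||% 1,
                      method = config$imputation)
  v <- cohortValues(ncoh); m <- cohortMask(ncoh); d <- cohortDelta(ncoh)
  Tt <- dim(v)[3]; S <- dim(v)[2]
  Xatt <- imp$values[att, , , drop = FALSE]
  Dem <- v[dem, , , drop = FALSE]
  Mask <- abind3(m[att, , , drop = FALSE],
                 array(1, c(length(dem), S, Tt)))
  Delta <- d[att, , , drop = FALSE]
  list(Xatt = Xatt, Dem = Dem, Mask = Mask, Delta = Delta,
       target_m = v[mri, , -1, drop = FALSE] |> naTo0(),
       target_m_mask = m[mri, , -1, drop = FALSE],
       target_c = v[cog, , -1, drop = FALSE] |> naTo0(),
       target_c_mask = m[cog, , -1, drop = FALSE],
       features = list(att = att, dem = dem, mri = mri, cog = cog))
}

naTo0 <- function(x) { x[!is.finite(x)] <- 0; x }

# bind two 3D arrays along dim 1
abind3 <- function(a, b) {
  stopifnot(dim(a)[2] == dim(b)[2], dim(a)[3] == dim(b)[3])
  out <- array(NA_real_, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  na <- dimnames(a)[[1]]; nb <- dimnames(b)[[1]]
  if (length(na) == dim(a)[1] && length(nb) == dim(b)[1])
    dimnames(out) <- list(c(na, nb), dimnames(a)[[2]], NULL)
  out
}

#' Teacher-forced forward pass over a cohort
#'
#' Runs the fusion -> decay-GRU -> heads recurrence over visits 1..T-1, each
#' step consuming the (imputed) observation at t and emitting the prediction
#' for t+1. Inputs are normalized and imputed with the model's stored
#' training-split statistics.
#'
#' @param model a trained \linkS4class{TrajectoryModel}.
#' @param cohort a \linkS4class{LongitudinalCohort} (any subjects).
#' @return list: \code{mhat} (6 x subjects x T-1) and \code{chat}
#'   (9 x subjects x T-1) predictions in normalized space for visits 2..T,
#'   \code{hidden} (H x subjects x T-1), \code{attention}
#'   (B x B x subjects x T-1 or NULL), plus the assembled \code{inputs}.
#' @export
forwardSequence <- function(model, cohort) {
  if (dim(cohortValues(cohort))[3] < 2)
    stop("insufficient history: at least 2 visits required")
  inp <- .assembleInputs(cohort, model@normalizer,
                         model@config$train_means_norm, model@config)
  fw <- .forwardBatch(model@params, inp, model@config, keep_cache = FALSE)
  dimnames(fw$mhat) <- list(inp$features$mri, colnames(cohort), NULL)
  dimnames(fw$chat) <- list(inp$features$cog, colnames(cohort), NULL)
  fw$inputs <- inp
  fw
}

#' Autoregressive rollout beyond the observed history
#'
#' Consumes the subject's observed history up to visit \code{t0} (teacher
#' forced), then feeds each prediction back as the next visit's input with
#' mask 0 (the recurrent module treats model-generated values as imputed).
#' Demographics are carried forward with age incremented by the step length;
#' APOE and Centiloid are carried forward unchanged. Step length is the
#' subject's median observed visit gap (1 year for annual protocols).
#'
#' @param model a trained \linkS4class{TrajectoryModel}.
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param subject subject name or index.
#' @param t0 last observed visit consumed before free-running (default T).
#' @param horizon number of autoregressive steps (>= 1).
#' @return list: \code{m_hat} (6 x horizon), \code{c_hat} (9 x horizon)
#'   normalized-space forecasts, \code{ages} the age input used at each
#'   rollout step (native years).
#' @export
rolloutTrajectory <- function(model, cohort, subject, t0 = NULL, horizon = 1) {
  stopifnot(horizon >= 1)
  sub <- subsetSubjects(cohort, subject)
  Tt <- dim(cohortValues(sub))[3]
  if (is.null(t0)) t0 <- Tt
  stopifnot(t0 >= 2, t0 <= Tt)
  inp <- .assembleInputs(sub, model@normalizer,
                         model@config$train_means_norm, model@config)
  B <- dim(inp$Xatt)[1]; H <- length(model@params$bri)
  att <- inp$features$att
  n_pred <- length(inp$features$mri) + length(inp$features$cog)
  vt <- visitTimes(sub)[1, seq_len(t0)]
  step_len <- if (t0 > 1) stats::median(diff(vt)) else 1
  schema <- cohortSchema(sub)
  age_row <- match(schemaFeatures(schema, "demographic_age"),
                   inp$features$dem)
  # teacher-forced warmup over visits 1..t0
  Hprev <- matrix(0, H, 1)
  out <- NULL
  for (t in seq_len(t0)) {
    step <- .stepOnce(model, inp$Xatt[, 1, t], inp$Dem[, 1, t],
                      inp$Mask[, 1, t], inp$Delta[, 1, t], Hprev)
    Hprev <- step$H
    out <- step
  }
  m_hat <- matrix(NA_real_, length(inp$features$mri), horizon,
                  dimnames = list(inp$features$mri, NULL))
  c_hat <- matrix(NA_real_, length(inp$features$cog), horizon,
                  dimnames = list(inp$features$cog, NULL))
  ages <- numeric(horizon)
  x <- inp$Xatt[, 1, t0]
  dem <- inp$Dem[, 1, t0]
  delta <- inp$Delta[, 1, t0]
  age_state <- model@normalizer
  npred_idx <- seq_len(n_pred)
  for (k in seq_len(horizon)) {
    m_hat[, k] <- out$m_hat
    c_hat[, k] <- out$c_hat
    if (k == horizon) break
    # feed predictions back: predicted features replace inputs with mask 0
    x[npred_idx] <- c(out$m_hat, out$c_hat)
    mask <- c(rep(0, n_pred), rep(1, B - n_pred), rep(1, length(dem)))
    delta <- delta + step_len
    dem[age_row] <- dem[age_row] +
      step_len / (age_state@maximum["age"] - age_state@minimum["age"])
    ages[k + 1] <- denormalizeArray(dem[age_row], age_state, "age")
    out <- .stepOnce(model, x, dem, mask, delta, Hprev)
    Hprev <- out$H
  }
  ages[1] <- denormalizeArray(inp$Dem[age_row, 1, t0], model@normalizer, "age")
  list(m_hat = m_hat, c_hat = c_hat, ages = ages)
}

# single-subject single-step forward using the batch engine
.stepOnce <- function(model, x_att, dem, mask, delta, Hprev) {
  params <- model@params; config <- model@config
  if (config$use_attention) {
    fz <- fuseFeatures(x_att, dem, params)
    fused <- fz$fused
  } else {
    fused <- c(x_att, dem)
  }
  if (config$use_decay) {
    omega <- drop(exp(-pmax(0, model@params$Womega %*% delta +
                                 model@params$bomega)))
  } else {
    omega <- rep(1, length(model@params$bri))
  }
  Hp <- drop(Hprev)
  Ht <- trmStep(Hp, omega, fused, mask, params)
  pr <- predictNext(Ht, params)
  list(H = matrix(Ht, ncol = 1), m_hat = pr$m_hat, c_hat = pr$c_hat)
}

#' Serialize a trained model to JSON
#'
#' Writes all parameter blocks, the dimension record, model options, and the
#' normalization state to a single portable JSON file at full precision; the
#' dimension record is validated on load.
#'
#' @param model a \linkS4class{TrajectoryModel}.
#' @param path output file path.
#' @export
saveModel <- function(model, path) {
  flat <- list()
  for (nm in names(model@params)) {
    x <- model@params[[nm]]
    if (is.list(x)) {
      for (i in seq_along(x))
        flat[[paste0(nm, ".", i)]] <- list(dim = dim(x[[i]]) %||% length(x[[i]]),
                                           data = as.vector(x[[i]]))
    } else {
      flat[[nm]] <- list(dim = dim(x) %||% length(x), data = as.vector(x))
    }
  }
  ser <- list(dims = model@dims,
              config = model@config[setdiff(names(model@config),
                                            "train_means_norm")],
              train_means = list(features = names(model@config$train_means_norm),
                                 values = unname(model@config$train_means_norm)),
              params = flat,
              normalizer = list(features = names(model@normalizer@minimum),
                                minimum = unname(model@normalizer@minimum),
                                maximum = unname(model@normalizer@maximum)))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname saveModel
#' @return \code{loadModel}: the restored \linkS4class{TrajectoryModel}.
#' @export
loadModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- lapply(x$dims, as.integer)
  unflat <- function(entry) {
    d <- unlist(entry$dim)
    v <- as.numeric(unlist(entry$data))
    if (length(d) == 2) matrix(v, d[1], d[2]) else v
  }
  flat <- x$params
  p <- list()
  listparts <- grepl("\\.", names(flat))
  for (nm in names(flat)[!listparts]) p[[nm]] <- unflat(flat[[nm]])
  for (base in unique(sub("\\..*$", "", names(flat)[listparts]))) {
    parts <- sort(names(flat)[startsWith(names(flat), paste0(base, "."))])
    p[[base]] <- lapply(parts, function(nm) unflat(flat[[nm]]))
  }
  p <- p[c("Wq", "Wk", "Wv", "Wf", "bf", "Womega", "bomega",
           "Wri", "Wzi", "Whi", "Wrh", "Wzh", "Whh",
           "bri", "bzi", "bhi", "brh", "bzh", "bhh",
           "Wm", "bm", "Wc", "bc")]
  if (nrow(p$Wq) != dims$B || length(p$bri) != dims$H)
    stop("model file dimension record does not match parameter shapes")
  attr(p, "dims") <- dims
  cfg <- x$config
  if (!is.null(cfg$impute_w)) cfg$impute_w <- unlist(cfg$impute_w)
  cfg$train_means_norm <- setNames(as.numeric(x$train_means$values),
                                   x$train_means$features)
  new("TrajectoryModel", params = p, dims = dims, config = cfg,
      normalizer = new("NormalizationState",
                       minimum = setNames(as.numeric(x$normalizer$minimum),
                                          x$normalizer$features),
                       maximum = setNames(as.numeric(x$normalizer$maximum),
                                          x$normalizer$features),
                       method = "minmax"),
      history = data.frame())
}
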