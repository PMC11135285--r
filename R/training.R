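#' Masked mean squared error
#'
#' Squared error between predictions and true observations, restricted to
#' cells whose target was directly observed (mask = 1), averaged over the
#' count of such cells. Predictions at imputed targets carry no loss.
#'
#' @param pred,truth numeric arrays of identical shape.
#' @param mask binary array of the same shape.
#' @return scalar loss.
#' @export
maskedMSE <- function(pred, truth, mask) {
  stopifnot(identical(dim(pred) %||% length(pred),
                      dim(truth) %||% length(truth)))
  n <- sum(mask)
  if (n == 0) stop("undefined loss: zero observed target cells")
  sum(((pred - truth) * mask)^2) / n
}

#' Composite multi-task loss
#'
#' \code{alpha * L_m + gamma * L_c}: the weighted combination of the MRI
#' marker loss and the cognitive score loss (defaults alpha = 0.75,
#' gamma = 1.0).
#'
#' @param L_m,L_c task losses (>= 0).
#' @param alpha,gamma nonnegative task weights.
#' @return scalar total loss.
#' @export
totalLoss <- function(L_m, L_c, alpha = 0.75, gamma = 1.0) {
  stopifnot(alpha >= 0, gamma >= 0)
  alpha * L_m + gamma * L_c
}

#' Default training configuration
#'
#' Loss weights, optimizer settings, the hyperparameter grids, and the
#' cross-validation protocol (5 folds x 5 repetitions, 10\% validation and
#' 10\% test subjects per class).
#'
#' @param alpha,gamma loss weights (defaults 0.75 and 1.0).
#' @param lr learning rate; \code{l2} decoupled weight-decay strength.
#' @param hidden_units GRU hidden size H (default 48).
#' @param ffn_depth refinement layers in the fusion module (default 1).
#' @param max_epochs,patience early-stopping budget (validation masked MSE).
#' @param batch_size minibatch size in subjects.
#' @param optimizer \code{"adam"} (default) or \code{"sgd"}.
#' @param loss \code{"mse"} (default) or \code{"mae"}.
#' @param use_attention,use_decay,imputation model-variant switches; the
#'   mean-imputation GRU baseline sets all three off/"mean".
#' @param impute_decay \code{"fitted"} (default) calibrates per-feature
#'   input-level decay rates on the training split
#'   (\code{\link{fitImputationDecay}}); \code{"fixed"} pins w = 1, b = 0.
#' @param folds,repetitions,val_frac,test_frac cross-validation protocol.
#' @param lr_grid,depth_grid,units_grid,l2_grid grid-search axes
#'   (4 x 3 x 6 x 4 = 288 combinations).
#' @param seed integer seed controlling initialization and shuffling.
#' @return named list.
#' @export
defaultTrainConfig <- function(alpha = 0.75, gamma = 1.0,
                               lr = 1e-3, l2 = 1e-5,
                               hidden_units = 48, ffn_depth = 1,
                               max_epochs = 300, patience = 20,
                               batch_size = 64, optimizer = "adam",
                               loss = "mse",
                               use_attention = TRUE, use_decay = TRUE,
                               imputation = "decay", impute_decay = "fitted",
                               folds = 5, repetitions = 5,
                               val_frac = 0.10, test_frac = 0.10,
                               lr_grid = c(5e-5, 1e-4, 1e-3, 1e-2),
                               depth_grid = 1:3,
                               units_grid = c(16, 32, 48, 64, 80, 96),
                               l2_grid = c(1e-6, 1e-5, 1e-4, 1e-3),
                               seed = 1) {
  stopifnot(alpha >= 0, gamma >= 0, val_frac + test_frac < 1,
            length(lr_grid) > 0, length(units_grid) > 0)
  as.list(environment())
}

# subject-dimension slice of an assembled input list
.sliceSubjects <- function(inp, idx) {
  out <- inp
  for (nm in c("Xatt", "Dem", "Mask", "Delta",
               "target_m", "target_m_mask", "target_c", "target_c_mask"))
    out[[nm]] <- inp[[nm]][, idx, , drop = FALSE]
  out
}

#' Train the trajectory model
#'
#' End-to-end gradient training of all three modules under the masked
#' composite loss, with minibatch Adam (or plain SGD), decoupled l2 weight
#' decay on the weight matrices, and early stopping on the validation
#' masked MSE. Returns the parameters of the epoch with minimal validation
#' loss. Deterministic under a fixed seed in single-threaded execution.
#'
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param train_ids,val_ids disjoint subject-name vectors.
#' @param config a \code{\link{defaultTrainConfig}} list.
#' @param verbose print per-epoch losses.
#' @return a \linkS4class{TrajectoryModel}.
#' @export
trainModel <- function(cohort, train_ids, val_ids,
                       config = defaultTrainConfig(), verbose = FALSE) {
  if (length(intersect(train_ids, val_ids)))
    stop("train and validation splits overlap")
  schema <- cohortSchema(cohort)
  normalizer <- fitNormalizer(cohort, train_ids)
  ncoh <- applyNormalizer(cohort, normalizer)
  means_norm <- trainMeans(ncoh, train_ids)
  impute_w <- if (config$imputation == "decay" &&
                  identical(config$impute_decay, "fitted"))
    fitImputationDecay(ncoh, train_ids, means_norm)
  else setNames(rep(1, length(means_norm)), names(means_norm))
  mcfg <- list(use_attention = config$use_attention,
               use_decay = config$use_decay,
               imputation = config$imputation,
               impute_w = impute_w,
               loss_type = config$loss,
               alpha = config$alpha, gamma = config$gamma,
               train_means_norm = means_norm)
  B <- length(attendedFeatures(schema)); D <- length(demographicFeatures(schema))
  H <- config$hidden_units
  inp_all <- .assembleInputs(cohort, normalizer, means_norm, mcfg)
  tr_idx <- match(train_ids, colnames(cohort))
  va_idx <- match(val_ids, colnames(cohort))
  inp_tr <- .sliceSubjects(inp_all, tr_idx)
  inp_va <- .sliceSubjects(inp_all, va_idx)
  params <- initModelParams(B = B, D = D, H = H,
                            ffn_depth = config$ffn_depth,
                            seed = stageSeed(config$seed, "init"))
  dims <- attr(params, "dims")
  opt <- .makeOptimizer(params, config)
  best <- list(val = Inf, params = params, epoch = 0L)
  since_best <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  set.seed(stageSeed(config$seed, "shuffle"))
  ntr <- length(tr_idx)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(ntr)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_n <- 0
    for (bidx in batches) {
      lg <- .lossGradBatch(params, .sliceSubjects(inp_tr, bidx), mcfg,
                           config$alpha, config$gamma)
      if (!is.finite(lg$loss))
        stop("divergence: non-finite training loss at epoch ", epoch,
             " (lr=", config$lr, ")")
      # the scalar stepped on is exactly totalLoss(L_m, L_c, alpha, gamma)
      stopifnot(isTRUE(all.equal(lg$loss,
        totalLoss(lg$L_m, lg$L_c, config$alpha, config$gamma))))
      params <- opt$step(params, lg$grad)
      ep_loss <- ep_loss + lg$loss * length(bidx); ep_n <- ep_n + length(bidx)
    }
    vl <- .lossGradBatch(params, inp_va, mcfg, config$alpha, config$gamma,
                         want_grad = FALSE)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / ep_n,
                                   val_loss = vl$loss))
    if (verbose)
      message(sprintf("epoch %3d train %.5f val %.5f", epoch,
                      ep_loss / ep_n, vl$loss))
    if (vl$loss < best$val) {
      best <- list(val = vl$loss, params = params, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best > config$patience) break
    }
  }
  new("TrajectoryModel", params = best$params, dims = dims, config = mcfg,
      normalizer = normalizer, history = hist)
}

# Adam (bias-corrected) or SGD with decoupled l2 weight decay on W matrices.
.makeOptimizer <- function(params, config) {
  zero <- lapply(params, function(x)
    if (is.list(x)) lapply(x, function(y) y * 0) else x * 0)
  m <- zero; v <- zero; t_step <- 0L
  lr <- config$lr; l2 <- config$l2
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  decayed <- function(nm) startsWith(nm, "W")
  step_adam <- function(params, grad) {
    t_step <<- t_step + 1L
    upd <- function(p, g, mm, vv) {
      mm <- b1 * mm + (1 - b1) * g
      vv <- b2 * vv + (1 - b2) * g^2
      mhat <- mm / (1 - b1^t_step); vhat <- vv / (1 - b2^t_step)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = mm, v = vv)
    }
    for (nm in names(params)) {
      if (is.list(params[[nm]])) {
        for (i in seq_along(params[[nm]])) {
          r <- upd(params[[nm]][[i]], grad[[nm]][[i]], m[[nm]][[i]], v[[nm]][[i]])
          params[[nm]][[i]] <- r$p; m[[nm]][[i]] <<- r$m; v[[nm]][[i]] <<- r$v
          if (decayed(nm))
            params[[nm]][[i]] <- params[[nm]][[i]] * (1 - lr * l2)
        }
      } else {
        r <- upd(params[[nm]], grad[[nm]], m[[nm]], v[[nm]])
        params[[nm]] <- r$p; m[[nm]] <<- r$m; v[[nm]] <<- r$v
        if (decayed(nm)) params[[nm]] <- params[[nm]] * (1 - lr * l2)
      }
    }
    params
  }
  step_sgd <- function(params, grad) {
    for (nm in names(params)) {
      if (is.list(params[[nm]])) {
        for (i in seq_along(params[[nm]])) {
          params[[nm]][[i]] <- params[[nm]][[i]] - lr * grad[[nm]][[i]]
          if (decayed(nm))
            params[[nm]][[i]] <- params[[nm]][[i]] * (1 - lr * l2)
        }
      } else {
        params[[nm]] <- params[[nm]] - lr * grad[[nm]]
        if (decayed(nm)) params[[nm]] <- params[[nm]] * (1 - lr * l2)
      }
    }
    params
  }
  list(step = if (config$optimizer == "adam") step_adam else step_sgd)
}

#' Mean-imputation GRU baseline
#'
#' The ablation reference: missing observations are filled with training
#' means, the attention module is bypassed (raw concatenated features +
#' demographics), the temporal decay is disabled (omega = 1), and the mask
#' vector is still appended for input-width parity. Training protocol is
#' otherwise identical, so performance differences are attributable to the
#' attention fusion and decay mechanisms.
#'
#' @inheritParams trainModel
#' @return a \linkS4class{TrajectoryModel}.
#' @export
gruMBaseline <- function(cohort, train_ids, val_ids,
                         config = defaultTrainConfig(), verbose = FALSE) {
  config$use_attention <- FALSE
  config$use_decay <- FALSE
  config$imputation <- "mean"
  trainModel(cohort, train_ids, val_ids, config, verbose)
}

# class-stratified chunk assignment: shuffle each class, deal into n_chunks
.stratifiedChunks <- function(labels, n_chunks, seed) {
  set.seed(seed)
  chunk <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- sample(idx)
    chunk[idx] <- rep(seq_len(n_chunks), length.out = length(idx))
  }
  chunk
}

#' Class-stratified train/validation/test split
#'
#' @param labels per-subject class labels.
#' @param val_frac,test_frac fractions per class.
#' @param seed integer seed.
#' @return list of integer index vectors \code{train}, \code{val},
#'   \code{test}; realized fractions are within one subject per class.
#' @export
stratifiedSplit <- function(labels, val_frac = 0.1, test_frac = 0.1,
                            seed = 1) {
  set.seed(seed)
  test <- val <- integer()
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    nt <- round(test_frac * n); nv <- round(val_frac * n)
    if (n - nt - nv < 1) stop("split error: class '", cl, "' too small")
    test <- c(test, idx[seq_len(nt)])
    val <- c(val, idx[nt + seq_len(nv)])
  }
  list(train = setdiff(seq_along(labels), c(test, val)),
       val = sort(val), test = sort(test))
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates the full Cartesian product of the learning-rate, depth,
#' hidden-unit and l2 grids, selecting the trial with minimal validation
#' masked MSE. Ties prefer the smaller model: fewer units, then fewer
#' layers, then stronger regularization. Diverged trials (non-finite loss)
#' are recorded with validation loss \code{Inf} and never selected.
#'
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param train_ids,val_ids subject splits.
#' @param config base configuration; the grids come from its
#'   \code{*_grid} entries.
#' @return list: \code{best} (named list of selected hyperparameters),
#'   \code{model} (refit at the best setting), \code{trials} (data.frame of
#'   all evaluated combinations with their validation losses).
#' @export
gridSearch <- function(cohort, train_ids, val_ids,
                       config = defaultTrainConfig()) {
  grid <- expand.grid(lr = config$lr_grid, depth = config$depth_grid,
                      units = config$units_grid, l2 = config$l2_grid,
                      KEEP.OUT.ATTRS = FALSE)
  trials <- grid
  trials$val_loss <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$lr <- grid$lr[i]; cfg$ffn_depth <- grid$depth[i]
    cfg$hidden_units <- grid$units[i]; cfg$l2 <- grid$l2[i]
    fit <- tryCatch(trainModel(cohort, train_ids, val_ids, cfg),
                    error = function(e) NULL)
    trials$val_loss[i] <- if (is.null(fit)) Inf else min(fit@history$val_loss)
  }
  ord <- order(trials$val_loss, trials$units, trials$depth, -trials$l2)
  bestrow <- trials[ord[1], ]
  cfg <- config
  cfg$lr <- bestrow$lr; cfg$ffn_depth <- bestrow$depth
  cfg$hidden_units <- bestrow$units; cfg$l2 <- bestrow$l2
  model <- trainModel(cohort, train_ids, val_ids, cfg)
  list(best = as.list(bestrow[c("lr", "depth", "units", "l2")]),
       model = model, trials = trials)
}

#' Repeated stratified cross-validation
#'
#' Per repetition, each class is shuffled into chunks of 10\% of its
#' subjects; fold k takes chunk k as the test set and a disjoint chunk as
#' the validation set, training on the rest. 5 folds x 5 repetitions yield
#' 25 fold results. Test subjects are never seen during training or
#' validation of their fold.
#'
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param config a \code{\link{defaultTrainConfig}} list.
#' @param trainer training function (default \code{\link{trainModel}};
#'   pass \code{\link{gruMBaseline}} for the ablation reference).
#' @return list: \code{folds} data.frame of per-feature test metrics with
#'   fold/repetition ids, \code{aggregate} per-feature mean and sd across
#'   the 25 results, \code{splits} the index sets used.
#' @export
crossValidate <- function(cohort, config = defaultTrainConfig(),
                          trainer = trainModel) {
  labels <- abetaGroup(cohort)
  if (min(table(labels)) < config$folds)
    stop("split error: a class has fewer subjects than folds")
  n_chunks <- max(config$folds + 1, round(1 / config$test_frac))
  subjects <- colnames(cohort)
  folds <- list(); splits <- list()
  for (rep_i in seq_len(config$repetitions)) {
    chunk <- .stratifiedChunks(labels, n_chunks,
                               stageSeed(config$seed, paste0("cv", rep_i)))
    for (k in seq_len(config$folds)) {
      val_chunk <- ((k + config$folds - 1) %% n_chunks) + 1
      test_ids <- subjects[chunk == k]
      val_ids <- subjects[chunk == val_chunk]
      train_ids <- setdiff(subjects, c(test_ids, val_ids))
      cfg <- config
      cfg$seed <- stageSeed(config$seed, sprintf("fold%d_%d", rep_i, k))
      model <- trainer(cohort, train_ids, val_ids, cfg)
      mr <- regressionMetrics(model, cohort, test_ids)
      mr$fold <- k; mr$repetition <- rep_i
      folds[[length(folds) + 1]] <- mr
      splits[[length(splits) + 1]] <- list(rep = rep_i, fold = k,
                                           train = train_ids, val = val_ids,
                                           test = test_ids)
    }
  }
  folds <- do.call(rbind, folds)
  agg <- do.call(rbind, lapply(split(folds, folds$feature), function(d)
    data.frame(feature = d$feature[1], role = d$role[1],
               mae_mean = mean(d$mae), mae_sd = sd(d$mae),
               mape_mean = mean(d$mape), mape_sd = sd(d$mape),
               r2_mean = mean(d$r2), r2_sd = sd(d$r2))))
  rownames(agg) <- NULL
  list(folds = folds, aggregate = agg, splits = splits)
}
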