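# --- independent oracles -----------------------------------------------

# scalar loop-based attention fusion (no matrix ops)
oracleFuse <- function(x, dem, params) {
  B <- length(x)
  Q <- K <- V <- numeric(B)
  for (i in 1:B) for (j in 1:B) {
    Q[i] <- Q[i] + params$Wq[i, j] * x[j]
    K[i] <- K[i] + params$Wk[i, j] * x[j]
    V[i] <- V[i] + params$Wv[i, j] * x[j]
  }
  A <- matrix(0, B, B)
  for (i in 1:B) {
    logits <- numeric(B)
    for (j in 1:B) logits[j] <- Q[i] * K[j] / sqrt(B)
    e <- exp(logits - max(logits))
    A[i, ] <- e / sum(e)
  }
  U <- numeric(B)
  for (i in 1:B) for (j in 1:B) U[i] <- U[i] + A[i, j] * V[j]
  Z <- U
  for (p in seq_along(params$Wf)) {
    Zn <- numeric(B)
    for (i in 1:B) {
      acc <- params$bf[[p]][i]
      for (j in 1:B) acc <- acc + params$Wf[[p]][i, j] * Z[j]
      Zn[i] <- max(0, acc)
    }
    Z <- Zn
  }
  list(fused = c(Z + x, dem), attention = A)
}

# independent reference GRU step on input g = [x; n] (standard equations)
oracleGRU <- function(h_prev, g, params) {
  lin <- function(W, v, b) drop(W %*% v) + b
  r <- 1 / (1 + exp(-(lin(params$Wri, g, params$bri) +
                      lin(params$Wrh, h_prev, params$brh))))
  z <- 1 / (1 + exp(-(lin(params$Wzi, g, params$bzi) +
                      lin(params$Wzh, h_prev, params$bzh))))
  cand <- tanh(lin(params$Whi, g, params$bhi) +
               lin(params$Whh, r * h_prev, params$bhh))
  (1 - z) * h_prev + z * cand
}

randParams <- function(B, D, H, ffn_depth = 1, seed = 1, n_mri = 2,
                       n_cog = 2) {
  p <- initModelParams(B = B, D = D, H = H, n_mri = n_mri, n_cog = n_cog,
                       ffn_depth = ffn_depth, seed = seed)
  p
}

randInputs <- function(B, D, H, S, T, seed = 1, n_mri = 2, n_cog = 2,
                       p_miss = 0.3) {
  set.seed(seed)
  list(Xatt = array(runif(B * S * T), c(B, S, T)),
       Dem = array(runif(D * S * T), c(D, S, T)),
       Mask = array(rbinom((B + D) * S * T, 1, 1 - p_miss), c(B + D, S, T)),
       Delta = array(sample(0:2, B * S * T, TRUE), c(B, S, T)),
       target_m = array(runif(n_mri * S * (T - 1)), c(n_mri, S, T - 1)),
       target_m_mask = array(rbinom(n_mri * S * (T - 1), 1, 0.8),
                             c(n_mri, S, T - 1)),
       target_c = array(runif(n_cog * S * (T - 1)), c(n_cog, S, T - 1)),
       target_c_mask = array(rbinom(n_cog * S * (T - 1), 1, 0.8),
                             c(n_cog, S, T - 1)))
}

# --- attention fusion ---------------------------------------------------

test_that("attention rows are stochastic and uniform under zero query", {
  p <- randParams(5, 2, 3, seed = 2)
  x <- runif(5); dem <- runif(2)
  fz <- fuseFeatures(x, dem, p)
  expect_equal(unname(rowSums(fz$attention)), rep(1, 5), tolerance = 1e-6)
  p0 <- p; p0$Wq <- p0$Wq * 0
  fz0 <- fuseFeatures(x, dem, p0)
  expect_equal(unname(fz0$attention), matrix(1 / 5, 5, 5), tolerance = 1e-12)
  # invariance to adding a constant to all logits (shift K projection output
  # uniformly by scaling x's contribution): softmax(c + const) = softmax(c)
  A1 <- fz$attention
  logits <- outer(drop(p$Wq %*% x), drop(p$Wk %*% x)) / sqrt(5)
  A2 <- t(apply(logits + 3.7, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  expect_equal(unname(A1), unname(A2), tolerance = 1e-12)
})

test_that("fusion matches the scalar loop oracle on small fixed weights", {
  for (seed in 1:5) {
    p <- randParams(3, 2, 2, ffn_depth = 2, seed = seed)
    set.seed(seed + 100)
    x <- runif(3); dem <- runif(2)
    got <- fuseFeatures(x, dem, p)
    want <- oracleFuse(x, dem, p)
    expect_equal(got$fused, want$fused, tolerance = 1e-10)
    expect_equal(got$attention, want$attention, tolerance = 1e-10)
  }
  expect_error(fuseFeatures(runif(4), runif(2), randParams(3, 2, 2)),
               "shape error")
})

# --- decay/mask GRU step ------------------------------------------------

test_that("with omega = 1 and full mask the step equals a reference GRU", {
  set.seed(33)
  for (i in 1:50) {
    B <- sample(2:5, 1); D <- 2; H <- sample(2:6, 1)
    p <- randParams(B, D, H, seed = i)
    fused <- runif(B + D); n <- rep(1, B + D); h <- runif(H, -0.5, 0.5)
    got <- trmStep(h, rep(1, H), fused, n, p)
    want <- oracleGRU(h, c(fused, n), p)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("omega = 0 fully forgets history", {
  p <- randParams(3, 2, 4, seed = 9)
  fused <- runif(5); n <- rep(1, 5); h <- runif(4)
  got <- trmStep(h, rep(0, 4), fused, n, p)
  g <- c(fused, n)
  z <- 1 / (1 + exp(-(drop(p$Wzi %*% g) + p$bzi + p$bzh)))
  cand <- tanh(drop(p$Whi %*% g) + p$bhi + p$bhh)
  expect_equal(got, z * cand, tolerance = 1e-12)
})

test_that("all-zero weights halve the previous hidden state", {
  H <- 2
  p <- randParams(2, 0, H, seed = 1)
  for (nm in names(p)) {
    if (is.list(p[[nm]])) p[[nm]] <- lapply(p[[nm]], function(x) x * 0)
    else p[[nm]] <- p[[nm]] * 0
  }
  h <- c(0.4, -1.2)
  got <- trmStep(h, rep(1, H), rep(0.3, 2), rep(1, 2), p)
  # r = z = sigmoid(0) = 0.5, cand = tanh(0) = 0 -> h_t = 0.5 * h_prev
  expect_identical(got, 0.5 * h)
})

test_that("hidden states stay inside (-1, 1) after the first step from h0 = 0", {
  p <- randParams(4, 2, 6, seed = 17)
  inp <- randInputs(4, 2, 6, S = 8, T = 4, seed = 18)
  cfg <- list(use_attention = TRUE, use_decay = TRUE, loss_type = "mse")
  fw <- mciTrajectory:::.forwardBatch(p, inp, cfg)
  expect_true(all(abs(fw$hidden) < 1))
})

# --- prediction heads ---------------------------------------------------

test_that("heads are affine in the hidden state", {
  p <- randParams(3, 2, 4, seed = 3, n_mri = 2, n_cog = 3)
  z <- predictNext(rep(0, 4), p)
  expect_equal(z$m_hat, p$bm)
  expect_equal(z$c_hat, p$bc)
  e1 <- c(1, 0, 0, 0)
  z1 <- predictNext(e1, p)
  expect_equal(z1$m_hat, p$Wm[, 1] + p$bm)
  # random instance vs explicit loop
  h <- runif(4)
  want <- numeric(2)
  for (i in 1:2) want[i] <- sum(p$Wm[i, ] * h) + p$bm[i]
  expect_equal(predictNext(h, p)$m_hat, want, tolerance = 1e-12)
})

# --- sequence forward ---------------------------------------------------

test_that("batch forward equals the per-step composition of the module ops", {
  B <- 3; D <- 2; H <- 2; T <- 2
  p <- randParams(B, D, H, seed = 5)
  inp <- randInputs(B, D, H, S = 1, T = T, seed = 6)
  inp$Mask[B + seq_len(D), , ] <- 1
  cfg <- list(use_attention = TRUE, use_decay = TRUE, loss_type = "mse")
  fw <- mciTrajectory:::.forwardBatch(p, inp, cfg)
  # compose by hand: fuse -> decay -> trm -> heads
  x <- inp$Xatt[, 1, 1]; dem <- inp$Dem[, 1, 1]
  fz <- fuseFeatures(x, dem, p)
  omega <- drop(exp(-pmax(0, p$Womega %*% inp$Delta[, 1, 1] + p$bomega)))
  h1 <- trmStep(rep(0, H), omega, fz$fused, inp$Mask[, 1, 1], p)
  pr <- predictNext(h1, p)
  expect_equal(drop(fw$mhat[, 1, 1]), pr$m_hat, tolerance = 1e-10)
  expect_equal(drop(fw$chat[, 1, 1]), pr$c_hat, tolerance = 1e-10)
  expect_equal(drop(fw$hidden[, 1, 1]), h1, tolerance = 1e-10)
  expect_equal(unname(fw$attention[, , 1, 1]), unname(fz$attention),
               tolerance = 1e-10)
  # T = 2 emits exactly one prediction pair
  expect_equal(dim(fw$mhat)[3], 1L)
})

test_that("subjects are independent: permuting a batch permutes outputs", {
  B <- 4; D <- 2; H <- 3
  p <- randParams(B, D, H, seed = 7)
  inp <- randInputs(B, D, H, S = 6, T = 3, seed = 8)
  cfg <- list(use_attention = TRUE, use_decay = TRUE, loss_type = "mse")
  fw <- mciTrajectory:::.forwardBatch(p, inp, cfg)
  perm <- c(4, 1, 6, 2, 5, 3)
  fw2 <- mciTrajectory:::.forwardBatch(p, mciTrajectory:::.sliceSubjects(inp, perm), cfg)
  expect_equal(fw2$mhat, fw$mhat[, perm, , drop = FALSE], tolerance = 1e-12)
  expect_equal(fw2$hidden, fw$hidden[, perm, , drop = FALSE], tolerance = 1e-12)
})

test_that("forwardSequence rejects single-visit cohorts", {
  tm <- tinyModel()
  co <- tm$sim$observed
  v <- cohortValues(co)[, , 1, drop = FALSE]
  expect_error(makeCohort(array(v, c(dim(v)[1], dim(v)[2], 1)),
                          labels = abetaGroup(co)),
               "visits")
})

# --- gradient check -----------------------------------------------------

test_that("analytic gradients match finite differences on a tiny instance", {
  B <- 4; D <- 2; H <- 3; T <- 3; S <- 2
  p <- randParams(B, D, H, ffn_depth = 1, seed = 11)
  inp <- randInputs(B, D, H, S = S, T = T, seed = 12)
  cfg <- list(use_attention = TRUE, use_decay = TRUE, loss_type = "mse")
  lossAt <- function(pp)
    mciTrajectory:::.lossGradBatch(pp, inp, cfg, 0.75, 1.0,
                                   want_grad = FALSE)$loss
  lg <- mciTrajectory:::.lossGradBatch(p, inp, cfg, 0.75, 1.0)
  eps <- 1e-6
  worst <- 0
  for (nm in names(p)) {
    blocks <- if (is.list(p[[nm]])) seq_along(p[[nm]]) else NA
    for (bl in blocks) {
      get <- function(pp) if (is.na(bl)) pp[[nm]] else pp[[nm]][[bl]]
      setv <- function(pp, v) {
        if (is.na(bl)) pp[[nm]] <- v else pp[[nm]][[bl]] <- v
        pp
      }
      theta <- get(p)
      ga <- get(lg$grad)
      idx <- seq_along(theta)
      if (length(idx) > 12) { set.seed(13); idx <- sample(idx, 12) }
      for (k in idx) {
        tp <- theta; tp[k] <- tp[k] + eps
        tm_ <- theta; tm_[k] <- tm_[k] - eps
        gn <- (lossAt(setv(p, tp)) - lossAt(setv(p, tm_))) / (2 * eps)
        rel <- abs(ga[k] - gn) / max(1e-6, abs(ga[k]) + abs(gn))
        worst <- max(worst, rel)
      }
    }
  }
  expect_lt(worst, 1e-4)
})

# --- rollout ------------------------------------------------------------

test_that("rollout horizon 1 equals the teacher-forced prediction at t0", {
  tm <- tinyModel()
  co <- tm$sim$observed
  fw <- forwardSequence(model = tm$model, cohort = co)
  Tn <- dim(cohortValues(co))[3]
  t0 <- Tn - 1   # forecast of visit t0 + 1, emitted after consuming visit t0
  ro <- rolloutTrajectory(tm$model, co, subject = 1, t0 = t0, horizon = 1)
  expect_equal(unname(ro$m_hat[, 1]), unname(fw$mhat[, 1, t0]),
               tolerance = 1e-10)
  expect_equal(unname(ro$c_hat[, 1]), unname(fw$chat[, 1, t0]),
               tolerance = 1e-10)
})

test_that("rollout advances age strictly and stacks horizon predictions", {
  tm <- tinyModel()
  ro <- rolloutTrajectory(tm$model, tm$sim$observed, subject = 2,
                          t0 = 4, horizon = 3)
  expect_equal(ncol(ro$m_hat), 3L)
  expect_true(all(diff(ro$ages) > 0))
})

test_that("multi-step rollout error does not beat one-step error on average", {
  tm <- tinyModel()
  co <- tm$sim$observed; comp <- tm$sim$complete
  mri <- schemaFeatures(cohortSchema(co), "mri")
  st <- tm$model@normalizer
  vn <- cohortValues(applyNormalizer(comp, st))
  e1 <- e2 <- numeric(0)
  for (i in seq_len(min(40, ncol(co)))) {
    ro <- rolloutTrajectory(tm$model, co, subject = i, t0 = 2, horizon = 2)
    e1 <- c(e1, abs(ro$m_hat[, 1] - vn[mri, i, 3]))
    e2 <- c(e2, abs(ro$m_hat[, 2] - vn[mri, i, 4]))
  }
  expect_gte(mean(e2), mean(e1) * 0.95)
})

# --- serialization ------------------------------------------------------

test_that("model JSON round-trip preserves parameters and predictions", {
  tm <- tinyModel()
  f <- withr::local_tempfile(fileext = ".json")
  saveModel(tm$model, f)
  m2 <- loadModel(f)
  expect_equal(m2@params, tm$model@params, tolerance = 1e-12)
  fw1 <- forwardSequence(tm$model, tm$sim$observed)
  fw2 <- forwardSequence(m2, tm$sim$observed)
  expect_equal(fw1$mhat, fw2$mhat, tolerance = 1e-12)
})
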