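#' Initialize model parameters
#'
#' Glorot-style scaled-uniform initialization of all parameter blocks:
#' attention projections (query/key/value, each B x B), the feed-forward
#' refinement stack, the hidden-level decay projection, the decay/mask GRU
#' gates (input side H x 2F, hidden side H x H, F = B + D fused width), and
#' the two linear prediction heads (6 MRI and 9 cognitive outputs).
#'
#' @param B number of attended features (default 17).
#' @param D number of demographic features (default 3).
#' @param H hidden units (default 48).
#' @param n_mri,n_cog head output sizes (6 and 9).
#' @param ffn_depth number of affine+ReLU refinement layers (default 1).
#' @param seed integer seed for reproducible initialization.
#' @return named list of parameter matrices/vectors.
#' @export
initModelParams <- function(B = 17, D = 3, H = 48, n_mri = 6, n_cog = 9,
                            ffn_depth = 1, seed = 1) {
  set.seed(seed)
  glorot <- function(nr, nc) {
    s <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -s, s), nr, nc)
  }
  F <- B + D; G <- 2 * F
  p <- list(
    Wq = glorot(B, B), Wk = glorot(B, B), Wv = glorot(B, B),
    Wf = lapply(seq_len(ffn_depth), function(i) glorot(B, B)),
    bf = lapply(seq_len(ffn_depth), function(i) numeric(B)),
    # decay projection starts near zero so omega ~= 1 at initialization
    # (the recurrence begins as a standard GRU and learns to decay)
    Womega = glorot(H, B) * 0.1, bomega = numeric(H),
    Wri = glorot(H, G), Wzi = glorot(H, G), Whi = glorot(H, G),
    Wrh = glorot(H, H), Wzh = glorot(H, H), Whh = glorot(H, H),
    bri = numeric(H), bzi = numeric(H), bhi = numeric(H),
    brh = numeric(H), bzh = numeric(H), bhh = numeric(H),
    Wm = glorot(n_mri, H), bm = numeric(n_mri),
    Wc = glorot(n_cog, H), bc = numeric(n_cog))
  attr(p, "dims") <- list(B = B, D = D, H = H, n_mri = n_mri, n_cog = n_cog,
                          ffn_depth = ffn_depth)
  p
}

#' Self-attention feature fusion for one visit
#'
#' Each of the B scalar features is one attention token. The concatenated
#' feature vector x is projected to query, key and value vectors
#' (Q = Wq x, K = Wk x, V = Wv x); the attention matrix is the row-wise
#' softmax of the outer product Q K' / sqrt(B); the attended values A V are
#' refined by the feed-forward stack, added back to x (residual), and
#' concatenated with the demographic features which bypass attention.
#'
#' @param x_att numeric vector of the B attended features (MRI + cognitive +
#'   APOE + Centiloid), already imputed and normalized.
#' @param demographics numeric vector of demographic features.
#' @param params parameter list (see \code{\link{initModelParams}}).
#' @return list: \code{fused} numeric vector of length B + D,
#'   \code{attention} the B x B row-stochastic attention matrix.
#' @export
fuseFeatures <- function(x_att, demographics, params) {
  B <- length(x_att)
  if (nrow(params$Wq) != B) stop("shape error: x_att length != nrow(Wq)")
  Q <- drop(params$Wq %*% x_att)
  K <- drop(params$Wk %*% x_att)
  V <- drop(params$Wv %*% x_att)
  logits <- outer(Q, K) / sqrt(B)
  A <- t(apply(logits, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  U <- drop(A %*% V)
  Z <- U
  for (p in seq_along(params$Wf))
    Z <- relu(drop(params$Wf[[p]] %*% Z) + params$bf[[p]])
  list(fused = c(Z + x_att, demographics), attention = A)
}

#' One step of the decay/mask-modified GRU
#'
#' The previous hidden state is attenuated elementwise by the temporal decay
#' factor, \code{htil = h_prev * omega}; the gate input is the concatenation
#' of the fused feature vector and the observation-mask vector. Reset and
#' update gates and the candidate state follow the standard GRU form with
#' separate input-side and hidden-side weights:
#' \preformatted{
#'   r = sigmoid(Wri g + bri + Wrh htil + brh)
#'   z = sigmoid(Wzi g + bzi + Wzh htil + bzh)
#'   h' = tanh(Whi g + bhi + Whh (r * htil) + bhh)
#'   h  = (1 - z) * htil + z * h'
#' }
#'
#' @param h_prev hidden state vector (length H).
#' @param omega decay vector in (0,1] (length H); all ones recovers a
#'   standard GRU on the concatenated input.
#' @param x_fused fused feature vector (length F).
#' @param n_mask observation-mask vector (length F; demographic entries 1).
#' @param params parameter list.
#' @return hidden state vector h_t (length H).
#' @export
trmStep <- function(h_prev, omega, x_fused, n_mask, params) {
  if (length(x_fused) != length(n_mask))
    stop("shape error: fused vector and mask vector lengths differ")
  g <- c(x_fused, n_mask)
  if (ncol(params$Wri) != length(g))
    stop("shape error: gate input width != ncol(Wri)")
  htil <- h_prev * omega
  r <- sigmoid(drop(params$Wri %*% g) + params$bri +
               drop(params$Wrh %*% htil) + params$brh)
  z <- sigmoid(drop(params$Wzi %*% g) + params$bzi +
               drop(params$Wzh %*% htil) + params$bzh)
  cand <- tanh(drop(params$Whi %*% g) + params$bhi +
               drop(params$Whh %*% (r * htil)) + params$bhh)
  (1 - z) * htil + z * cand
}

#' Multi-task linear prediction heads
#'
#' Affine maps from the hidden state to the next-visit predictions: 6 MRI
#' markers and 9 cognitive scores, in normalized feature space (no
#' activation).
#'
#' @param h_t hidden state vector (length H).
#' @param params parameter list.
#' @return list: \code{m_hat} (length 6), \code{c_hat} (length 9).
#' @export
predictNext <- function(h_t, params) {
  list(m_hat = drop(params$Wm %*% h_t) + params$bm,
       c_hat = drop(params$Wc %*% h_t) + params$bc)
}

# ---------------------------------------------------------------------------
# Batched forward / backward engine (subjects vectorized per time step).
# Layout for attention internals: P-matrices have B rows indexed by token j
# and B*S columns indexed by (i, s), i fast. Softmax runs down columns.
# ---------------------------------------------------------------------------

.forwardBatch <- function(params, inp, config, keep_cache = FALSE) {
  B <- dim(inp$Xatt)[1]; S <- dim(inp$Xatt)[2]; Tt <- dim(inp$Xatt)[3]
  Fw <- B + dim(inp$Dem)[1]
  H <- length(params$bri)
  nm <- nrow(params$Wm); nc <- nrow(params$Wc)
  mhat <- array(NA_real_, c(nm, S, Tt - 1))
  chat <- array(NA_real_, c(nc, S, Tt - 1))
  hidden <- array(NA_real_, c(H, S, Tt - 1))
  attn <- if (config$use_attention) array(NA_real_, c(B, B, S, Tt - 1)) else NULL
  cache <- if (keep_cache) vector("list", Tt - 1) else NULL
  Hprev <- matrix(0, H, S)
  sqB <- sqrt(B)
  colrep <- rep(seq_len(S), each = B)
  for (t in seq_len(Tt - 1)) {
    X <- .slice3(inp$Xatt, t); Dm <- .slice3(inp$Dem, t)
    Msk <- .slice3(inp$Mask, t); Dl <- .slice3(inp$Delta, t)
    st <- list(X = X)
    if (config$use_attention) {
      Q <- params$Wq %*% X; K <- params$Wk %*% X; V <- params$Wv %*% X
      Qexp <- matrix(rep(as.vector(Q), each = B), B)
      Kexp <- K[, colrep, drop = FALSE]
      Lp <- Qexp * Kexp / sqB
      cm <- .colMaxs(Lp)
      E <- exp(Lp - rep(cm, each = B))
      A_P <- E / rep(colSums(E), each = B)
      Vexp <- V[, colrep, drop = FALSE]
      U <- matrix(colSums(A_P * Vexp), B, S)
      Zs <- list(U); Zpre <- list()
      Z <- U
      for (p in seq_along(params$Wf)) {
        pre <- params$Wf[[p]] %*% Z + params$bf[[p]]
        Z <- relu(pre)
        Zpre[[p]] <- pre; Zs[[p + 1]] <- Z
      }
      R <- Z + X
      fused <- rbind(R, Dm)
      # attention maps: A[i, j, s] = A_P[j, (s-1)B + i]
      attn[, , , t] <- aperm(array(A_P, c(B, B, S)), c(2, 1, 3))
      if (keep_cache)
        st <- c(st, list(Q = Q, K = K, V = V, A_P = A_P, Qexp = Qexp,
                         Kexp = Kexp, Vexp = Vexp, Zs = Zs, Zpre = Zpre))
    } else {
      fused <- rbind(X, Dm)
    }
    Gt <- rbind(fused, Msk)
    if (config$use_decay) {
      pre_o <- params$Womega %*% Dl + params$bomega
      omega <- exp(-relu(pre_o))
    } else {
      pre_o <- NULL
      omega <- matrix(1, H, S)
    }
    htil <- Hprev * omega
    r <- sigmoid(params$Wri %*% Gt + params$bri + params$Wrh %*% htil + params$brh)
    z <- sigmoid(params$Wzi %*% Gt + params$bzi + params$Wzh %*% htil + params$bzh)
    cand <- tanh(params$Whi %*% Gt + params$bhi +
                 params$Whh %*% (r * htil) + params$bhh)
    Ht <- (1 - z) * htil + z * cand
    mhat[, , t] <- params$Wm %*% Ht + params$bm
    chat[, , t] <- params$Wc %*% Ht + params$bc
    hidden[, , t] <- Ht
    if (keep_cache) {
      st <- c(st, list(Gt = Gt, Dl = Dl, pre_o = pre_o, omega = omega,
                       htil = htil, r = r, z = z, cand = cand,
                       Hprev = Hprev, Ht = Ht))
      cache[[t]] <- st
    }
    Hprev <- Ht
  }
  list(mhat = mhat, chat = chat, hidden = hidden, attention = attn,
       cache = cache)
}

# Masked composite loss and analytic gradients for one batch.
# Returns loss components and a gradient list congruent with params.
.lossGradBatch <- function(params, inp, config, alpha, gamma,
                           want_grad = TRUE) {
  fw <- .forwardBatch(params, inp, config, keep_cache = want_grad)
  tm <- inp$target_m; tmm <- inp$target_m_mask
  tc <- inp$target_c; tcm <- inp$target_c_mask
  cnt_m <- sum(tmm); cnt_c <- sum(tcm)
  if (cnt_m + cnt_c == 0) stop("undefined loss: no observed target cells")
  em <- (fw$mhat - tm) * tmm
  ec <- (fw$chat - tc) * tcm
  L_m <- if (cnt_m > 0) sum(em^2) / cnt_m else 0
  L_c <- if (cnt_c > 0) sum(ec^2) / cnt_c else 0
  loss <- totalLoss(L_m, L_c, alpha, gamma)
  if (!want_grad)
    return(list(loss = loss, L_m = L_m, L_c = L_c, forward = fw))
  dmhat <- if (cnt_m > 0) 2 * alpha * em / cnt_m else 0 * em
  dchat <- if (cnt_c > 0) 2 * gamma * ec / cnt_c else 0 * ec
  g <- lapply(params, function(x)
    if (is.list(x)) lapply(x, function(y) y * 0) else x * 0)
  B <- dim(inp$Xatt)[1]; S <- dim(inp$Xatt)[2]; Tt <- dim(inp$Xatt)[3]
  sqB <- sqrt(B)
  Fw <- B + dim(inp$Dem)[1]
  dHnext <- matrix(0, length(params$bri), S)
  for (t in rev(seq_len(Tt - 1))) {
    st <- fw$cache[[t]]
    dmh <- .slice3(dmhat, t); dch <- .slice3(dchat, t)
    g$Wm <- g$Wm + dmh %*% t(st$Ht); g$bm <- g$bm + rowSums(dmh)
    g$Wc <- g$Wc + dch %*% t(st$Ht); g$bc <- g$bc + rowSums(dch)
    dH <- crossprod(params$Wm, dmh) + crossprod(params$Wc, dch) + dHnext
    dz <- dH * (st$cand - st$htil)
    dcand <- dH * st$z
    dhtil <- dH * (1 - st$z)
    dac <- dcand * (1 - st$cand^2)
    g$Whi <- g$Whi + dac %*% t(st$Gt); g$bhi <- g$bhi + rowSums(dac)
    rh <- st$r * st$htil
    g$Whh <- g$Whh + dac %*% t(rh); g$bhh <- g$bhh + rowSums(dac)
    drh <- crossprod(params$Whh, dac)
    dr <- drh * st$htil
    dhtil <- dhtil + drh * st$r
    daz <- dz * st$z * (1 - st$z)
    g$Wzi <- g$Wzi + daz %*% t(st$Gt); g$bzi <- g$bzi + rowSums(daz)
    g$Wzh <- g$Wzh + daz %*% t(st$htil); g$bzh <- g$bzh + rowSums(daz)
    dhtil <- dhtil + crossprod(params$Wzh, daz)
    dar <- dr * st$r * (1 - st$r)
    g$Wri <- g$Wri + dar %*% t(st$Gt); g$bri <- g$bri + rowSums(dar)
    g$Wrh <- g$Wrh + dar %*% t(st$htil); g$brh <- g$brh + rowSums(dar)
    dhtil <- dhtil + crossprod(params$Wrh, dar)
    dG <- crossprod(params$Wri, dar) + crossprod(params$Wzi, daz) +
      crossprod(params$Whi, dac)
    dHnext <- dhtil * st$omega
    if (config$use_decay) {
      domega <- dhtil * st$Hprev
      dpre <- -domega * st$omega * (st$pre_o > 0)
      g$Womega <- g$Womega + dpre %*% t(st$Dl)
      g$bomega <- g$bomega + rowSums(dpre)
    }
    if (config$use_attention) {
      dR <- dG[seq_len(B), , drop = FALSE]
      dZ <- dR
      for (p in rev(seq_along(params$Wf))) {
        dpre <- dZ * (st$Zpre[[p]] > 0)
        g$Wf[[p]] <- g$Wf[[p]] + dpre %*% t(st$Zs[[p]])
        g$bf[[p]] <- g$bf[[p]] + rowSums(dpre)
        dZ <- crossprod(params$Wf[[p]], dpre)
      }
      dU <- dZ
      dUexp <- matrix(rep(as.vector(dU), each = B), B)
      dA_P <- st$Vexp * dUexp
      tmp <- st$A_P * dUexp
      dV <- colSums(aperm(array(tmp, c(B, B, S)), c(2, 1, 3)))
      dV <- matrix(dV, B, S)
      dLp <- st$A_P * (dA_P - rep(colSums(st$A_P * dA_P), each = B))
      dQ <- matrix(colSums(dLp * st$Kexp), B, S) / sqB
      tmp2 <- dLp * st$Qexp / sqB
      dK <- matrix(colSums(aperm(array(tmp2, c(B, B, S)), c(2, 1, 3))), B, S)
      g$Wq <- g$Wq + dQ %*% t(st$X)
      g$Wk <- g$Wk + dK %*% t(st$X)
      g$Wv <- g$Wv + dV %*% t(st$X)
    }
  }
  list(loss = loss, L_m = L_m, L_c = L_c, grad = g, forward = fw)
}
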