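## Multi-head attention across the frame axis.
##
## Key/query/value tensors come from per-frame 2D convolutions; scores are
## computed between frames.  In the default "pooled" mode the score for a
## frame pair (t, s) aggregates over the head's channels AND all pixels,
## giving one F x F attention matrix per head — cost linear in pixel count
## and quadratic only in the (short) frame axis.  The "pixelwise" mode
## keeps an F x F softmax at every pixel instead.

attn_pooled_fw <- function(K, Q, V, n_heads, keep = FALSE) {
  d <- dim(Q); H <- d[1]; W <- d[2]; C <- d[3]; F <- d[4]; B <- d[5]
  dh <- C %/% n_heads
  scale <- 1 / sqrt(dh * H * W)
  y <- array(0, dim = d)
  cache <- if (keep) {
    list(dims = d, n_heads = n_heads,
         mats = vector("list", B * n_heads))
  } else NULL
  for (b in seq_len(B)) {
    for (h in seq_len(n_heads)) {
      cr <- ((h - 1) * dh + 1):(h * dh)
      Qm <- Q[, , cr, , b, drop = FALSE]; dim(Qm) <- c(H * W * dh, F)
      Km <- K[, , cr, , b, drop = FALSE]; dim(Km) <- c(H * W * dh, F)
      Vm <- V[, , cr, , b, drop = FALSE]; dim(Vm) <- c(H * W * dh, F)
      S <- crossprod(Qm, Km) * scale          # F x F, S[t, s]
      A <- exp(S - apply(S, 1, max))
      A <- A / rowSums(A)
      Om <- Vm %*% t(A)
      y[, , cr, , b] <- Om
      if (keep) cache$mats[[(b - 1) * n_heads + h]] <-
          list(Qm = Qm, Km = Km, Vm = Vm, A = A)
    }
  }
  list(y = y, cache = cache)
}

attn_pooled_bw <- function(cache, dY) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; F <- d[4]; B <- d[5]
  n_heads <- cache$n_heads
  dh <- C %/% n_heads
  scale <- 1 / sqrt(dh * H * W)
  dK <- array(0, dim = d); dQ <- array(0, dim = d); dV <- array(0, dim = d)
  for (b in seq_len(B)) {
    for (h in seq_len(n_heads)) {
      cr <- ((h - 1) * dh + 1):(h * dh)
      mt <- cache$mats[[(b - 1) * n_heads + h]]
      dOm <- dY[, , cr, , b, drop = FALSE]; dim(dOm) <- c(H * W * dh, F)
      dA <- crossprod(dOm, mt$Vm)             # F x F, dA[t, s]
      dVm <- dOm %*% mt$A
      rs <- rowSums(dA * mt$A)
      dS <- mt$A * (dA - rs) * scale
      dQ[, , cr, , b] <- mt$Km %*% t(dS)
      dK[, , cr, , b] <- mt$Qm %*% dS
      dV[, , cr, , b] <- dVm
    }
  }
  list(dK = dK, dQ = dQ, dV = dV)
}

attn_pixelwise_fw <- function(K, Q, V, n_heads, keep = FALSE) {
  d <- dim(Q); H <- d[1]; W <- d[2]; C <- d[3]; F <- d[4]; B <- d[5]
  dh <- C %/% n_heads
  scale <- 1 / sqrt(dh)
  P <- H * W
  y <- array(0, dim = d)
  cache <- if (keep) list(dims = d, n_heads = n_heads,
                          mats = vector("list", B * n_heads)) else NULL
  for (b in seq_len(B)) {
    for (h in seq_len(n_heads)) {
      cr <- ((h - 1) * dh + 1):(h * dh)
      Qa <- Q[, , cr, , b, drop = FALSE]; dim(Qa) <- c(P, dh, F)
      Ka <- K[, , cr, , b, drop = FALSE]; dim(Ka) <- c(P, dh, F)
      Va <- V[, , cr, , b, drop = FALSE]; dim(Va) <- c(P, dh, F)
      S <- array(0, dim = c(P, F, F))
      for (t in seq_len(F)) for (s in seq_len(F)) {
        S[, t, s] <- .rowSums(Qa[, , t, drop = FALSE] * Ka[, , s, drop = FALSE],
                              P, dh) * scale
      }
      A <- array(0, dim = c(P, F, F))
      for (t in seq_len(F)) {
        M <- S[, t, , drop = FALSE]; dim(M) <- c(P, F)
        M <- exp(M - apply(M, 1, max))
        A[, t, ] <- M / rowSums(M)
      }
      Oa <- array(0, dim = c(P, dh, F))
      for (t in seq_len(F)) for (s in seq_len(F)) {
        Oa[, , t] <- Oa[, , t] + A[, t, s] * Va[, , s]
      }
      y[, , cr, , b] <- Oa
      if (keep) cache$mats[[(b - 1) * n_heads + h]] <-
          list(Qa = Qa, Ka = Ka, Va = Va, A = A)
    }
  }
  list(y = y, cache = cache)
}

attn_pixelwise_bw <- function(cache, dY) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; F <- d[4]; B <- d[5]
  n_heads <- cache$n_heads
  dh <- C %/% n_heads
  scale <- 1 / sqrt(dh)
  P <- H * W
  dK <- array(0, dim = d); dQ <- array(0, dim = d); dV <- array(0, dim = d)
  for (b in seq_len(B)) {
    for (h in seq_len(n_heads)) {
      cr <- ((h - 1) * dh + 1):(h * dh)
      mt <- cache$mats[[(b - 1) * n_heads + h]]
      dOa <- dY[, , cr, , b, drop = FALSE]; dim(dOa) <- c(P, dh, F)
      dA <- array(0, dim = c(P, F, F))
      dVa <- array(0, dim = c(P, dh, F))
      for (t in seq_len(F)) for (s in seq_len(F)) {
        dA[, t, s] <- .rowSums(dOa[, , t, drop = FALSE] *
                                 mt$Va[, , s, drop = FALSE], P, dh)
        dVa[, , s] <- dVa[, , s] + mt$A[, t, s] * dOa[, , t]
      }
      dS <- array(0, dim = c(P, F, F))
      for (t in seq_len(F)) {
        At <- mt$A[, t, , drop = FALSE]; dim(At) <- c(P, F)
        dAt <- dA[, t, , drop = FALSE]; dim(dAt) <- c(P, F)
        rs <- rowSums(dAt * At)
        dS[, t, ] <- At * (dAt - rs) * scale
      }
      dQa <- array(0, dim = c(P, dh, F))
      dKa <- array(0, dim = c(P, dh, F))
      for (t in seq_len(F)) for (s in seq_len(F)) {
        dQa[, , t] <- dQa[, , t] + dS[, t, s] * mt$Ka[, , s]
        dKa[, , s] <- dKa[, , s] + dS[, t, s] * mt$Qa[, , t]
      }
      dQ[, , cr, , b] <- dQa
      dK[, , cr, , b] <- dKa
      dV[, , cr, , b] <- dVa
    }
  }
  list(dK = dK, dQ = dQ, dV = dV)
}

attn_fw <- function(K, Q, V, n_heads, mode, keep = FALSE) {
  fa_assert(dim(Q)[3] %% n_heads == 0,
            "channel count must be divisible by n_heads",
            "faunet_config_error")
  if (mode == "pooled") attn_pooled_fw(K, Q, V, n_heads, keep)
  else attn_pixelwise_fw(K, Q, V, n_heads, keep)
}

attn_bw <- function(cache, dY, mode) {
  if (mode == "pooled") attn_pooled_bw(cache, dY)
  else attn_pixelwise_bw(cache, dY)
}
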