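## The frame-attention transformer cell: an input projection that sets the
## channel width, a pre-norm attention sublayer (instance norm -> K/Q/V
## convolutions -> frame attention -> output projection, residual), and a
## pre-norm convolutional mixer sublayer (norm -> conv -> GELU -> conv,
## residual).  No positional encoding is used, so the cell is equivariant
## to permutations of the frame axis.

cell_init <- function(k_proj, k_mix, c_in, c, expansion) {
  list(
    inp = conv_params(k_proj, c_in, c),
    n1g = rep(1, c), n1b = numeric(c),
    k = conv_params(k_proj, c, c),
    q = conv_params(k_proj, c, c),
    v = conv_params(k_proj, c, c),
    o = conv_params(k_proj, c, c),
    n2g = rep(1, c), n2b = numeric(c),
    m1 = conv_params(k_mix, c, expansion * c),
    m2 = conv_params(k_mix, expansion * c, c)
  )
}

cell_fw <- function(x, pm, cfg, keep = FALSE) {
  p <- conv_fw(x, pm$inp)
  n1 <- inorm_fw(p, pm$n1g, pm$n1b)
  Kt <- conv_fw(n1$y, pm$k)
  Qt <- conv_fw(n1$y, pm$q)
  Vt <- conv_fw(n1$y, pm$v)
  at <- attn_fw(Kt, Qt, Vt, cfg$n_heads, cfg$attention_mode, keep)
  ao <- conv_fw(at$y, pm$o)
  y <- p + ao
  n2 <- inorm_fw(y, pm$n2g, pm$n2b)
  m1y <- conv_fw(n2$y, pm$m1)
  g <- gelu_fw(m1y)
  m2y <- conv_fw(g$y, pm$m2)
  z <- y + m2y
  cache <- if (keep) {
    list(x = x, n1 = n1$cache, n1y = n1$y, Kt = Kt, Qt = Qt, Vt = Vt,
         at = at$cache, aty = at$y, p = p, y = y, n2 = n2$cache,
         n2y = n2$y, g = g$cache, gy = g$y)
  } else NULL
  list(y = z, cache = cache)
}

cell_bw <- function(cache, dz, pm, cfg) {
  ## mixer sublayer
  dy <- dz
  r_m2 <- conv_bw(cache$gy, pm$m2, dz)
  dg <- gelu_bw(cache$g, r_m2$dx)
  r_m1 <- conv_bw(cache$n2y, pm$m1, dg)
  r_n2 <- inorm_bw(cache$n2, r_m1$dx)
  dy <- dy + r_n2$dx
  ## attention sublayer
  dp <- dy
  r_o <- conv_bw(cache$aty, pm$o, dy)
  r_at <- attn_bw(cache$at, r_o$dx, cfg$attention_mode)
  r_k <- conv_bw(cache$n1y, pm$k, r_at$dK)
  r_q <- conv_bw(cache$n1y, pm$q, r_at$dQ)
  r_v <- conv_bw(cache$n1y, pm$v, r_at$dV)
  r_n1 <- inorm_bw(cache$n1, r_k$dx + r_q$dx + r_v$dx)
  dp <- dp + r_n1$dx
  r_in <- conv_bw(cache$x, pm$inp, dp)
  grads <- list(
    inp = list(w = r_in$dw, b = r_in$db),
    n1g = r_n1$dgamma, n1b = r_n1$dbeta,
    k = list(w = r_k$dw, b = r_k$db),
    q = list(w = r_q$dw, b = r_q$db),
    v = list(w = r_v$dw, b = r_v$db),
    o = list(w = r_o$dw, b = r_o$db),
    n2g = r_n2$dgamma, n2b = r_n2$dbeta,
    m1 = list(w = r_m1$dw, b = r_m1$db),
    m2 = list(w = r_m2$dw, b = r_m2$db)
  )
  list(dx = r_in$dx, grads = grads)
}
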