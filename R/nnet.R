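# Desk-scale segmentation networks with hand-written forward/backward
# passes. All three architectures share the same primitives: same-padded
# convolutions (Rcpp), block average pooling, nearest-neighbour upsampling.
# 2D architectures are realized as 3D operations with unit kernel/pool
# extent along z, which is mathematically identical to independent per-slice
# processing with the coarse grids stacked.

#' @noRd
conv_fw <- function(x, w, b) {
  .cpp_conv3d_fw(as.numeric(x), as.numeric(w), as.numeric(b),
                 as.integer(dim(x)), as.integer(dim(w)))
}

#' @noRd
conv_bw <- function(x, w, dy) {
  .cpp_conv3d_bw(as.numeric(x), as.numeric(w), as.numeric(dy),
                 as.integer(dim(x)), as.integer(dim(w)))
}

#' @noRd
he_init <- function(kx, ky, kz, cin, cout) {
  array(rnorm(kx * ky * kz * cin * cout, 0,
              sqrt(2 / (kx * ky * kz * cin))),
        dim = c(kx, ky, kz, cin, cout))
}

#' @noRd
cat_ch <- function(a, b) {
  d <- dim(a)
  out <- array(0, dim = c(d[1:3], d[4] + dim(b)[4]))
  out[, , , seq_len(d[4])] <- a
  out[, , , d[4] + seq_len(dim(b)[4])] <- b
  out
}

# Architecture definitions ---------------------------------------------------

#' @noRd
init_weights <- function(arch, cin, w, K, S) {
  k2 <- function(ci, co) he_init(3, 3, 1, ci, co)
  k3 <- function(ci, co) he_init(3, 3, 3, ci, co)
  k1 <- function(ci, co) he_init(1, 1, 1, ci, co)
  z <- function(n) numeric(n)
  switch(arch,
    unet3d = list(
      W1 = k3(cin, w), b1 = z(w),
      W2 = k3(w, 2 * w), b2 = z(2 * w),
      W3 = k3(2 * w, K), b3 = z(K),
      W4 = k3(K + 2 * w, 2 * w), b4 = z(2 * w),
      W5 = k3(2 * w + w, w), b5 = z(w),
      W6 = k1(w, 1), b6 = z(1)),
    `attn-unet2d` = list(
      W1 = k2(cin, w), b1 = z(w),
      W2 = k2(w, w), b2 = z(w),
      W3 = k2(w, K), b3 = z(K),
      Wa = k1(w, 1), ba = z(1),
      Wg = k1(K, 1), bg = z(1),
      W4 = k2(K + w, w), b4 = z(w),
      W5 = k1(w, 1), b5 = z(1)),
    vqed2d = list(
      W1 = k2(cin, w), b1 = z(w),
      W2 = k2(w, K), b2 = z(K),
      E = matrix(rnorm(S * K, 0, 0.5), S, K),
      W3 = k2(K, w), b3 = z(w),
      W4 = k1(w, 1), b4 = z(1)),
    stop("unknown architecture: ", arch))
}

# forward passes return logits, bottleneck and every intermediate needed by
# the matching backward pass.

#' @noRd
fw_unet3d <- function(wts, x) {
  a1 <- conv_fw(x, wts$W1, wts$b1); e1 <- relu(a1)
  p1 <- avg_pool(e1, c(2, 2, 2))
  a2 <- conv_fw(p1, wts$W2, wts$b2); e2 <- relu(a2)
  p2 <- avg_pool(e2, c(2, 2, 2))
  a3 <- conv_fw(p2, wts$W3, wts$b3); bt <- relu(a3)
  u2 <- upsample_nn(bt, c(2, 2, 2))
  c2 <- cat_ch(u2, e2)
  a4 <- conv_fw(c2, wts$W4, wts$b4); d2 <- relu(a4)
  u1 <- upsample_nn(d2, c(2, 2, 2))
  c1 <- cat_ch(u1, e1)
  a5 <- conv_fw(c1, wts$W5, wts$b5); d1 <- relu(a5)
  logits <- conv_fw(d1, wts$W6, wts$b6)
  list(logits = logits, bottleneck = bt,
       cache = list(x = x, a1 = a1, e1 = e1, p1 = p1, a2 = a2, e2 = e2,
                    p2 = p2, a3 = a3, bt = bt, c2 = c2, a4 = a4, d2 = d2,
                    c1 = c1, a5 = a5, d1 = d1))
}

#' @noRd
bw_unet3d <- function(wts, cache, dlogits) {
  g6 <- conv_bw(cache$d1, wts$W6, dlogits)
  dd1 <- g6$dx * (cache$a5 > 0)
  g5 <- conv_bw(cache$c1, wts$W5, dd1)
  w <- dim(cache$e1)[4]
  du1 <- g5$dx[, , , seq_len(dim(cache$c1)[4] - w), drop = FALSE]
  de1 <- g5$dx[, , , dim(cache$c1)[4] - w + seq_len(w), drop = FALSE]
  dd2 <- upsample_nn_bw(du1, c(2, 2, 2)) * (cache$a4 > 0)
  g4 <- conv_bw(cache$c2, wts$W4, dd2)
  K <- dim(cache$bt)[4]
  du2 <- g4$dx[, , , seq_len(K), drop = FALSE]
  de2 <- g4$dx[, , , K + seq_len(dim(cache$e2)[4]), drop = FALSE]
  dbt <- upsample_nn_bw(du2, c(2, 2, 2)) * (cache$a3 > 0)
  g3 <- conv_bw(cache$p2, wts$W3, dbt)
  dp2 <- g3$dx
  de2 <- de2 + upsample_nn(dp2, c(2, 2, 2)) / 8
  da2 <- de2 * (cache$a2 > 0)
  g2 <- conv_bw(cache$p1, wts$W2, da2)
  dp1 <- g2$dx
  de1 <- de1 + upsample_nn(dp1, c(2, 2, 2)) / 8
  da1 <- de1 * (cache$a1 > 0)
  g1 <- conv_bw(cache$x, wts$W1, da1)
  list(W1 = g1$dw, b1 = g1$db, W2 = g2$dw, b2 = g2$db,
       W3 = g3$dw, b3 = g3$db, W4 = g4$dw, b4 = g4$db,
       W5 = g5$dw, b5 = g5$db, W6 = g6$dw, b6 = g6$db)
}

#' @noRd
fw_attn <- function(wts, x, f = c(4, 4, 1)) {
  a1 <- conv_fw(x, wts$W1, wts$b1); e1 <- relu(a1)
  a2 <- conv_fw(e1, wts$W2, wts$b2); e2 <- relu(a2)
  p <- avg_pool(e2, f)
  a3 <- conv_fw(p, wts$W3, wts$b3); bt <- relu(a3)
  u <- upsample_nn(bt, f)
  ga <- conv_fw(e2, wts$Wa, wts$ba)
  gg <- conv_fw(u, wts$Wg, wts$bg)
  att <- sigmoid(ga + gg)                   # one gate map, broadcast over ch
  attb <- array(att, dim = dim(e2))         # channel broadcast (att has 1 ch)
  s <- e2 * attb
  c1 <- cat_ch(u, s)
  a4 <- conv_fw(c1, wts$W4, wts$b4); d1 <- relu(a4)
  logits <- conv_fw(d1, wts$W5, wts$b5)
  list(logits = logits, bottleneck = bt,
       cache = list(x = x, a1 = a1, e1 = e1, a2 = a2, e2 = e2, p = p,
                    a3 = a3, bt = bt, u = u, att = att, s = s, c1 = c1,
                    a4 = a4, d1 = d1))
}

#' @noRd
bw_attn <- function(wts, cache, dlogits, f = c(4, 4, 1)) {
  g5 <- conv_bw(cache$d1, wts$W5, dlogits)
  dd1 <- g5$dx * (cache$a4 > 0)
  g4 <- conv_bw(cache$c1, wts$W4, dd1)
  K <- dim(cache$bt)[4]
  du <- g4$dx[, , , seq_len(K), drop = FALSE]
  ds <- g4$dx[, , , K + seq_len(dim(cache$e2)[4]), drop = FALSE]
  attb <- array(cache$att, dim = dim(cache$e2))
  de2 <- ds * attb
  # gradient into the single-channel gate: sum over broadcast channels
  datt <- apply(ds * cache$e2, 1:3, sum)
  dim(datt) <- c(dim(cache$att)[1:3], 1)
  dgate <- datt * cache$att * (1 - cache$att)
  ga_bw <- conv_bw(cache$e2, wts$Wa, dgate)
  gg_bw <- conv_bw(cache$u, wts$Wg, dgate)
  de2 <- de2 + ga_bw$dx
  du <- du + gg_bw$dx
  dbt <- upsample_nn_bw(du, f) * (cache$a3 > 0)
  g3 <- conv_bw(cache$p, wts$W3, dbt)
  de2 <- de2 + upsample_nn(g3$dx, f) / prod(f)
  da2 <- de2 * (cache$a2 > 0)
  g2 <- conv_bw(cache$e1, wts$W2, da2)
  de1 <- g2$dx * (cache$a1 > 0)
  g1 <- conv_bw(cache$x, wts$W1, de1)
  list(W1 = g1$dw, b1 = g1$db, W2 = g2$dw, b2 = g2$db,
       W3 = g3$dw, b3 = g3$db, Wa = ga_bw$dw, ba = ga_bw$db,
       Wg = gg_bw$dw, bg = gg_bw$db, W4 = g4$dw, b4 = g4$db,
       W5 = g5$dw, b5 = g5$db)
}

#' @noRd
vq_quantize <- function(ze, E) {
  d <- dim(ze)
  Zm <- matrix(ze, prod(d[1:3]), d[4])
  # squared distances to every codebook vector
  d2 <- outer(rowSums(Zm^2), rowSums(E^2), `+`) - 2 * Zm %*% t(E)
  idx <- max.col(-d2, ties.method = "first")
  zq <- E[idx, , drop = FALSE]
  dim(zq) <- d
  list(zq = zq, idx = array(idx, dim = d[1:3]))
}

#' @noRd
fw_vqed <- function(wts, x, f = c(4, 4, 1)) {
  a1 <- conv_fw(x, wts$W1, wts$b1); e1 <- relu(a1)
  p <- avg_pool(e1, f)
  ze <- conv_fw(p, wts$W2, wts$b2)
  q <- vq_quantize(ze, wts$E)
  u <- upsample_nn(q$zq, f)
  a3 <- conv_fw(u, wts$W3, wts$b3); d1 <- relu(a3)
  logits <- conv_fw(d1, wts$W4, wts$b4)
  list(logits = logits, bottleneck = ze, codebook_indices = q$idx,
       cache = list(x = x, a1 = a1, e1 = e1, p = p, ze = ze, zq = q$zq,
                    u = u, idx = q$idx, a3 = a3, d1 = d1))
}

#' @noRd
bw_vqed <- function(wts, cache, dlogits, f = c(4, 4, 1), beta = 0.25) {
  g4 <- conv_bw(cache$d1, wts$W4, dlogits)
  dd1 <- g4$dx * (cache$a3 > 0)
  g3 <- conv_bw(cache$u, wts$W3, dd1)
  dzq <- upsample_nn_bw(g3$dx, f)
  n <- length(cache$ze)
  resid <- cache$ze - cache$zq
  # straight-through estimator + commitment term
  dze <- dzq + (2 * beta / n) * resid
  # codebook pulled towards the encoder outputs it quantized
  d <- dim(cache$ze)
  Rm <- matrix(-2 / n * resid, prod(d[1:3]), d[4])
  dE <- matrix(0, nrow(wts$E), ncol(wts$E))
  agg <- rowsum(Rm, group = as.integer(cache$idx))
  dE[as.integer(rownames(agg)), ] <- agg
  g2 <- conv_bw(cache$p, wts$W2, dze)
  de1 <- upsample_nn(g2$dx, f) / prod(f) * (cache$a1 > 0)
  g1 <- conv_bw(cache$x, wts$W1, de1)
  list(W1 = g1$dw, b1 = g1$db, W2 = g2$dw, b2 = g2$db, E = dE,
       W3 = g3$dw, b3 = g3$db, W4 = g4$dw, b4 = g4$db)
}

# Loss: positive-weighted binary cross-entropy plus soft Dice.
#' @noRd
seg_loss_grad <- function(logits, y) {
  p <- sigmoid(logits)
  npos <- sum(y)
  n <- length(y)
  wpos <- if (npos > 0) min(20, (n - npos) / npos) else 1
  wts <- ifelse(y > 0, wpos, 1)
  sw <- sum(wts)
  bce <- sum(wts * (log1p(exp(-abs(logits))) + pmax(logits, 0) - y * logits)) / sw
  dbce <- wts * (p - y) / sw
  eps <- 1e-6
  sp <- sum(p); sy <- sum(y); spy <- sum(p * y)
  dice_l <- 1 - (2 * spy + eps) / (sp + sy + eps)
  ddice_dp <- -(2 * y * (sp + sy + eps) - (2 * spy + eps)) / (sp + sy + eps)^2
  dl <- dbce + ddice_dp * p * (1 - p)
  dim(dl) <- dim(logits)
  list(loss = bce + dice_l, grad = dl)
}

#' @noRd
adam_init <- function(wts) {
  list(m = lapply(wts, function(w) w * 0),
       v = lapply(wts, function(w) w * 0), t = 0)
}

#' @noRd
adam_step <- function(wts, grads, state, lr = 3e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    wts[[nm]] <- wts[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = wts, state = state)
}
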