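# Internal array helpers shared by the preprocessing and network code.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a per-stage 32-bit seed from a global seed.  The derivation is a
# fixed affine map modulo a Mersenne prime so partial pipeline reruns see
# the same stream as a full run.
#' @noRd
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  salt <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 48271 + salt * 16807) %% 2147483647)
}

# Zero-pad a 3D (or 4D channel-last) array at the high end so spatial dims
# are multiples of `f` (length 3).
#' @noRd
pad_to_multiple <- function(x, f) {
  d <- dim(x)
  sp <- d[1:3]
  target <- as.integer(ceiling(sp / f) * f)
  if (all(target == sp)) return(x)
  nd <- d
  nd[1:3] <- target
  out <- array(0, dim = nd)
  if (length(d) == 3L) {
    out[seq_len(sp[1]), seq_len(sp[2]), seq_len(sp[3])] <- x
  } else {
    out[seq_len(sp[1]), seq_len(sp[2]), seq_len(sp[3]), ] <- x
  }
  out
}

# Block mean-pool a channel-last 4D array by per-axis integer factors.
#' @noRd
avg_pool <- function(x, f) {
  d <- dim(x)
  stopifnot(length(d) == 4L, all(d[1:3] %% f == 0))
  dc <- d[1:3] %/% f
  dim(x) <- c(f[1], dc[1], f[2], dc[2], f[3], dc[3], d[4])
  x <- aperm(x, c(1, 3, 5, 2, 4, 6, 7))
  dim(x) <- c(prod(f), prod(dc) * d[4])
  y <- colMeans(x)
  dim(y) <- c(dc, d[4])
  y
}

# Block sum-pool (3D input), used for mask overlap counting and pool backprop.
#' @noRd
sum_pool3 <- function(x, f) {
  d <- dim(x)
  stopifnot(length(d) == 3L, all(d %% f == 0))
  dc <- d %/% f
  dim(x) <- c(f[1], dc[1], f[2], dc[2], f[3], dc[3])
  x <- aperm(x, c(1, 3, 5, 2, 4, 6))
  dim(x) <- c(prod(f), prod(dc))
  y <- colSums(x)
  dim(y) <- dc
  y
}

# Nearest-neighbour upsample of a channel-last 4D array by factors f.
#' @noRd
upsample_nn <- function(x, f) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = f[1]),
    rep(seq_len(d[2]), each = f[2]),
    rep(seq_len(d[3]), each = f[3]), , drop = FALSE]
}

# Backward pass of upsample_nn: block-sum the gradient.
#' @noRd
upsample_nn_bw <- function(dy, f) {
  d <- dim(dy)
  dc <- d[1:3] %/% f
  out <- array(0, dim = c(dc, d[4]))
  for (c in seq_len(d[4])) out[, , , c] <- sum_pool3(dy[, , , c, drop = TRUE], f)
  dim(out) <- c(dc, d[4])
  out
}

#' @noRd
sigmoid <- function(z) 1 / (1 + exp(-z))

#' @noRd
relu <- function(z) {
  z[z < 0] <- 0
  z
}
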