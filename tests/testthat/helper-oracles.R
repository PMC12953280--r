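# Independent oracles used to cross-check the package's implementations.

# AUC by exhaustive positive-negative pair counting (ties count one half).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Projected-gradient solver for min ||Pw - y||^2 subject to w >= 0.
nnls_oracle <- function(P, y, iters = 20000) {
  w <- rep(0, ncol(P))
  L <- max(eigen(crossprod(P), only.values = TRUE)$values)
  for (i in seq_len(iters)) {
    g <- crossprod(P, P %*% w - y)
    w <- pmax(0, w - as.numeric(g) / L)
  }
  w
}
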