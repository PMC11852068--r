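# Compact Elman-style recurrent classifier, trained by backpropagation
# through time with Adam. Sequences here are short (the 7 sliding windows of
# an epoch) with 1-2 input channels, so a plain-R implementation is fast.

rnnInit <- function(dIn, hidden, seed) {
  withSeed(seed, {
    list(
      Wxh = matrix(stats::rnorm(dIn * hidden, sd = 1 / sqrt(max(dIn, 1))),
                   dIn, hidden),
      Whh = matrix(stats::rnorm(hidden * hidden, sd = 1 / sqrt(hidden)),
                   hidden, hidden),
      bh = numeric(hidden),
      wo = matrix(stats::rnorm(hidden, sd = 1 / sqrt(hidden)), hidden, 1),
      bo = 0
    )
  })
}

rnnForward <- function(par, X) {
  # X: batch x T x dIn; returns list(H = list of batch x hidden states, p)
  B <- dim(X)[1]; Tn <- dim(X)[2]
  H <- vector("list", Tn + 1)
  H[[1]] <- matrix(0, B, ncol(par$Wxh))
  for (t in seq_len(Tn)) {
    Xt <- matrix(X[, t, ], nrow = B)
    H[[t + 1]] <- tanh(Xt %*% par$Wxh + H[[t]] %*% par$Whh +
                       matrix(par$bh, B, length(par$bh), byrow = TRUE))
  }
  z <- H[[Tn + 1]] %*% par$wo + par$bo
  p <- 1 / (1 + exp(-z))
  list(H = H, p = as.vector(p))
}

rnnGrad <- function(par, X, y) {
  B <- dim(X)[1]; Tn <- dim(X)[2]
  fw <- rnnForward(par, X)
  H <- fw$H
  dz <- matrix((fw$p - y) / B, B, 1)               # d(BCE)/d logit
  g <- list(Wxh = 0 * par$Wxh, Whh = 0 * par$Whh, bh = 0 * par$bh,
            wo = t(H[[Tn + 1]]) %*% dz, bo = sum(dz))
  dH <- dz %*% t(par$wo)
  for (t in rev(seq_len(Tn))) {
    dZ <- dH * (1 - H[[t + 1]]^2)
    Xt <- matrix(X[, t, ], nrow = B)
    g$Wxh <- g$Wxh + t(Xt) %*% dZ
    g$Whh <- g$Whh + t(H[[t]]) %*% dZ
    g$bh <- g$bh + colSums(dZ)
    dH <- dZ %*% t(par$Whh)
  }
  g
}

rnnTrain <- function(X, y, hidden = 16, epochs = 50, lr = 1e-2,
                     batchSize = 16, seed = 1) {
  dIn <- dim(X)[3]
  par <- rnnInit(dIn, hidden, seed)
  mAdam <- lapply(par, function(p) 0 * p)
  vAdam <- lapply(par, function(p) 0 * p)
  beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8
  step <- 0
  n <- dim(X)[1]
  withSeed(seed + 1, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1, n)]
        if (length(idx) < 2) next
        g <- rnnGrad(par, X[idx, , , drop = FALSE], y[idx])
        step <- step + 1
        for (nm in names(par)) {
          mAdam[[nm]] <- beta1 * mAdam[[nm]] + (1 - beta1) * g[[nm]]
          vAdam[[nm]] <- beta2 * vAdam[[nm]] + (1 - beta2) * g[[nm]]^2
          mh <- mAdam[[nm]] / (1 - beta1^step)
          vh <- vAdam[[nm]] / (1 - beta2^step)
          par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + epsA)
        }
      }
    }
  })
  par
}

rnnPredict <- function(par, X) {
  rnnForward(par, X)$p
}
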