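.taperCache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first \code{k} DPSS tapers of length \code{n} for
#' time-bandwidth product \code{nw} via the classical symmetric tridiagonal
#' eigenproblem, whose eigenvectors order the tapers by spectral
#' concentration. Tapers are unit-norm columns; results are cached per
#' \code{(n, nw, k)}.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers; must satisfy \code{k <= 2 nw - 1}.
#' @return n x k matrix of tapers.
#' @export
dpssTapers <- function(n, nw = 3, k = 5) {
  if (k > 2 * nw - 1) {
    stop(sprintf("parameter error: k = %d tapers exceeds 2*nw - 1 = %g", k, 2 * nw - 1),
         call. = FALSE)
  }
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.taperCache[[key]])) return(.taperCache[[key]])
  W <- nw / n
  t0 <- 0:(n - 1)
  diagonal <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * W)
  offdiag <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  diag(A) <- diagonal
  A[cbind(1:(n - 1), 2:n)] <- offdiag
  A[cbind(2:n, 1:(n - 1))] <- offdiag
  e <- eigen(A, symmetric = TRUE)
  tapers <- e$vectors[, seq_len(k), drop = FALSE]
  # polarity convention: make each taper's mean (or leading lobe) positive
  for (j in seq_len(k)) {
    s <- sum(tapers[, j])
    if (abs(s) < 1e-10) s <- tapers[2, j] - tapers[1, j]
    if (s < 0) tapers[, j] <- -tapers[, j]
  }
  .taperCache[[key]] <- tapers
  tapers
}

#' Plan sliding windows over an epoch
#'
#' Windows of \code{winLen} samples advance by \code{step} and tile the whole
#' epoch: \code{floor((epochLen - winLen)/step) + 1} windows. Each window is
#' labelled "pre" when its midpoint sample falls before the event sample and
#' "post" otherwise, so a 2000-sample epoch with a 256/128 window plan and the
#' event at sample 1000 yields 14 windows, 7 per condition.
#'
#' @param epochLen epoch length in samples.
#' @param winLen window length in samples (default 256).
#' @param step step in samples (default 128).
#' @param eventSample 0-based event sample within the epoch.
#' @return a [WindowPlan-class].
#' @export
planWindows <- function(epochLen, winLen = 256, step = 128,
                        eventSample = epochLen / 2) {
  if (winLen > epochLen) {
    stop(sprintf("parameter error: window length %d exceeds epoch length %d",
                 winLen, epochLen), call. = FALSE)
  }
  assertScalar(step, "step", min = 1, integer = TRUE)
  nWin <- floor((epochLen - winLen) / step) + 1
  starts <- (seq_len(nWin) - 1) * step           # 0-based
  mids <- starts + winLen / 2
  condition <- ifelse(mids < eventSample, "pre", "post")
  new("WindowPlan", winLen = winLen, step = step, nWindows = nWin,
      starts = starts, condition = condition, epochLen = epochLen,
      eventSample = eventSample)
}

# tapered eigenspectra of a channels x winLen block: array freq x channels x k
mtmEigenspectra <- function(windowData, tapers) {
  nCh <- nrow(windowData)
  n <- ncol(windowData)
  k <- ncol(tapers)
  out <- array(0i, dim = c(n, nCh, k))
  xT <- t(windowData)                             # n x channels
  for (j in seq_len(k)) {
    out[, , j] <- stats::mvfft(xT * tapers[, j])
  }
  out
}

#' Multitaper coherence spectrum of two signals
#'
#' The magnitude-squared coherence
#' \deqn{C_{xy}(f) = |\langle S_{xy}(f)\rangle|^2 /
#'   (\langle S_{xx}(f)\rangle \langle S_{yy}(f)\rangle)}
#' with \eqn{\langle\cdot\rangle} averaging the k Slepian eigenspectra.
#' Values are clipped to \code{[0, 1]}; a zero-variance input yields zero
#' coherence with a warning.
#'
#' @param x,y equal-length numeric vectors.
#' @param fs sampling rate (Hz).
#' @param nw time-bandwidth product (default 3).
#' @param k taper count (default 5).
#' @return data.frame with columns \code{freq} (Hz, up to Nyquist) and
#'   \code{coherence}.
#' @export
mtmCoherence <- function(x, y, fs, nw = 3, k = 5) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  tapers <- dpssTapers(n, nw, k)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero-variance input: coherence undefined, returning 0")
    nf <- floor(n / 2) + 1
    return(data.frame(freq = (seq_len(nf) - 1) * fs / n, coherence = 0))
  }
  X <- stats::mvfft(x * tapers)                   # n x k
  Y <- stats::mvfft(y * tapers)
  Sxx <- rowMeans(Mod(X)^2)
  Syy <- rowMeans(Mod(Y)^2)
  Sxy <- rowMeans(X * Conj(Y))
  coh <- Mod(Sxy)^2 / (Sxx * Syy)
  coh <- pmin(pmax(coh, 0), 1)
  nf <- floor(n / 2) + 1
  data.frame(freq = (seq_len(nf) - 1) * fs / n, coherence = coh[seq_len(nf)])
}

#' Band-averaged coherence adjacency of one window
#'
#' All-pairs multitaper coherence averaged over the frequency bins inside
#' \code{[fLo, fHi]} (bin spacing fs / winLen), returning the symmetric
#' channels x channels adjacency with unit diagonal that one sliding window
#' contributes to the network.
#'
#' @param windowData channels x winLen matrix of band-filtered signal.
#' @param fs sampling rate (Hz).
#' @param band a [BandSpec-class].
#' @param nw,k multitaper parameters.
#' @return channels x channels symmetric matrix, diagonal 1, entries in
#'   \code{[0, 1]}.
#' @export
bandAdjacency <- function(windowData, fs, band, nw = 3, k = 5) {
  n <- ncol(windowData)
  nCh <- nrow(windowData)
  freqs <- (0:(n - 1)) * fs / n
  bins <- which(freqs >= band@fLo & freqs <= band@fHi & freqs <= fs / 2)
  if (!length(bins)) {
    stop(sprintf("parameter error: band '%s' contains no frequency bin at resolution %g Hz",
                 band@name, fs / n), call. = FALSE)
  }
  tapers <- dpssTapers(n, nw, k)
  spectra <- mtmEigenspectra(windowData, tapers)   # n x nCh x k
  vars <- apply(windowData, 1, stats::var)
  acc <- matrix(0, nCh, nCh)
  for (f in bins) {
    Xf <- matrix(spectra[f, , ], nrow = nCh)       # nCh x k
    S <- (Xf %*% Conj(t(Xf))) / k                  # cross-spectral matrix
    p <- Re(diag(S))
    denom <- outer(p, p)
    C <- Mod(S)^2 / denom
    acc <- acc + C
  }
  adj <- acc / length(bins)
  adj <- pmin(pmax(adj, 0), 1)
  if (any(vars == 0)) {
    warning("zero-variance channel(s): coherence undefined, set to 0")
    bad <- which(vars == 0)
    adj[bad, ] <- 0
    adj[, bad] <- 0
  }
  adj <- (adj + t(adj)) / 2
  diag(adj) <- 1
  adj
}

#' Assemble the trial x window coherence tensor
#'
#' Applies [bandAdjacency()] to every (trial, window) block of an epoch set
#' under a window plan.
#'
#' @param epochs an [EpochSet-class] (band-filtered).
#' @param plan a [WindowPlan-class] fitting the epoch length.
#' @param nw,k multitaper parameters.
#' @return a [CoherenceTensor-class] of shape trials x windows x channels x
#'   channels.
#' @export
coherenceTensor <- function(epochs, plan, nw = 3, k = 5) {
  d <- dim(epochs@data)
  if (plan@epochLen != d[3]) {
    stop("parameter error: window plan epoch length does not match the epochs",
         call. = FALSE)
  }
  nTrials <- d[1]; nCh <- d[2]
  vals <- array(0, dim = c(nTrials, plan@nWindows, nCh, nCh))
  for (tr in seq_len(nTrials)) {
    trial <- matrix(epochs@data[tr, , ], nrow = nCh)
    for (w in seq_len(plan@nWindows)) {
      idx <- (plan@starts[w] + 1):(plan@starts[w] + plan@winLen)
      vals[tr, w, , ] <- bandAdjacency(trial[, idx, drop = FALSE],
                                       epochs@fs, epochs@band, nw, k)
    }
  }
  new("CoherenceTensor", subjectId = epochs@subjectId, band = epochs@band,
      values = vals, windowPlan = plan)
}

#' Global mean coherence trace
#'
#' Per window: mean of the strict upper triangle of each trial's adjacency,
#' then the mean across trials — the global coherence time course around the
#' event.
#'
#' @param tensor a [CoherenceTensor-class].
#' @return numeric vector, one mean per window.
#' @export
globalMeanCoherence <- function(tensor) {
  d <- dim(tensor@values)
  if (d[1] == 0 || d[2] == 0) stop("parameter error: empty coherence tensor",
                                   call. = FALSE)
  ut <- upper.tri(matrix(0, d[3], d[4]))
  sapply(seq_len(d[2]), function(w) {
    mean(sapply(seq_len(d[1]), function(tr) mean(tensor@values[tr, w, , ][ut])))
  })
}
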