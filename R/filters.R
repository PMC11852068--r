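# Zero-phase IIR filtering machinery.
#
# All Butterworth filters in the package are designed as zero-pole-gain
# (analog prototype -> frequency transform -> bilinear) and applied as a
# cascade of biquad (second-order) sections, each run forward-backward.
# Transfer-function realizations of high-order Butterworth filters are
# numerically unusable at the extreme normalized edges this pipeline needs
# (e.g. a 1 Hz edge at a 30 kHz rate); the sectioned form is exact there.

# Design an order-n Butterworth as a list of biquads.
# W: normalized edge(s), Nyquist = 1. type: "low", "high" or "pass".
# For "pass", W = c(lo, hi) and the polynomial order doubles (2n poles).
butterSos <- function(n, W, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  if (any(W <= 0) || any(W >= 1)) {
    stop("sampling error: normalized band edges must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  k <- seq_len(n)
  protoPoles <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # analog LP, wc = 1
  Wa <- tan(pi * W / 2)                                   # prewarp (T = 2)
  tr <- switch(type,
    low  = signal::sftrans(numeric(0), protoPoles, 1, W = Wa, stop = FALSE),
    high = signal::sftrans(numeric(0), protoPoles, 1, W = Wa, stop = TRUE),
    pass = signal::sftrans(numeric(0), protoPoles, 1, W = Wa, stop = FALSE))
  dig <- signal::bilinear(tr$zero, tr$pole, tr$gain, T = 2)
  poles <- dig$pole

  # pair conjugate poles into sections (all Butterworth transforms of even or
  # paired odd order yield conjugate pairs; lone real poles are paired up)
  cplx <- poles[Im(poles) > 1e-12]
  realp <- Re(poles[abs(Im(poles)) <= 1e-12])
  sections <- list()
  for (p in cplx) {
    sections[[length(sections) + 1L]] <-
      list(a = c(1, -2 * Re(p), Mod(p)^2))
  }
  if (length(realp)) {
    realp <- sort(realp)
    for (i in seq(1, length(realp), by = 2)) {
      p1 <- realp[i]
      p2 <- if (i + 1 <= length(realp)) realp[i + 1] else 0
      sections[[length(sections) + 1L]] <- list(a = c(1, -(p1 + p2), p1 * p2))
    }
  }

  # zeros and per-section normalization point
  zref <- switch(type,
    low  = 1 + 0i,                       # unit gain at DC
    high = -1 + 0i,                      # unit gain at Nyquist
    pass = exp(1i * pi * 2 * atan(sqrt(prod(Wa))) / pi))  # band centre
  bsec <- switch(type,
    low  = c(1, 2, 1),
    high = c(1, -2, 1),
    pass = c(1, 0, -1))
  lapply(sections, function(s) {
    zz <- 1 / zref
    H <- sum(bsec * zz^(0:2)) / sum(s$a * zz^(0:2))
    list(b = bsec / abs(H), a = s$a)
  })
}

# forward-backward application of a biquad cascade to a vector
sosFiltfilt <- function(sections, x) {
  for (s in sections) {
    x <- signal::filtfilt(signal::Arma(b = s$b, a = s$a), x)
  }
  x
}

# apply to each row of a channels x samples matrix
sosFiltfiltRows <- function(sections, signalMat) {
  t(apply(signalMat, 1, function(ch) sosFiltfilt(sections, ch)))
}
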