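#' Generate one synthetic multichannel LFP recording
#'
#' Builds a channels x samples recording emulating an event-related coupling
#' change. Each frequency band contributes one latent band-limited Gaussian
#' source (white noise band-pass filtered to the band and standardized),
#' shared by all channels. A channel receives each source scaled by the
#' band's pre-event gain, switching instantaneously to the post-event gain
#' for the \code{epochPost} seconds after every event, plus independent white
#' noise of sd \code{noiseSd} and a common 50 Hz sinusoid of amplitude
#' \code{lineAmp}. Events are spaced so consecutive epochs never overlap.
#'
#' With all gains 0 and no line component the channels are statistically
#' independent; with gain 1 and no noise all channels are identical copies of
#' the summed sources.
#'
#' @param config a [CohortConfig-class].
#' @param subjectIndex which subject to generate, in \code{1..nSubjects};
#'   subject s derives its seed as \code{seed + s - 1}.
#' @return a [Recording-class].
#' @export
generateRecording <- function(config, subjectIndex = 1) {
  stopifnot(is(config, "CohortConfig"))
  assertScalar(subjectIndex, "subjectIndex", min = 1, max = config@nSubjects,
               integer = TRUE)
  fs <- config@fsRaw
  gap <- 0.5
  spacing <- config@epochPre + config@epochPost + gap
  lead <- config@epochPre + gap
  events <- lead + (seq_len(config@nTrials) - 1) * spacing
  dur <- events[length(events)] + config@epochPost + gap
  nSamp <- ceiling(dur * fs)
  nCh <- config@nChannels
  bands <- attr(config, "bands")

  withSeed(config@seed + subjectIndex - 1, {
    # per-band shared latent sources, unit sd
    shared <- numeric(nSamp)
    for (nm in names(config@bandCoupling)) {
      b <- bands[[nm]]
      bp <- butterSos(4, c(b@fLo, b@fHi) / (fs / 2), type = "pass")
      src <- sosFiltfilt(bp, rnorm(nSamp))
      src <- src / stats::sd(src)
      g <- config@bandCoupling[[nm]]
      w <- rep(g[1], nSamp)
      if (g[2] != g[1]) {
        for (ev in events) {
          i0 <- floor(ev * fs) + 1
          i1 <- min(nSamp, floor((ev + config@epochPost) * fs))
          w[i0:i1] <- g[2]
        }
      }
      shared <- shared + w * src
    }
    line <- config@lineAmp * sin(2 * pi * 50 * (seq_len(nSamp) - 1) / fs)
    common <- shared + line
    sig <- matrix(stats::rnorm(nCh * nSamp, sd = config@noiseSd), nrow = nCh)
    sig <- sweep(sig, 2, common, "+")
    recording(sprintf("S%02d", subjectIndex), fs, sig, events)
  })
}

#' Generate a synthetic cohort
#'
#' One [Recording-class] per subject, with per-subject seeds derived from the
#' config's master seed, so the whole cohort is reproducible from
#' \code{(config, seed)} alone.
#'
#' @param config a [CohortConfig-class].
#' @return list of [Recording-class], length \code{nSubjects}.
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  lapply(seq_len(config@nSubjects), function(s) generateRecording(config, s))
}

#' Serialize a recording to flat binary + JSON sidecar
#'
#' Writes \code{<prefix>.bin}, the signal as little-endian float64 in
#' channel-major order (all samples of channel 1, then channel 2, ...), and
#' \code{<prefix>.json} holding subject id, rate, shape and event times. The
#' round-trip through [readRecording()] is bit-exact.
#'
#' @param rec a [Recording-class].
#' @param prefix file path prefix.
#' @return invisibly, the two paths written.
#' @export
writeRecording <- function(rec, prefix) {
  binPath <- paste0(prefix, ".bin")
  jsonPath <- paste0(prefix, ".json")
  con <- file(binPath, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec@signal)), con, size = 8, endian = "little")
  meta <- list(subject_id = rec@subjectId, fs = rec@fs,
               n_channels = nrow(rec@signal), n_samples = ncol(rec@signal),
               events = rec@events)
  jsonlite::write_json(meta, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(binPath, jsonPath))
}

#' @rdname writeRecording
#' @export
readRecording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = meta$n_channels * meta$n_samples,
                  size = 8, endian = "little")
  sig <- matrix(vals, nrow = meta$n_channels, byrow = TRUE)
  recording(meta$subject_id, meta$fs, sig, as.numeric(meta$events))
}
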