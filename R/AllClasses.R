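#' @import methods
NULL

#' Frequency band specification
#'
#' A named frequency band \code{[fLo, fHi]} in Hz. The canonical five-band set
#' used throughout avian LFP work (delta, theta, beta, slow gamma, fast gamma)
#' is returned by [canonicalBands()].
#'
#' @slot name band name.
#' @slot fLo lower edge in Hz.
#' @slot fHi upper edge in Hz.
#' @export
setClass("BandSpec",
  representation(name = "character", fLo = "numeric", fHi = "numeric"),
  validity = function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
      return("band name must be a non-empty string")
    if (!(object@fLo > 0)) return("fLo must be > 0")
    if (!(object@fHi > object@fLo)) return("fHi must exceed fLo")
    TRUE
  })

#' @param name band name.
#' @param fLo lower band edge (Hz).
#' @param fHi upper band edge (Hz).
#' @rdname BandSpec-class
#' @export
bandSpec <- function(name, fLo, fHi) {
  new("BandSpec", name = as.character(name), fLo = as.numeric(fLo),
      fHi = as.numeric(fHi))
}

#' The canonical five-band decomposition
#'
#' delta 1-4, theta 5-12, beta 13-30, slow gamma 31-45, fast gamma 55-80 Hz.
#' Note the deliberate 45-55 Hz gap straddling the 50 Hz power line.
#'
#' @return named list of [BandSpec-class] objects.
#' @export
canonicalBands <- function() {
  list(
    delta        = bandSpec("delta", 1, 4),
    theta        = bandSpec("theta", 5, 12),
    beta         = bandSpec("beta", 13, 30),
    `slow gamma` = bandSpec("slow gamma", 31, 45),
    `fast gamma` = bandSpec("fast gamma", 55, 80)
  )
}

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic multichannel LFP generator: cohort size, trial
#' structure, sampling, per-band coupling gains before/after the detection
#' event, line-noise amplitude, private channel noise, and the master seed.
#'
#' @slot nSubjects number of subjects.
#' @slot nTrials trials per subject.
#' @slot nChannels recording channels.
#' @slot fsRaw generation sampling rate (Hz). Set to 1000 for the fast path
#'   that skips the 30 kHz stage.
#' @slot epochPre seconds of epoch before the event.
#' @slot epochPost seconds after.
#' @slot bandCoupling named list: band name -> c(pre, post) mixing gains in
#'   \code{[0, 1]} for the shared band-limited source.
#' @slot lineAmp amplitude of the common 50 Hz component.
#' @slot noiseSd standard deviation of per-channel private white noise.
#' @slot seed master seed; subject s uses seed + s - 1.
#' @export
setClass("CohortConfig",
  representation(nSubjects = "numeric", nTrials = "numeric",
                 nChannels = "numeric", fsRaw = "numeric",
                 epochPre = "numeric", epochPost = "numeric",
                 bandCoupling = "list", lineAmp = "numeric",
                 noiseSd = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@nChannels < 2) return("configuration error: 'nChannels' must be >= 2")
    for (nm in names(object@bandCoupling)) {
      g <- object@bandCoupling[[nm]]
      if (length(g) != 2L || any(!is.finite(g)) || any(g < 0) || any(g > 1))
        return(sprintf(
          "configuration error: 'bandCoupling[%s]' gains must be two values in [0, 1]", nm))
    }
    TRUE
  })

#' @param nSubjects,nTrials,nChannels,fsRaw,epochPre,epochPost,lineAmp,noiseSd,seed
#'   see slots.
#' @param bandCoupling named list mapping band name to \code{c(pre, post)} gains.
#'   The default plants a beta-band coupling increase (0.3 before the event,
#'   0.8 after) with all other bands held at 0.3 throughout.
#' @param bands band definitions the coupling names refer to; defaults to
#'   [canonicalBands()].
#' @rdname CohortConfig-class
#' @export
cohortConfig <- function(nSubjects = 4, nTrials = 60, nChannels = 16,
                         fsRaw = 30000, epochPre = 1, epochPost = 1,
                         bandCoupling = NULL, lineAmp = 1, noiseSd = 1,
                         seed = 1, bands = canonicalBands()) {
  assertScalar(nSubjects, "nSubjects", min = 1, integer = TRUE)
  assertScalar(nTrials, "nTrials", min = 1, integer = TRUE)
  assertScalar(nChannels, "nChannels", min = 2, integer = TRUE)
  assertScalar(fsRaw, "fsRaw", min = 1)
  assertScalar(epochPre, "epochPre", min = 0)
  assertScalar(epochPost, "epochPost", min = 0)
  assertScalar(lineAmp, "lineAmp", min = 0)
  assertScalar(noiseSd, "noiseSd", min = 0)
  assertScalar(seed, "seed", integer = TRUE)
  if (is.null(bandCoupling)) {
    bandCoupling <- lapply(bands, function(b) c(0.3, 0.3))
    if ("beta" %in% names(bandCoupling)) bandCoupling[["beta"]] <- c(0.3, 0.8)
  }
  for (nm in names(bandCoupling)) {
    if (!nm %in% names(bands))
      stop(sprintf("configuration error: 'bandCoupling[%s]' names no known band", nm),
           call. = FALSE)
    g <- bandCoupling[[nm]]
    if (length(g) != 2L || any(!is.finite(g)) || any(g < 0) || any(g > 1))
      stop(sprintf("configuration error: 'bandCoupling[%s]' gains must be in [0, 1]", nm),
           call. = FALSE)
    hi <- bands[[nm]]@fHi
    if (fsRaw <= 2 * hi)
      stop(sprintf("configuration error: 'fsRaw' = %g is not above twice the %s upper edge (%g Hz)",
                   fsRaw, nm, hi), call. = FALSE)
  }
  cfg <- new("CohortConfig", nSubjects = nSubjects, nTrials = nTrials,
             nChannels = nChannels, fsRaw = fsRaw, epochPre = epochPre,
             epochPost = epochPost, bandCoupling = bandCoupling,
             lineAmp = lineAmp, noiseSd = noiseSd, seed = seed)
  attr(cfg, "bands") <- bands[names(bandCoupling)]
  cfg
}

#' Multichannel recording
#'
#' A channels x samples signal matrix with its sampling rate, subject id and
#' the event (sensor trigger) times, one per trial.
#'
#' @slot subjectId subject identifier.
#' @slot fs sampling rate (Hz).
#' @slot signal channels x samples numeric matrix.
#' @slot events event times in seconds.
#' @export
setClass("Recording",
  representation(subjectId = "character", fs = "numeric", signal = "matrix",
                 events = "numeric"),
  validity = function(object) {
    if (!is.numeric(object@signal)) return("signal must be numeric")
    dur <- ncol(object@signal) / object@fs
    if (any(object@events < 0 | object@events > dur))
      return("every event must lie within the recording")
    TRUE
  })

#' @param subjectId,fs,signal,events see slots.
#' @rdname Recording-class
#' @export
recording <- function(subjectId, fs, signal, events) {
  new("Recording", subjectId = as.character(subjectId), fs = as.numeric(fs),
      signal = signal, events = as.numeric(events))
}

#' Event-centred epochs for one band
#'
#' trials x channels x samples array cut around each event, with the sample
#' offset of the event inside the epoch. Sample 1 of each epoch corresponds to
#' (event - preS); the epoch covers the half-open window
#' [event - preS, event + postS).
#'
#' @slot band the [BandSpec-class] the data were filtered to (may have an
#'   empty name for broadband epochs).
#' @slot fs sampling rate (Hz).
#' @slot data trials x channels x samples array.
#' @slot eventSample 0-based sample offset of the event within an epoch
#'   (= preS * fs).
#' @slot subjectId subject identifier.
#' @export
setClass("EpochSet",
  representation(band = "BandSpec", fs = "numeric", data = "array",
                 eventSample = "numeric", subjectId = "character"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3-d array")
    TRUE
  })

#' Sliding-window plan over an epoch
#'
#' Window start offsets (0-based), the pre/post condition label of each window
#' (by window midpoint relative to the event sample), and the plan geometry.
#'
#' @slot winLen window length in samples.
#' @slot step step in samples.
#' @slot nWindows number of windows.
#' @slot starts 0-based start sample of each window.
#' @slot condition "pre"/"post" label per window.
#' @slot epochLen epoch length in samples.
#' @slot eventSample 0-based event sample within the epoch.
#' @export
setClass("WindowPlan",
  representation(winLen = "numeric", step = "numeric", nWindows = "numeric",
                 starts = "numeric", condition = "character",
                 epochLen = "numeric", eventSample = "numeric"),
  validity = function(object) {
    if (object@nWindows != length(object@starts)) return("nWindows mismatch")
    if (length(object@starts) > 1 &&
        any(diff(object@starts) != object@step)) return("starts must step uniformly")
    if (length(object@starts) &&
        object@starts[length(object@starts)] + object@winLen > object@epochLen)
      return("last window exceeds the epoch")
    TRUE
  })

#' Sliding-window coherence tensor
#'
#' trials x windows x channels x channels band-averaged multitaper coherence,
#' one symmetric unit-diagonal adjacency per (trial, window).
#'
#' @slot subjectId subject identifier.
#' @slot band the [BandSpec-class].
#' @slot values 4-d array in \code{[0, 1]}.
#' @slot windowPlan the [WindowPlan-class] used.
#' @export
setClass("CoherenceTensor",
  representation(subjectId = "character", band = "BandSpec", values = "array",
                 windowPlan = "WindowPlan"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 4L) return("values must be trials x windows x channels x channels")
    if (d[3] != d[4]) return("last two axes must be square")
    rng <- range(object@values)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) return("coherence values must lie in [0, 1]")
    TRUE
  })

#' Undirected binary graph
#'
#' Symmetric hollow 0/1 adjacency with edge count m and total pair count
#' M = n(n-1)/2, the bookkeeping the hypergeometric Surprise needs.
#'
#' @slot n node count.
#' @slot adjacency symmetric 0/1 matrix with zero diagonal.
#' @slot m number of edges.
#' @slot M number of node pairs.
#' @export
setClass("BinaryGraph",
  representation(n = "numeric", adjacency = "matrix", m = "numeric",
                 M = "numeric"),
  validity = function(object) {
    a <- object@adjacency
    if (nrow(a) != object@n || ncol(a) != object@n) return("adjacency shape mismatch")
    if (any(a != 0 & a != 1)) return("adjacency must be 0/1")
    if (any(diag(a) != 0)) return("adjacency must be hollow")
    if (!isTRUE(all.equal(a, t(a)))) return("adjacency must be symmetric")
    if (object@m != sum(a) / 2) return("edge count inconsistent with adjacency")
    if (object@M != object@n * (object@n - 1) / 2) return("pair count inconsistent")
    TRUE
  })

#' @param adjacency symmetric hollow 0/1 matrix.
#' @rdname BinaryGraph-class
#' @export
binaryGraph <- function(adjacency) {
  adjacency <- (adjacency != 0) * 1
  diag(adjacency) <- 0
  n <- nrow(adjacency)
  new("BinaryGraph", n = n, adjacency = adjacency, m = sum(adjacency) / 2,
      M = n * (n - 1) / 2)
}

#' Node partition into communities
#'
#' @slot labels integer community id per node, contiguous from 0.
#' @slot nCommunities number of communities.
#' @export
setClass("Partition",
  representation(labels = "integer", nCommunities = "integer"),
  validity = function(object) {
    u <- sort(unique(object@labels))
    if (!identical(u, seq_len(object@nCommunities) - 1L))
      return("labels must be contiguous integers from 0")
    TRUE
  })

#' @param labels community id per node; any coding, made contiguous from 0 in
#'   first-appearance order.
#' @rdname Partition-class
#' @export
partition <- function(labels) {
  labels <- as.integer(factor(labels, levels = unique(labels))) - 1L
  new("Partition", labels = labels, nCommunities = length(unique(labels)))
}

#' Threshold sweep result
#'
#' The 100-tier sparsification sweep: grand-mean Surprise and mean
#' largest-connected-component fraction at each candidate threshold, and the
#' selected optimum (argmax of mean Surprise, ties to the smallest threshold).
#'
#' @slot band the band the sweep was run for.
#' @slot thresholds candidate thresholds, strictly increasing on (0, 1).
#' @slot meanSurprise grand-mean S (log10 units) per threshold.
#' @slot lccFraction mean largest-component fraction per threshold.
#' @slot optimal selected threshold.
#' @export
setClass("ThresholdSweep",
  representation(band = "BandSpec", thresholds = "numeric",
                 meanSurprise = "numeric", lccFraction = "numeric",
                 optimal = "numeric"),
  validity = function(object) {
    if (any(diff(object@thresholds) <= 0)) return("thresholds must be strictly increasing")
    if (any(object@meanSurprise < -1e-9)) return("mean Surprise must be nonnegative")
    TRUE
  })

#' Decoding result for one (feature set, decoder) pair
#'
#' @slot featureSet one of "degree", "modularity", "combined".
#' @slot decoder one of "margin", "recurrent", "tree".
#' @slot foldAccuracies held-out accuracy per fold.
#' @slot meanAccuracy mean over folds.
#' @slot roc two-column matrix (fpr, tpr) from (0,0) to (1,1).
#' @slot auc trapezoidal area under the ROC.
#' @export
setClass("DecodeResult",
  representation(featureSet = "character", decoder = "character",
                 foldAccuracies = "numeric", meanAccuracy = "numeric",
                 roc = "matrix", auc = "numeric"),
  validity = function(object) {
    if (any(object@foldAccuracies < 0 | object@foldAccuracies > 1))
      return("fold accuracies must lie in [0, 1]")
    if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
    TRUE
  })

#' Pipeline configuration
#'
#' End-to-end run parameters: the synthetic cohort, analysis bands, sliding
#' window, multitaper and threshold-grid settings, stage seeds and the output
#' directory. Serializable to/from JSON or YAML via [readPipelineConfig()].
#'
#' @slot cohort a [CohortConfig-class].
#' @slot bands named list of [BandSpec-class] to analyse.
#' @slot fsAnalysis analysis sampling rate after downsampling (Hz).
#' @slot winLen,step sliding-window geometry in samples.
#' @slot nw multitaper time-bandwidth product.
#' @slot k number of Slepian tapers.
#' @slot gridSize number of interior thresholds on (0, 1).
#' @slot decodeBand band name whose features feed the decoders.
#' @slot seeds named numeric: simulation, community, decoding.
#' @slot outputDir directory for run artifacts.
#' @export
setClass("PipelineConfig",
  representation(cohort = "CohortConfig", bands = "list", fsAnalysis = "numeric",
                 winLen = "numeric", step = "numeric", nw = "numeric",
                 k = "numeric", gridSize = "numeric", decodeBand = "character",
                 seeds = "numeric", outputDir = "character"))
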