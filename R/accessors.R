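#' @name accessors
#' @title Accessors for nclnet classes
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots.
#' @param x an nclnet object.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setGeneric("eventTimes", function(x) standardGeneric("eventTimes"))
#' @rdname accessors
#' @export
setGeneric("bandOf", function(x) standardGeneric("bandOf"))
#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("coherenceValues", function(x) standardGeneric("coherenceValues"))
#' @rdname accessors
#' @export
setGeneric("windowPlanOf", function(x) standardGeneric("windowPlanOf"))
#' @rdname accessors
#' @export
setGeneric("windowConditions", function(x) standardGeneric("windowConditions"))
#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))
#' @rdname accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))
#' @rdname accessors
#' @export
setGeneric("pairCount", function(x) standardGeneric("pairCount"))
#' @rdname accessors
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))
#' @rdname accessors
#' @export
setGeneric("communityLabels", function(x) standardGeneric("communityLabels"))
#' @rdname accessors
#' @export
setGeneric("nCommunities", function(x) standardGeneric("nCommunities"))
#' @rdname accessors
#' @export
setGeneric("optimalThreshold", function(x) standardGeneric("optimalThreshold"))
#' @rdname accessors
#' @export
setGeneric("foldAccuracies", function(x) standardGeneric("foldAccuracies"))
#' @rdname accessors
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))
#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setGeneric("aucOf", function(x) standardGeneric("aucOf"))

#' @rdname accessors
setMethod("subjectId", "Recording", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "EpochSet", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "CoherenceTensor", function(x) x@subjectId)
#' @rdname accessors
setMethod("samplingRate", "Recording", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@fs)
#' @rdname accessors
setMethod("signalMatrix", "Recording", function(x) x@signal)
#' @rdname accessors
setMethod("eventTimes", "Recording", function(x) x@events)
#' @rdname accessors
setMethod("bandOf", "EpochSet", function(x) x@band)
#' @rdname accessors
setMethod("bandOf", "CoherenceTensor", function(x) x@band)
#' @rdname accessors
setMethod("bandOf", "ThresholdSweep", function(x) x@band)
#' @rdname accessors
setMethod("epochData", "EpochSet", function(x) x@data)
#' @rdname accessors
setMethod("coherenceValues", "CoherenceTensor", function(x) x@values)
#' @rdname accessors
setMethod("windowPlanOf", "CoherenceTensor", function(x) x@windowPlan)
#' @rdname accessors
setMethod("windowConditions", "WindowPlan", function(x) x@condition)
#' @rdname accessors
setMethod("windowConditions", "CoherenceTensor", function(x) x@windowPlan@condition)
#' @rdname accessors
setMethod("adjacencyMatrix", "BinaryGraph", function(x) x@adjacency)
#' @rdname accessors
setMethod("edgeCount", "BinaryGraph", function(x) x@m)
#' @rdname accessors
setMethod("pairCount", "BinaryGraph", function(x) x@M)
#' @rdname accessors
setMethod("nodeCount", "BinaryGraph", function(x) x@n)
#' @rdname accessors
setMethod("communityLabels", "Partition", function(x) x@labels)
#' @rdname accessors
setMethod("nCommunities", "Partition", function(x) x@nCommunities)
#' @rdname accessors
setMethod("optimalThreshold", "ThresholdSweep", function(x) x@optimal)
#' @rdname accessors
setMethod("foldAccuracies", "DecodeResult", function(x) x@foldAccuracies)
#' @rdname accessors
setMethod("meanAccuracy", "DecodeResult", function(x) x@meanAccuracy)
#' @rdname accessors
setMethod("rocPoints", "DecodeResult", function(x) x@roc)
#' @rdname accessors
setMethod("aucOf", "DecodeResult", function(x) x@auc)

setMethod("show", "BandSpec", function(object) {
  cat(sprintf("BandSpec '%s': %g-%g Hz\n", object@name, object@fLo, object@fHi))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d subjects x %d trials, %d channels @ %g Hz\n",
              object@nSubjects, object@nTrials, object@nChannels, object@fsRaw))
  cat(sprintf("  epoch %g s pre + %g s post; line amp %g, noise sd %g, seed %d\n",
              object@epochPre, object@epochPost, object@lineAmp,
              object@noiseSd, object@seed))
  for (nm in names(object@bandCoupling)) {
    g <- object@bandCoupling[[nm]]
    cat(sprintf("  coupling %-10s pre %.2f -> post %.2f\n", nm, g[1], g[2]))
  }
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording '%s': %d channels x %d samples @ %g Hz, %d events\n",
              object@subjectId, nrow(object@signal), ncol(object@signal),
              object@fs, length(object@events)))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet '%s' [%s]: %d trials x %d channels x %d samples @ %g Hz\n",
              object@subjectId, object@band@name, d[1], d[2], d[3], object@fs))
})

setMethod("show", "WindowPlan", function(object) {
  cat(sprintf("WindowPlan: %d windows (len %d, step %d) over %d samples; %d pre / %d post\n",
              object@nWindows, object@winLen, object@step, object@epochLen,
              sum(object@condition == "pre"), sum(object@condition == "post")))
})

setMethod("show", "CoherenceTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("CoherenceTensor '%s' [%s]: %d trials x %d windows x %d x %d\n",
              object@subjectId, object@band@name, d[1], d[2], d[3], d[4]))
})

setMethod("show", "BinaryGraph", function(object) {
  cat(sprintf("BinaryGraph: %d nodes, %d / %d edges\n",
              object@n, object@m, object@M))
})

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition: %d nodes in %d communities\n",
              length(object@labels), object@nCommunities))
})

setMethod("show", "ThresholdSweep", function(object) {
  cat(sprintf("ThresholdSweep [%s]: %d thresholds, optimal tau = %.4g (mean S = %.4g)\n",
              object@band@name, length(object@thresholds), object@optimal,
              object@meanSurprise[which.min(abs(object@thresholds - object@optimal))]))
})

setMethod("show", "DecodeResult", function(object) {
  cat(sprintf("DecodeResult %s/%s: mean accuracy %.3f (%d folds), AUC %.3f\n",
              object@decoder, object@featureSet, object@meanAccuracy,
              length(object@foldAccuracies), object@auc))
})
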