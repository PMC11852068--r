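#' Node degrees
#'
#' @param graph a [BinaryGraph-class].
#' @return integer degree per node; degrees sum to 2m.
#' @export
nodeDegrees <- function(graph) {
  as.integer(rowSums(graph@adjacency))
}

#' Average node degree
#'
#' \deqn{\bar k = \frac{1}{N}\sum_i k_i = 2m/N,} the overall connection
#' density of the network. Isolated nodes stay in the graph and contribute
#' degree 0, so N is always the channel count.
#'
#' @param graph a [BinaryGraph-class].
#' @return average degree in \code{[0, n - 1]}.
#' @export
averageNodeDegree <- function(graph) {
  2 * graph@m / graph@n
}

#' Newman modularity of a partition
#'
#' \deqn{Q = \frac{1}{2m}\sum_{ij}\left[A_{ij} - \frac{k_i k_j}{2m}\right]
#'   \delta(c_i, c_j),} computed through the equivalent community sum
#' \eqn{\sum_c [e_c/m - (d_c/2m)^2]}. Q lies in \code{[-1, 1]}; the
#' all-in-one partition scores 0 and an edgeless graph returns 0 by
#' convention.
#'
#' @param graph a [BinaryGraph-class].
#' @param part a [Partition-class] covering all nodes.
#' @return modularity Q.
#' @export
modularity <- function(graph, part) {
  if (length(part@labels) != graph@n) {
    stop("data error: partition does not cover all nodes", call. = FALSE)
  }
  if (graph@m == 0) {
    message("edgeless graph: modularity is 0 by convention")
    return(0)
  }
  m <- graph@m
  deg <- rowSums(graph@adjacency)
  q <- 0
  for (c in unique(part@labels)) {
    idx <- which(part@labels == c)
    ec <- sum(graph@adjacency[idx, idx, drop = FALSE]) / 2
    dc <- sum(deg[idx])
    q <- q + ec / m - (dc / (2 * m))^2
  }
  q
}

#' Modularity-maximizing community detection
#'
#' Greedy agglomerative search with single-node refinement: from singletons,
#' repeatedly applies the merge or relabel that most increases Q until no
#' move improves; deterministic given the tie-break seed. An edgeless graph
#' returns the all-singleton partition with a warning.
#'
#' @param graph a [BinaryGraph-class].
#' @param seed integer tie-break seed.
#' @return a [Partition-class].
#' @export
detectCommunitiesModularity <- function(graph, seed = 1) {
  if (graph@m == 0) {
    warning("edgeless graph: returning the all-singleton partition")
    return(new("Partition", labels = seq_len(graph@n) - 1L,
               nCommunities = as.integer(graph@n)))
  }
  labels <- .cppDetectModularity(storage.mode2int(graph@adjacency),
                                 as.integer(seed))
  new("Partition", labels = as.integer(labels),
      nCommunities = length(unique(labels)))
}

#' Per-window network features of a coherence tensor
#'
#' Binarizes every (trial, window) adjacency at the band's optimal threshold,
#' finds the modularity-maximal partition, and tabulates average node degree
#' and modularity with the window's pre/post condition label — one tidy row
#' per (trial, window).
#'
#' @param tensor a [CoherenceTensor-class].
#' @param tau threshold (typically [optimalThreshold()] of the band's sweep).
#' @param seed community-search tie-break seed.
#' @return data.frame with columns subject_id, band, trial, window,
#'   condition, k_bar, Q (the NetFeatureTable layout).
#' @export
featuresPerWindow <- function(tensor, tau, seed = 1) {
  d <- dim(tensor@values)
  nTrials <- d[1]; nWin <- d[2]; n <- d[3]
  mats <- aperm(tensor@values, c(3, 4, 1, 2))
  res <- .cppFeaturesBatch(as.numeric(mats), c(n, n, nTrials * nWin),
                           as.numeric(tau), as.integer(seed))
  if (any(res$zeroEdge == 1)) {
    warning(sprintf("%d window graph(s) had no edges at tau = %g; Q set to 0",
                    sum(res$zeroEdge), tau))
  }
  # stack order matches aperm: trial varies fastest, then window
  data.frame(
    subject_id = tensor@subjectId,
    band = tensor@band@name,
    trial = rep(seq_len(nTrials), times = nWin),
    window = rep(seq_len(nWin), each = nTrials),
    condition = rep(tensor@windowPlan@condition, each = nTrials),
    k_bar = res$kbar,
    Q = res$Q,
    stringsAsFactors = FALSE
  )
}
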