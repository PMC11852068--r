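#' Binarize a weighted adjacency matrix
#'
#' Retains the edge (i, j), i != j, exactly when its weight strictly exceeds
#' \code{tau}; the diagonal is discarded. At \code{tau = 1} (or above the
#' maximum weight) the graph is empty.
#'
#' @param weights square symmetric matrix of weights in \code{[0, 1]}.
#' @param tau threshold in \code{[0, 1]}.
#' @return a [BinaryGraph-class].
#' @export
binarize <- function(weights, tau) {
  if (nrow(weights) != ncol(weights)) {
    stop("data error: weight matrix must be square", call. = FALSE)
  }
  if (max(abs(weights - t(weights))) > 1e-9) {
    stop("data error: weight matrix is asymmetric beyond 1e-9", call. = FALSE)
  }
  assertScalar(tau, "tau", min = 0, max = 1)
  adj <- (weights > tau) * 1
  diag(adj) <- 0
  binaryGraph(adj)
}

#' Hypergeometric Surprise of a partition
#'
#' The Surprise S is minus the base-10 log of the probability of drawing at
#' least the observed number of intra-community edges when the graph's m
#' edges are placed uniformly among its M node pairs, of which
#' \eqn{M_{int}} are intra-community:
#' \deqn{S = -\log_{10} \sum_{j = m_{int}}^{\min(m, M_{int})}
#'   \frac{\binom{M_{int}}{j}\binom{M - M_{int}}{m - j}}{\binom{M}{m}}.}
#' Higher S means the partition captures more edge concentration than chance.
#' Computed from the log-space hypergeometric tail for stability. Trivial
#' partitions (all-in-one, all singletons) and edgeless graphs give S = 0.
#'
#' @param graph a [BinaryGraph-class].
#' @param part a [Partition-class] covering all nodes.
#' @return nonnegative S in log10 units.
#' @export
surpriseOfPartition <- function(graph, part) {
  if (length(part@labels) != graph@n) {
    stop("data error: partition does not cover all nodes", call. = FALSE)
  }
  if (graph@m == 0) {
    message("edgeless graph: Surprise is 0 by convention")
    return(0)
  }
  sizes <- tabulate(part@labels + 1L)
  Mint <- sum(sizes * (sizes - 1) / 2)
  same <- outer(part@labels, part@labels, "==")
  mint <- sum(graph@adjacency[same & upper.tri(same)])
  surpriseValue(graph@M, Mint, graph@m, mint)
}

# S from the counts alone (log-space tail)
surpriseValue <- function(M, Mint, m, mint) {
  if (m == 0 || mint <= 0 || Mint <= 0) return(0)
  logp <- stats::phyper(mint - 1, Mint, M - Mint, m,
                        lower.tail = FALSE, log.p = TRUE)
  max(0, -logp / log(10))
}

#' Surprise-maximizing community detection
#'
#' Greedy agglomerative search: starting from singletons, repeatedly applies
#' the single community merge or single-node relabel that most increases the
#' partition Surprise, until no move improves it. Ties between equal-gain
#' moves are broken by the seed, making the search deterministic.
#'
#' @param graph a [BinaryGraph-class].
#' @param seed integer tie-break seed.
#' @return a [Partition-class].
#' @export
detectCommunitiesSurprise <- function(graph, seed = 1) {
  labels <- .cppDetectSurprise(storage.mode2int(graph@adjacency),
                               as.integer(seed))
  new("Partition", labels = as.integer(labels),
      nCommunities = length(unique(labels)))
}

storage.mode2int <- function(x) {
  storage.mode(x) <- "integer"
  x
}

#' Percolation profile of a weighted network
#'
#' For each threshold, the fraction of nodes in the largest connected
#' component after binarization — the standard percolation diagnostic for
#' data-driven sparsification. Non-increasing in the threshold.
#'
#' @param weights square symmetric weight matrix.
#' @param thresholds ascending thresholds.
#' @return numeric vector of largest-component fractions.
#' @export
percolationProfile <- function(weights, thresholds) {
  if (is.unsorted(thresholds)) {
    stop("parameter error: thresholds must be sorted ascending", call. = FALSE)
  }
  n <- nrow(weights)
  sapply(thresholds, function(tau) {
    g <- binarize(weights, tau)
    ig <- igraph::graph_from_adjacency_matrix(g@adjacency, mode = "undirected")
    max(igraph::components(ig)$csize) / n
  })
}

#' Select the per-band optimal sparsification threshold
#'
#' Runs the 100-tier sweep: thresholds \code{i/(gridSize+1)} for
#' \code{i = 1..gridSize} (interior points of (0, 1)); every trial-window
#' adjacency from every supplied tensor is binarized at each threshold, its
#' Surprise-maximal partition is found and scored, and the threshold with the
#' largest grand-mean S is selected (ties to the smallest threshold, which
#' retains more edges). The mean largest-component fraction is recorded as
#' the percolation diagnostic.
#'
#' @param tensors list of [CoherenceTensor-class], all of the same band
#'   (typically one per subject).
#' @param gridSize number of candidate thresholds (default 100).
#' @param seed tie-break seed for the community search.
#' @return a [ThresholdSweep-class].
#' @export
selectOptimalThreshold <- function(tensors, gridSize = 100, seed = 1) {
  if (is(tensors, "CoherenceTensor")) tensors <- list(tensors)
  if (!length(tensors)) stop("parameter error: no tensors supplied", call. = FALSE)
  bandName <- tensors[[1]]@band@name
  for (tt in tensors) {
    if (tt@band@name != bandName) {
      stop("parameter error: all tensors must share one band", call. = FALSE)
    }
  }
  mats <- do.call(c, lapply(tensors, function(tt) {
    d <- dim(tt@values)
    if (d[1] * d[2] == 0) stop("parameter error: empty tensor", call. = FALSE)
    # flatten trial x window matrices into an n x n x nmat stack
    aperm(tt@values, c(3, 4, 1, 2))
  }))
  n <- dim(tensors[[1]]@values)[3]
  nmat <- length(mats) / (n * n)
  taus <- seq_len(gridSize) / (gridSize + 1)
  res <- .cppSweepSurprise(as.numeric(mats), c(n, n, nmat), taus,
                           as.integer(seed))
  opt <- taus[which.max(res$meanSurprise)]
  new("ThresholdSweep", band = tensors[[1]]@band, thresholds = taus,
      meanSurprise = pmax(0, res$meanSurprise),
      lccFraction = res$lccFraction, optimal = opt)
}
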