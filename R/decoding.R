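#' Assemble per-condition decoding feature matrices
#'
#' Each row is one (subject, trial, condition): the chosen feature's values
#' across the condition's windows in temporal order. With 60 trials and 7
#' windows per condition this gives a 120 x 7 matrix per subject per single
#' feature, and 120 x 14 for \code{"combined"} (degree block then modularity
#' block). Subjects are stacked row-wise with per-row metadata.
#'
#' @param features NetFeatureTable data.frame ([featuresPerWindow()] rows,
#'   possibly several subjects).
#' @param band band name to extract (e.g. "beta").
#' @param featureSet "degree", "modularity" or "combined".
#' @return list with \code{X} (matrix), \code{y} (factor pre/post),
#'   \code{rowMeta} (subject_id, trial), \code{featureSet}, \code{nSteps}.
#' @export
assembleFeatures <- function(features, band,
                             featureSet = c("degree", "modularity", "combined")) {
  featureSet <- match.arg(featureSet)
  ft <- features[features$band == band, ]
  if (!nrow(ft)) {
    stop(sprintf("parameter error: no features for band '%s'", band),
         call. = FALSE)
  }
  wPre <- sort(unique(ft$window[ft$condition == "pre"]))
  wPost <- sort(unique(ft$window[ft$condition == "post"]))
  cols <- list(degree = "k_bar", modularity = "Q",
               combined = c("k_bar", "Q"))[[featureSet]]
  rows <- list(); ys <- character(0); meta <- list()
  for (sid in unique(ft$subject_id)) {
    sub <- ft[ft$subject_id == sid, ]
    for (tr in sort(unique(sub$trial))) {
      for (cond in c("pre", "post")) {
        wins <- if (cond == "pre") wPre else wPost
        sel <- sub[sub$trial == tr & sub$condition == cond, ]
        sel <- sel[match(wins, sel$window), ]
        if (any(is.na(sel$window)) || nrow(sel) != length(wins)) {
          stop("data error: unequal window counts across trials", call. = FALSE)
        }
        rows[[length(rows) + 1L]] <- unlist(lapply(cols, function(cc) sel[[cc]]))
        ys <- c(ys, cond)
        meta[[length(meta) + 1L]] <- data.frame(subject_id = sid, trial = tr,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  X <- do.call(rbind, rows)
  colnames(X) <- unlist(lapply(cols, function(cc)
    paste0(cc, "_w", seq_len(ncol(X) / length(cols)))))
  list(X = X, y = factor(ys, levels = c("pre", "post")),
       rowMeta = do.call(rbind, meta), featureSet = featureSet,
       nSteps = ncol(X) / length(cols))
}

# stratified fold assignment: within each class, shuffle then deal round-robin
stratifiedFolds <- function(y, nFolds, seed) {
  folds <- integer(length(y))
  withSeed(seed, {
    for (cls in levels(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep(seq_len(nFolds), length.out = length(idx))
    }
  })
  folds
}

# per-column standardization fit on the training rows only
fitScaler <- function(Xtr) {
  mu <- colMeans(Xtr)
  sig <- apply(Xtr, 2, stats::sd)
  sig[sig == 0 | !is.finite(sig)] <- 1
  list(mu = mu, sig = sig)
}
applyScaler <- function(sc, X) {
  sweep(sweep(X, 2, sc$mu, "-"), 2, sc$sig, "/")
}

# reshape a flat feature matrix into batch x T x d sequences for the
# recurrent decoder (combined features become a 2-vector per window step)
toSequences <- function(X, featureSet, nSteps) {
  d <- if (featureSet == "combined") 2L else 1L
  n <- nrow(X)
  arr <- array(0, dim = c(n, nSteps, d))
  for (j in seq_len(d)) {
    arr[, , j] <- X[, ((j - 1) * nSteps + 1):(j * nSteps), drop = FALSE]
  }
  arr
}

decoderRegistry <- c("margin", "recurrent", "tree")

fitPredictDecoder <- function(decoder, Xtr, ytr, Xte, featureSet, nSteps,
                              seed) {
  if (decoder == "margin") {
    fit <- e1071::svm(x = Xtr, y = ytr, kernel = "linear", cost = 1,
                      scale = FALSE)
    pred <- stats::predict(fit, Xte, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    score <- as.vector(dv)
    # orient the decision value so larger = "post" (e1071 names the
    # decision column "<first>/<second>" with positive favouring <first>)
    if (grepl("^pre/", colnames(dv)[1])) score <- -score
    list(labels = pred, scores = score)
  } else if (decoder == "tree") {
    df <- data.frame(y = ytr, Xtr)
    fit <- rpart::rpart(y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(maxdepth = 5,
                                                       minbucket = 5,
                                                       cp = 0.001))
    te <- data.frame(Xte)
    colnames(te) <- colnames(df)[-1]
    prob <- stats::predict(fit, te, type = "prob")[, "post"]
    lab <- factor(ifelse(prob > 0.5, "post", "pre"), levels = levels(ytr))
    list(labels = lab, scores = prob)
  } else if (decoder == "recurrent") {
    par <- rnnTrain(toSequences(Xtr, featureSet, nSteps),
                    as.numeric(ytr == "post"), hidden = 16, epochs = 50,
                    lr = 1e-2, batchSize = 16, seed = seed)
    prob <- rnnPredict(par, toSequences(Xte, featureSet, nSteps))
    lab <- factor(ifelse(prob > 0.5, "post", "pre"), levels = levels(ytr))
    list(labels = lab, scores = prob)
  } else {
    stop(sprintf("parameter error: unknown decoder '%s'; registered: %s",
                 decoder, paste(decoderRegistry, collapse = ", ")),
         call. = FALSE)
  }
}

#' ROC curve and AUC from continuous scores
#'
#' Sweeps all score thresholds (higher score = positive class); the AUC is
#' the trapezoidal area, equal to the probability a random positive outscores
#' a random negative plus half the tie probability. All-equal scores give
#' AUC 0.5.
#'
#' @param scores numeric scores.
#' @param labels binary labels: logical, 0/1, or factor whose second level is
#'   the positive class.
#' @return list with \code{roc} (two-column matrix fpr, tpr from (0,0) to
#'   (1,1)) and \code{auc}.
#' @export
rocCurve <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) {
    stop("parameter error: both classes must be present for a ROC curve",
         call. = FALSE)
  }
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  fpr <- 1 - r$specificities
  tpr <- r$sensitivities
  ord <- order(fpr, tpr)
  roc <- cbind(fpr = fpr[ord], tpr = tpr[ord])
  list(roc = roc, auc = as.numeric(pROC::auc(r)))
}

#' Stratified ten-fold cross-validation of one decoder
#'
#' Rows are shuffled by the seed and dealt into \code{nFolds} folds stratified
#' by condition; per fold the decoder is fit on the remaining folds (feature
#' standardization fit on training rows only) and scored on the held-out
#' rows. Held-out continuous scores are pooled across folds into a single
#' ROC/AUC.
#'
#' @param fm feature matrix from [assembleFeatures()].
#' @param decoder "margin" (linear max-margin), "recurrent" (recurrent
#'   sequence classifier over the window sequence) or "tree" (decision tree).
#' @param seed seed for fold assignment and recurrent-net initialization.
#' @param nFolds number of folds (default 10).
#' @param groupBySubject if TRUE, folds respect subject identity (one fold
#'   per subject — leave-one-subject-out) instead of pooled stratification.
#' @return a [DecodeResult-class].
#' @export
tenFoldCv <- function(fm, decoder, seed = 1, nFolds = 10,
                      groupBySubject = FALSE) {
  if (!decoder %in% decoderRegistry) {
    stop(sprintf("parameter error: unknown decoder '%s'; registered: %s",
                 decoder, paste(decoderRegistry, collapse = ", ")),
         call. = FALSE)
  }
  if (groupBySubject) {
    subj <- factor(fm$rowMeta$subject_id)
    if (nlevels(subj) < 2) {
      stop("parameter error: subject-grouped folds need at least 2 subjects",
           call. = FALSE)
    }
    folds <- as.integer(subj)
    nFolds <- nlevels(subj)
  } else {
    if (min(table(fm$y)) < nFolds) {
      stop("parameter error: need at least nFolds rows per class",
           call. = FALSE)
    }
    folds <- stratifiedFolds(fm$y, nFolds, seed)
  }
  acc <- numeric(nFolds)
  pooledScores <- numeric(0)
  pooledLabels <- integer(0)
  for (f in seq_len(nFolds)) {
    tr <- folds != f; te <- !tr
    sc <- fitScaler(fm$X[tr, , drop = FALSE])
    Xtr <- applyScaler(sc, fm$X[tr, , drop = FALSE])
    Xte <- applyScaler(sc, fm$X[te, , drop = FALSE])
    res <- fitPredictDecoder(decoder, Xtr, fm$y[tr], Xte, fm$featureSet,
                             fm$nSteps, seed = seed + f)
    acc[f] <- mean(res$labels == fm$y[te])
    pooledScores <- c(pooledScores, res$scores)
    pooledLabels <- c(pooledLabels, as.integer(fm$y[te] == "post"))
  }
  rc <- rocCurve(pooledScores, pooledLabels)
  new("DecodeResult", featureSet = fm$featureSet, decoder = decoder,
      foldAccuracies = acc, meanAccuracy = mean(acc), roc = rc$roc,
      auc = rc$auc)
}

#' Run the full decoding suite
#'
#' Three feature sets (degree, modularity, combined) times three decoders
#' (margin, recurrent, tree), each under stratified ten-fold CV on the
#' requested band's features.
#'
#' @param features NetFeatureTable data.frame (all subjects stacked).
#' @param band band name (default "beta", the band whose features separate
#'   the conditions most clearly).
#' @param seed cross-validation / initialization seed.
#' @param decoders,featureSets subsets to run.
#' @return named list of [DecodeResult-class], keys "decoder.featureSet".
#' @export
runDecodingSuite <- function(features, band = "beta", seed = 1,
                             decoders = decoderRegistry,
                             featureSets = c("degree", "modularity", "combined")) {
  out <- list()
  for (fs in featureSets) {
    fm <- assembleFeatures(features, band, fs)
    for (dec in decoders) {
      out[[paste(dec, fs, sep = ".")]] <- tenFoldCv(fm, dec, seed = seed)
    }
  }
  out
}
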