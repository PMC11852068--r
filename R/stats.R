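#' Two-group one-way ANOVA
#'
#' Fixed-effects one-way ANOVA with two groups: F = MS_between / MS_within on
#' (1, n_a + n_b - 2) degrees of freedom, the upper tail of the F
#' distribution giving p. Algebraically identical to the squared pooled
#' two-sample t statistic. Degenerate inputs (zero within-group variance) are
#' resolved by convention: equal means give F = 0, p = 1; unequal means give
#' p = 0, each with a warning.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @return list with elements \code{F}, \code{p}, \code{df1}, \code{df2}.
#' @export
onewayAnova <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2) {
    stop("parameter error: each group needs at least 2 values", call. = FALSE)
  }
  values <- c(groupA, groupB)
  g <- factor(rep(c("a", "b"), c(length(groupA), length(groupB))))
  df2 <- length(values) - 2L
  withinVar <- sum((groupA - mean(groupA))^2) + sum((groupB - mean(groupB))^2)
  if (withinVar == 0) {
    if (mean(groupA) == mean(groupB)) {
      warning("degenerate ANOVA: no variance anywhere; F = 0, p = 1")
      return(list(F = 0, p = 1, df1 = 1L, df2 = df2))
    }
    warning("degenerate ANOVA: zero within-group variance, unequal means; p = 0")
    return(list(F = Inf, p = 0, df1 = 1L, df2 = df2))
  }
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       df1 = 1L, df2 = df2)
}

significanceMark <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s."))
}

#' Pre/post comparison of network features
#'
#' One ANOVA per (subject, band, feature in {k_bar, Q}) comparing all
#' pre-labelled against all post-labelled values, marked "**" for p < 0.01,
#' "*" for p < 0.05 and "n.s." otherwise. By default each trial-window value
#' is an observation; \code{pool = "trial"} first averages windows within
#' each (trial, condition).
#'
#' @param features NetFeatureTable data.frame from [featuresPerWindow()]
#'   (rows from several subjects/bands may be concatenated).
#' @param pool observation granularity, "window" (default) or "trial".
#' @return data.frame with one row per (subject, band, feature): counts,
#'   F, p and the significance mark.
#' @export
compareConditions <- function(features, pool = c("window", "trial")) {
  pool <- match.arg(pool)
  if (pool == "trial") {
    features <- stats::aggregate(
      cbind(k_bar, Q) ~ subject_id + band + trial + condition,
      data = features, FUN = mean)
  }
  out <- list()
  for (sid in unique(features$subject_id)) {
    for (bnd in unique(features$band[features$subject_id == sid])) {
      cell <- features[features$subject_id == sid & features$band == bnd, ]
      for (feat in c("k_bar", "Q")) {
        pre <- cell[[feat]][cell$condition == "pre"]
        post <- cell[[feat]][cell$condition == "post"]
        if (length(pre) < 2 || length(post) < 2) {
          warning(sprintf("skipping %s/%s/%s: a condition is missing",
                          sid, bnd, feat))
          next
        }
        a <- onewayAnova(pre, post)
        out[[length(out) + 1L]] <- data.frame(
          subject_id = sid, band = bnd, feature = feat,
          n_pre = length(pre), n_post = length(post),
          mean_pre = mean(pre), mean_post = mean(post),
          F = a$F, p = a$p, mark = significanceMark(a$p),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Mean +/- SD summary of network features
#'
#' Mean and sample (n - 1 denominator) standard deviation per
#' (subject, band, condition, feature), with a "mean +/- sd" string formatted
#' to two decimals — the conventional per-bird summary table layout
#' (bands x before/after rows, subjects as columns, one block per feature).
#'
#' @param features NetFeatureTable data.frame.
#' @return list with \code{long} (tidy rows) and \code{wide} (the formatted
#'   table: feature/band/state rows by subject columns).
#' @export
summarizeFeatures <- function(features) {
  if (!nrow(features)) stop("parameter error: empty feature table", call. = FALSE)
  long <- list()
  for (feat in c("k_bar", "Q")) {
    agg <- stats::aggregate(features[[feat]],
      by = list(subject_id = features$subject_id, band = features$band,
                condition = features$condition),
      FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
    df <- data.frame(agg[, 1:3],
                     feature = feat,
                     mean = agg$x[, "mean"],
                     sd = agg$x[, "sd"],
                     stringsAsFactors = FALSE)
    df$sd[is.na(df$sd)] <- 0
    df$formatted <- sprintf("%.2f ± %.2f", df$mean, df$sd)
    long[[feat]] <- df
  }
  long <- do.call(rbind, long)
  rownames(long) <- NULL
  # wide layout: state follows trial chronology (before = pre)
  long$state <- ifelse(long$condition == "pre", "before", "after")
  wide <- stats::reshape(
    long[, c("feature", "band", "state", "subject_id", "formatted")],
    idvar = c("feature", "band", "state"), timevar = "subject_id",
    direction = "wide")
  names(wide) <- sub("^formatted\\.", "", names(wide))
  ord <- order(match(wide$feature, c("k_bar", "Q")),
               match(wide$band, names(canonicalBands())),
               match(wide$state, c("before", "after")))
  wide <- wide[ord, ]
  rownames(wide) <- NULL
  list(long = long[, c("subject_id", "band", "condition", "feature",
                       "mean", "sd", "formatted")],
       wide = wide)
}
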