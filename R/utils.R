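#' Evaluate code under a temporary RNG state
#'
#' Runs \code{code} with the global RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so seeded internals never perturb user code.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# scalar checks used by constructors; error message names the offending field
assertScalar <- function(x, field, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("configuration error: '%s' must be a single finite number", field),
         call. = FALSE)
  }
  if (x < min || x > max) {
    stop(sprintf("configuration error: '%s' = %g is outside [%g, %g]",
                 field, x, min, max), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("configuration error: '%s' must be an integer", field),
         call. = FALSE)
  }
  invisible(x)
}

# strict upper-triangle mean of a square matrix
upperTriMean <- function(x) {
  mean(x[upper.tri(x)])
}
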