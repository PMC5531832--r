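#' Evaluate code with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so schedule/simulation functions are deterministic without
#' clobbering the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Derive child seeds from a root seed
#'
#' One root seed per cohort, one child per subject, grandchildren per
#' session: any subject or session is reproducible in isolation.
#'
#' @param seed Root seed.
#' @param n Number of children.
#' @return Integer vector of length `n`, all below 2^31.
#' @keywords internal
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Truncated-normal sampler by rejection
#'
#' @param n Number of draws.
#' @param mean,sd Normal parameters.
#' @param lower,upper Truncation bounds.
#' @return Numeric vector of draws within `[lower, upper]`.
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## data.frame constructor without the deparse/recycling overhead of
## data.frame(); columns must be equal-length atomic vectors (length-1
## columns are recycled).
fast_df <- function(cols) {
  n <- max(lengths(cols))
  cols <- lapply(cols, function(x) if (length(x) == 1L) rep(x, n) else x)
  structure(cols, class = "data.frame", row.names = c(NA_integer_, -n))
}
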