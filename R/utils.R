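# Internal helpers shared across modules.

#' Derive a reproducible child seed from a root seed
#'
#' Mixes a root seed with one or more integer stream identifiers so that
#' independent stochastic stages (replicates, simulations, pipeline steps)
#' get distinct but reproducible RNG streams. The result is always a
#' positive integer below 2^31.
#'
#' @param seed Integer root seed.
#' @param ... Integer stream identifiers (e.g. replicate index).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (x in ids) {
    # 32-bit multiplicative mix kept in double precision (exact below 2^53)
    h <- (h * 69069 + as.numeric(x) + 1) %% 2147483629
  }
  as.integer(h %% 2147483563 + 1)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

#' Clamp frequencies away from the boundaries
#'
#' Frequencies of 0 or 1 are undefined on the logit scale; they are moved to
#' `1/(2*coverage)` and `1 - 1/(2*coverage)`, the resolution limit of a read
#' sample of the given depth.
#'
#' @param p Numeric vector of frequencies.
#' @param coverage Read depth used to set the clamp bound.
#' @return Clamped frequencies, strictly inside (0, 1).
#' @export
clamp_freq <- function(p, coverage) {
  eps <- 1 / (2 * coverage)
  pmin(pmax(p, eps), 1 - eps)
}

stopifnot_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}
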