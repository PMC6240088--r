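# Internal numerical helpers shared across modules.

#' Numerically stable softmax
#'
#' @param x numeric vector of log weights; `-Inf` entries are allowed and map
#'   to probability zero (provided at least one entry is finite).
#' @return probability vector of the same length summing to 1.
#' @keywords internal
softmax <- function(x) {
  m <- max(x)
  if (!is.finite(m)) stop("softmax: no finite entry in input")
  e <- exp(x - m)
  e / sum(e)
}

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# x * log(x) with the convention 0 * log(0) = 0
#' @keywords internal
xlogx <- function(x) {
  out <- x * log(x)
  out[x == 0] <- 0
  out
}

# Deterministic sub-seed derivation: one user-facing seed is expanded into
# independent per-purpose streams so that, e.g., redrawing the site map does
# not shift the source or stimulus draws. Knuth multiplicative hashing on the
# purpose string, folded into 31 bits.
#' @keywords internal
derive_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(purpose)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((abs(seed) * 2654435761 + h + 1) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  expr
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_if_not_binary <- function(x, what) {
  if (!all(x %in% c(0L, 1L))) {
    stop(sprintf("%s must contain only 0/1 entries", what), call. = FALSE)
  }
}
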