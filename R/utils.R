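#' @keywords internal
"_PACKAGE"

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logit <- function(p) stats::qlogis(p)
invlogit <- function(x) stats::plogis(x)

#' Derive a child RNG seed from a base seed
#'
#' Deterministic stream splitting so that every stage of a pipeline run can
#' be seeded from one user-supplied integer without seed collisions.
#' Kept below 2^31 so the result is always a valid R integer seed.
#'
#' @param seed base integer seed.
#' @param k stream index (1, 2, ...).
#' @return an integer seed.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629) + 1L
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}
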