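#' Freeman-Tukey posterior predictive check
#'
#' For each posterior draw, detections are aggregated to site-year counts
#' and compared with their model-marginal expectation
#' `e[i,t] = pi[i,t] * sum_j p[i,t,j]` (realised visits only), where `pi`
#' is the model-marginal occupancy probability — not conditioned on the
#' observed data — so the observed and replicated discrepancies are
#' exchangeable under the model.  The discrepancy is
#' `T = sum (sqrt(y) - sqrt(e))^2`; a replicate dataset is drawn from the
#' generative model at the same draw and the Bayesian p-value is
#' `Pr(T_rep >= T_obs)`.  Values near 0.5 indicate adequate fit; values
#' near 0 or 1 indicate over/under-dispersion.
#'
#' @param fit an `occu_fit`.
#' @param seed integer RNG seed for the replicate simulations.
#' @param draw_ids optional subset of draws (all by default).
#' @return object of class `ppc_result`: `p_value`, `T_obs`, `T_rep`.
#' @export
freeman_tukey_ppc <- function(fit, seed = 1L, draw_ids = NULL) {
  design <- fit$design
  ids <- if (is.null(draw_ids)) seq_len(nrow(fit$draws)) else draw_ids
  set.seed(as.integer(seed))
  S <- design$S; T <- design$T; J <- design$J
  realised <- !design$miss
  nvis <- apply(realised, c(1, 2), sum)        # S x T realised visit counts
  yobs <- apply(design$y, c(1, 2), sum, na.rm = TRUE)
  use <- design$surveyed
  T_obs <- numeric(length(ids)); T_rep <- numeric(length(ids))
  for (d in seq_along(ids)) {
    pr <- occu_probs(fit$draws[ids[d], ], design)
    pi <- marginal_occupancy(pr, design)
    psum <- matrix(0, S, T)
    for (j in seq_len(J)) {
      pj <- matrix(pr$p[, , j], S, T)
      pj[!matrix(realised[, , j], S, T)] <- 0
      psum <- psum + pj
    }
    e <- pi * psum
    T_obs[d] <- sum((sqrt(yobs[use]) - sqrt(e[use]))^2)
    # replicate from the generative model at this draw
    z <- matrix(0L, S, T)
    z[, 1] <- stats::rbinom(S, 1L, pr$psi1)
    if (T > 1L) for (t in 2:T) {
      pt <- ifelse(z[, t - 1] == 1L, pr$psiC[, t], pr$psi0[, t])
      z[, t] <- stats::rbinom(S, 1L, pt)
    }
    yrep <- matrix(0, S, T)
    for (j in seq_len(J)) {
      pj <- matrix(pr$p[, , j], S, T) * z
      pj[!matrix(realised[, , j], S, T)] <- 0
      yrep <- yrep + matrix(stats::rbinom(S * T, 1L, as.vector(pj)), S, T)
    }
    T_rep[d] <- sum((sqrt(yrep[use]) - sqrt(e[use]))^2)
  }
  structure(list(p_value = mean(T_rep >= T_obs), T_obs = T_obs, T_rep = T_rep),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("Freeman-Tukey Bayesian p = %.3f (%d draws)\n",
              x$p_value, length(x$T_obs)))
  invisible(x)
}
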