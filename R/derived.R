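#' Yearly derived parameters from a fitted occupancy model
#'
#' For each posterior draw: the expected number of used transects
#' `n.occ_t` is the sum of smoothed latent-state probabilities
#' `Pr(z[i,t] = 1 | data)` over sites surveyed in year t; the average
#' habitat-use probability is `n.occ_t / S_t`; and mean detection is the
#' average of `p[i,t,j]` over realised surveys only.  Reported values are
#' posterior means with posterior SDs as SEs (the usual Est./SE table
#' shape).  Years with no surveyed sites yield `NA` rows.
#'
#' @param fit an `occu_fit`.
#' @param draw_ids optional subset of draws (all by default).
#' @return data frame with one row per year: `psi`, `psi_se`, `p`, `p_se`,
#'   `n_occ`, `n_occ_se`, `n_surveyed`.
#' @export
derived_parameters <- function(fit, draw_ids = NULL) {
  design <- fit$design
  ids <- if (is.null(draw_ids)) seq_len(nrow(fit$draws)) else draw_ids
  T <- design$T
  surveyed <- design$surveyed                 # S x T logical
  S_t <- colSums(surveyed)
  nd <- length(ids)
  nocc <- matrix(NA_real_, nd, T)
  pbar <- matrix(NA_real_, nd, T)
  realised <- !design$miss                    # S x T x J
  for (d in seq_len(nd)) {
    par <- fit$draws[ids[d], ]
    zs <- smoothed_z(par, design)
    pr <- occu_probs(par, design)
    for (t in seq_len(T)) {
      if (S_t[t] == 0L) next
      nocc[d, t] <- sum(zs[surveyed[, t], t])
      pt <- pr$p[, t, , drop = FALSE][, 1, ]
      pbar[d, t] <- mean(pt[realised[, t, , drop = FALSE][, 1, ]])
    }
  }
  psibar <- sweep(nocc, 2L, pmax(S_t, 1L), "/")
  data.frame(year = seq_len(T),
             psi = colMeans(psibar), psi_se = apply(psibar, 2L, stats::sd),
             p = colMeans(pbar), p_se = apply(pbar, 2L, stats::sd),
             n_occ = colMeans(nocc), n_occ_se = apply(nocc, 2L, stats::sd),
             n_surveyed = S_t)
}

#' Posterior direction of a coefficient
#'
#' The percentage of posterior draws sharing the sign of the posterior
#' mean; draws exactly at zero count half.  By construction the value lies
#' in [50, 100].  An all-zero posterior returns 50 with a warning.
#'
#' @param x numeric vector of posterior draws for one parameter.
#' @return percentage in `[50, 100]`.
#' @export
posterior_direction <- function(x) {
  if (!length(x)) stop("no draws supplied", call. = FALSE)
  m <- mean(x)
  if (all(x == 0)) {
    warning("all draws are zero; posterior direction undefined, returning 50")
    return(50)
  }
  if (m == 0) warning("posterior mean is exactly zero; direction is a tie")
  s <- if (m >= 0) 1 else -1
  100 * (sum(sign(x) == s) + 0.5 * sum(x == 0)) / length(x)
}
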