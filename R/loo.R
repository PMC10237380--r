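# Leave-one-out cross-validation by Pareto-smoothed importance sampling,
# with an exact refit alternative for small problems.  The exchangeable
# unit is the site (one transect's full multi-year history).

#' Per-site log pointwise predictive density
#'
#' `lpd_i = log( mean_d exp(loglik[d, i]) )` computed with log-sum-exp
#' stability.  Draws with non-finite likelihood for a site are dropped for
#' that site with a warning.
#'
#' @param loglik matrix `draws x sites` of per-site log-likelihoods (see
#'   [pointwise_loglik()]).
#' @return numeric vector of per-site lpd values.
#' @export
pointwise_lpd <- function(loglik) {
  nbad <- sum(!is.finite(loglik) & !is.na(loglik) & loglik != -Inf)
  if (nbad) warning(sprintf("%d non-finite likelihood values excluded", nbad))
  apply(loglik, 2L, function(x) {
    x <- x[is.finite(x) | x == -Inf]
    logsumexp(x) - log(length(x))
  })
}

#' Generalized-Pareto shape fit (Zhang-Stephens profile estimator)
#'
#' Fits GPD(k, sigma) to exceedances `x > 0` by the empirical-Bayes
#' profile-likelihood method used in PSIS; `k` is reported with the weak
#' n-dependent regularisation toward 0.5.
#'
#' @param x positive exceedances.
#' @return list with `k` and `sigma`.
#' @export
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / prior / xstar
  profile_ll <- vapply(theta, function(th) {
    k <- -mean(log1p(-th * x))
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- exp(profile_ll - max(profile_ll))
  w <- w / sum(w)
  th_hat <- sum(theta * w)
  k <- mean(log1p(-th_hat * x))   # shape (positive = heavy tail)
  sigma <- -k / th_hat
  # regularise k towards 0.5 with 10 pseudo-observations
  k <- (n * k + 5) / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smooth one site's log importance ratios; returns smoothed log
# weights and the tail shape k.
psis_smooth <- function(logr) {
  Sd <- length(logr)
  logr <- logr - max(logr)
  M <- ceiling(min(0.2 * Sd, 3 * sqrt(Sd)))
  if (M < 5L || stats::sd(logr) < 1e-12) {
    return(list(logw = logr, k = -Inf, smoothed = FALSE))
  }
  ord <- order(logr)
  tail_ids <- ord[(Sd - M + 1L):Sd]
  cutoff <- logr[ord[Sd - M]]
  exceed <- exp(logr[tail_ids]) - exp(cutoff)
  if (max(exceed) <= 0) return(list(logw = logr, k = -Inf, smoothed = FALSE))
  fit <- gpd_fit(exceed[exceed > 0])
  qq <- qgpd((rank(logr[tail_ids], ties.method = "first") - 0.5) / M,
             fit$k, fit$sigma)
  sm <- log(exp(cutoff) + qq)
  sm <- pmin(sm, 0)          # never exceed the max raw (normalised) weight
  logw <- logr
  logw[tail_ids] <- sm
  list(logw = logw, k = fit$k, smoothed = TRUE)
}

#' PSIS-LOO expected log predictive density
#'
#' Importance ratios `1 / L_i(theta_d)` per site, Pareto-smoothing of the
#' largest 20% of ratios, and the smoothed-weight estimate of each site's
#' leave-one-out predictive density.  Sites with tail shape `k > 0.7` are
#' flagged as unreliable.  Degenerate (all-equal) ratios fall back to
#' unsmoothed weights.
#'
#' @param loglik matrix `draws x sites`.
#' @return object of class `loo_result`: `elpd`, `se`, `pointwise`
#'   (per-site contributions), `pareto_k` (per site), `p_loo` (effective
#'   parameter count `sum(lpd_i - elpd_i)`).
#' @export
psis_loo <- function(loglik) {
  if (nrow(loglik) < 100L) {
    warning("fewer than 100 draws; PSIS tail fit may be unstable")
  }
  Ssites <- ncol(loglik)
  pw <- numeric(Ssites); kk <- numeric(Ssites)
  n_fallback <- 0L
  for (i in seq_len(Ssites)) {
    li <- loglik[, i]
    sm <- psis_smooth(-li)
    if (!sm$smoothed) n_fallback <- n_fallback + 1L
    # elpd_i = log( sum w_d L_d / sum w_d )
    pw[i] <- logsumexp(sm$logw + li) - logsumexp(sm$logw)
    kk[i] <- sm$k
  }
  if (n_fallback) {
    warning(sprintf("degenerate importance-ratio tail for %d site(s); unsmoothed weights used",
                    n_fallback))
  }
  lpd <- pointwise_lpd(loglik)
  structure(list(elpd = sum(pw), se = sqrt(Ssites * stats::var(pw)),
                 pointwise = pw, pareto_k = kk, lpd = lpd,
                 p_loo = sum(lpd - pw),
                 n_sites = Ssites, n_draws = nrow(loglik),
                 high_k = which(kk > 0.7)),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("elpd_loo %.2f (SE %.2f), p_loo %.2f, %d sites, %d draws\n",
              x$elpd, x$se, x$p_loo, x$n_sites, x$n_draws))
  if (length(x$high_k)) {
    cat(sprintf("  %d site(s) with Pareto k > 0.7: %s\n", length(x$high_k),
                paste(x$high_k, collapse = ", ")))
  }
  invisible(x)
}

#' Exact leave-one-out cross-validation by refitting
#'
#' Refits the model without each site and evaluates that site's predictive
#' density under the reduced posterior.  Feasible for small site counts;
#' the oracle against which PSIS-LOO is validated.
#'
#' @param design an [occu_design()].
#' @param chains,iter,warmup,seed MCMC settings for each refit.
#' @return object of class `loo_result` (with `pareto_k = NA`).
#' @export
loo_exact <- function(design, chains = 2L, iter = 1500L, warmup = 750L,
                      seed = 1L) {
  S <- design$S
  pw <- numeric(S)
  for (i in seq_len(S)) {
    di <- drop_site(design, i)
    fit_i <- fit_occu_design(di, chains = chains, iter = iter,
                             warmup = warmup, seed = child_seed(seed, i))
    # design holding only site i, for evaluating its likelihood
    d1 <- keep_site(design, i)
    ll_i <- vapply(seq_len(nrow(fit_i$draws)), function(d) {
      site_log_likelihood(fit_i$draws[d, ], d1)
    }, numeric(1))
    pw[i] <- logsumexp(ll_i) - log(length(ll_i))
  }
  structure(list(elpd = sum(pw), se = sqrt(S * stats::var(pw)),
                 pointwise = pw, pareto_k = rep(NA_real_, S), lpd = NULL,
                 p_loo = NA_real_, n_sites = S, n_draws = NA_integer_,
                 high_k = integer()),
            class = "loo_result")
}

subset_design <- function(design, keep) {
  structure(list(spec = design$spec,
                 y = design$y[keep, , , drop = FALSE],
                 miss = design$miss[keep, , , drop = FALSE],
                 surveyed = design$surveyed[keep, , drop = FALSE],
                 Xpsi = design$Xpsi[keep, , , drop = FALSE],
                 W = design$W[keep, , , , drop = FALSE],
                 S = length(keep), T = design$T, J = design$J,
                 K = design$K, L = design$L,
                 par_names = design$par_names, n_par = design$n_par),
            class = "occu_design")
}
drop_site <- function(design, i) subset_design(design, setdiff(seq_len(design$S), i))
keep_site <- function(design, i) subset_design(design, i)

#' Compare models by ELPD difference
#'
#' @param loos named list of `loo_result` objects.
#' @return data frame ranked by elpd, with pairwise differences to the top
#'   model and the SE of each difference (from pointwise contributions).
#' @export
loo_compare_models <- function(loos) {
  stopifnot(length(loos) >= 1L)
  elpd <- vapply(loos, function(l) l$elpd, numeric(1))
  ord <- order(-elpd)
  top <- loos[[ord[1]]]
  rows <- lapply(seq_along(ord), function(r) {
    l <- loos[[ord[r]]]
    dif <- l$pointwise - top$pointwise
    data.frame(model = names(loos)[ord[r]], elpd = l$elpd, se = l$se,
               delta_elpd = sum(dif),
               delta_se = sqrt(length(dif) * stats::var(dif)),
               p_loo = l$p_loo, max_k = suppressWarnings(max(l$pareto_k)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
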