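#' Generative parameters for the auto-logistic occupancy simulator
#'
#' Defaults mirror the study design the package emulates: 37 transects,
#' 4 years, up to 3 visits per year with an incomplete first-year visit
#' pattern, a removal treatment on 18 transects beginning in the final
#' year, a positive juniper effect on habitat use and a year-varying
#' detection intercept giving detection probabilities near 0.4-0.6.
#'
#' @param beta0 habitat-use (psi) intercept on the logit scale.
#' @param beta named numeric vector of psi-covariate coefficients (logit
#'   scale per SD of the standardized covariate).
#' @param theta auto-logistic carry-over: the additive logit effect of
#'   occupancy in the previous year.
#' @param alpha year-specific detection intercepts (length `n_years`).
#' @param gamma named numeric vector of detection-covariate coefficients.
#' @param n_sites,n_years,visits_per_year design dimensions.
#' @param missing_pattern integer matrix `n_sites x n_years` of realised
#'   visits per site-year (0 = unsurveyed); `NULL` = all visits realised.
#'   See [year1_missing_pattern()].
#' @param removal_year index (in 1..n_years) of the first post-removal
#'   year, or `NA` for no treatment.
#' @return a `sim_params` list.
#' @export
sim_params <- function(beta0 = 0.8,
                       beta = c(juniper_100 = 1.74),
                       theta = 1,
                       alpha = c(-0.28, -0.2, 0.32, 0.32),
                       gamma = c(tri = 0.22),
                       n_sites = 37L, n_years = 4L, visits_per_year = 3L,
                       missing_pattern = NULL, removal_year = 4L) {
  p <- list(beta0 = beta0, beta = beta, theta = theta, alpha = alpha,
            gamma = gamma, n_sites = as.integer(n_sites),
            n_years = as.integer(n_years),
            visits_per_year = as.integer(visits_per_year),
            missing_pattern = missing_pattern,
            removal_year = removal_year)
  stopifnot(all(is.finite(c(beta0, beta, theta, alpha, gamma))),
            p$n_years >= 1L, p$visits_per_year >= 1L,
            length(alpha) == p$n_years,
            is.na(removal_year) || (removal_year >= 1 && removal_year <= p$n_years))
  class(p) <- "sim_params"
  p
}

#' First-year incomplete visit pattern
#'
#' Visits-per-site vector for the first season of the emulated design:
#' of 37 transects, 30 were surveyed (18 with three visits, 10 with two,
#' 2 with one; 76 surveys) and 7 not at all.  The published counts are
#' internally inconsistent; this is the unique allocation consistent with
#' 30 surveyed transects and 76 total surveys.
#'
#' @param n_sites total number of sites (default 37).
#' @param n3,n2,n1 sites with 3, 2, 1 visits (defaults 18, 10, 2).
#' @param n_years number of seasons; later seasons get all visits.
#' @param visits_per_year maximum visits per season.
#' @return integer matrix `n_sites x n_years` of realised visits.
#' @export
year1_missing_pattern <- function(n_sites = 37L, n3 = 18L, n2 = 10L, n1 = 2L,
                                  n_years = 4L, visits_per_year = 3L) {
  if (n3 + n2 + n1 > n_sites) stop("visit pattern exceeds n_sites", call. = FALSE)
  v1 <- c(rep(3L, n3), rep(2L, n2), rep(1L, n1),
          rep(0L, n_sites - n3 - n2 - n1))
  m <- matrix(visits_per_year, n_sites, n_years)
  m[, 1] <- pmin(v1, visits_per_year)
  m
}

#' Simulate detection histories from the auto-logistic occupancy model
#'
#' First-year occupancy is Bernoulli with
#' `logit(psi[i,1]) = beta0 + beta'x[i,1]`; in later years
#' `logit(psi[i,t]) = beta0 + beta'x[i,t] + theta * z[i,t-1]`.  Detections
#' are Bernoulli `z[i,t] * p[i,t,j]` with
#' `logit(p[i,t,j]) = alpha[t] + gamma'w[i,t,j]`.  Unrealised visits are
#' `NA`.
#'
#' @param params a [sim_params()] object.
#' @param site_covs array `n_sites x n_years x length(beta)` of
#'   psi-covariates (already standardized), or a matrix `n_sites x
#'   length(beta)` recycled across years; `NULL` if `beta` is empty.
#' @param survey_covs array `n_sites x n_years x visits x length(gamma)` of
#'   detection covariates (or matrix `n_sites x length(gamma)` recycled);
#'   `NULL` if `gamma` is empty.
#' @param seed integer RNG seed.
#' @return list with `y` (`n_sites x n_years x visits` 0/1/NA array),
#'   `z` (true latent states), `psi`, `p` (the generative probabilities).
#' @export
simulate_detection_histories <- function(params, site_covs = NULL,
                                         survey_covs = NULL, seed = 1L) {
  S <- params$n_sites; T <- params$n_years; J <- params$visits_per_year
  X <- expand_site_covs(site_covs, S, T, length(params$beta))
  W <- expand_survey_covs(survey_covs, S, T, J, length(params$gamma))
  set.seed(as.integer(seed))

  eta <- matrix(params$beta0, S, T)
  if (length(params$beta)) {
    for (t in seq_len(T)) {
      eta[, t] <- eta[, t] +
        drop(matrix(X[, t, ], nrow = S) %*% params$beta)
    }
  }
  z <- matrix(0L, S, T)
  psi <- matrix(NA_real_, S, T)
  psi[, 1] <- invlogit(eta[, 1])
  z[, 1] <- stats::rbinom(S, 1L, psi[, 1])
  if (T > 1L) for (t in 2:T) {
    psi[, t] <- invlogit(eta[, t] + params$theta * z[, t - 1])
    z[, t] <- stats::rbinom(S, 1L, psi[, t])
  }

  p <- array(NA_real_, c(S, T, J))
  y <- array(NA_integer_, c(S, T, J))
  vis <- params$missing_pattern
  if (is.null(vis)) vis <- matrix(J, S, T)
  for (t in seq_len(T)) for (j in seq_len(J)) {
    lp <- rep(params$alpha[t], S)
    if (length(params$gamma)) {
      lp <- lp + drop(matrix(W[, t, j, ], nrow = S) %*% params$gamma)
    }
    p[, t, j] <- invlogit(lp)
    realised <- vis[, t] >= j
    y[realised, t, j] <- stats::rbinom(sum(realised), 1L,
                                       z[realised, t] * p[realised, t, j])
  }
  dimnames(y) <- list(site = NULL, year = NULL, visit = NULL)
  list(y = y, z = z, psi = psi, p = p)
}

expand_site_covs <- function(x, S, T, K) {
  if (K == 0L) return(array(0, c(S, T, 0L)))
  if (is.null(x)) stop("psi covariates required but `site_covs` is NULL", call. = FALSE)
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    if (!identical(dim(x), c(S, K))) {
      stop(sprintf("site covariate matrix must be %d x %d", S, K), call. = FALSE)
    }
    x <- array(rep(x, times = T), c(S, K, T))
    x <- aperm(x, c(1, 3, 2))
  }
  if (!identical(dim(x), c(S, T, K))) {
    stop(sprintf("site covariate array must be %d x %d x %d", S, T, K), call. = FALSE)
  }
  x
}

expand_survey_covs <- function(w, S, T, J, L) {
  if (L == 0L) return(array(0, c(S, T, J, 0L)))
  if (is.null(w)) stop("detection covariates required but `survey_covs` is NULL", call. = FALSE)
  if (is.matrix(w) || is.data.frame(w)) {
    w <- as.matrix(w)
    if (!identical(dim(w), c(S, L))) {
      stop(sprintf("survey covariate matrix must be %d x %d", S, L), call. = FALSE)
    }
    w <- array(rep(w, times = T * J), c(S, L, T, J))
    w <- aperm(w, c(1, 3, 4, 2))
  }
  if (!identical(dim(w), c(S, T, J, L))) {
    stop(sprintf("survey covariate array must be %d x %d x %d x %d", S, T, J, L),
         call. = FALSE)
  }
  w
}

#' Simulate prey layers for a set of sites
#'
#' Deer-mouse density is quadratic in juniper cover within 100 m, peaking
#' at a configurable cover (10% by default, matching the pattern that
#' densities are highest near 10% cover and decline into woodland);
#' pocket-mouse density is quadratic in mean sagebrush cover; songbird
#' relative abundance is a non-negative noisy function of cover; ground-
#' squirrel presence is drawn once per site and held constant across years.
#'
#' @param site_covs data frame with `juniper_100` and `sagebrush` (percent).
#' @param prey_coefficients list with `deer`, `pocket` quadratics
#'   (see [default_prey_coefficients()]), `songbird = c(intercept, slope,
#'   quad, sd)` and `squirrel_prob`.
#' @param n_years years over which squirrel presence is replicated.
#' @param seed integer RNG seed.
#' @return data frame, one row per site, with prey columns; attribute
#'   `"squirrel_by_year"` is the sites x years presence matrix (constant
#'   across columns by construction).
#' @export
simulate_prey_layers <- function(site_covs,
                                 prey_coefficients = default_prey_coefficients(),
                                 n_years = 4L, seed = 1L) {
  set.seed(as.integer(seed))
  n <- nrow(site_covs)
  sb <- prey_coefficients$songbird
  song <- sb[1] + sb[2] * site_covs$juniper_100 + sb[3] * site_covs$juniper_100^2 +
    stats::rnorm(n, 0, sb[4])
  squirrel <- stats::rbinom(n, 1L, prey_coefficients$squirrel_prob)
  out <- predict_prey_covariates(site_covs, prey_coefficients,
                                 squirrel = squirrel)
  out$songbird_abundance <- pmax(song, 0)
  attr(out, "squirrel_by_year") <- matrix(squirrel, n, n_years)
  out
}

#' Default synthetic prey-model coefficients
#'
#' Quadratics on the percent-cover scale chosen to reproduce the
#' qualitative shapes of the fitted prey models (deer-mouse density peaks
#' near 10% juniper cover and declines into woodland); the source study's
#' coefficients are not published, so these are synthetic stand-ins.
#'
#' @param deer_peak cover (%) at which deer-mouse density peaks.
#' @return coefficient list for [simulate_prey_layers()].
#' @export
default_prey_coefficients <- function(deer_peak = 10) {
  c2 <- -0.05
  list(deer = c(15, -2 * c2 * deer_peak, c2),    # vertex at deer_peak
       pocket = c(2, 0.6, -0.02),                # vertex at 15% sagebrush
       songbird = c(4, 0.25, -0.012, 1),         # rises then falls, sd 1
       squirrel_prob = 0.4)
}
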