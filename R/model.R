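#' Declare an auto-logistic multi-season occupancy model
#'
#' Habitat-use (psi) and detection (p) structures are given as one-sided
#' formulas over covariate columns; year-specific detection intercepts are
#' always included, and the auto-logistic carry-over term `theta` (the
#' previous year's latent state entering the current year's occupancy
#' logit) is on by default.  All coefficients, intercepts and `theta`
#' receive independent Normal(0, sd = `prior_sd`) priors; the default
#' `prior_sd = 10` corresponds to precision 0.01.
#'
#' @param psi one-sided formula for the occupancy/use linear predictor
#'   (intercept handled separately; quadratic and interaction terms via the
#'   usual formula syntax).
#' @param det one-sided formula for detection covariates (on top of the
#'   year intercepts).
#' @param autologistic include the carry-over term `theta`?
#' @param prior_sd prior standard deviation for all parameters.
#' @param name optional model label used in ranking reports.
#' @return an `occu_spec`.
#' @export
occu_spec <- function(psi = ~1, det = ~1, autologistic = TRUE, prior_sd = 10,
                      name = NULL) {
  stopifnot(inherits(psi, "formula"), inherits(det, "formula"),
            is.finite(prior_sd), prior_sd > 0)
  if (is.null(name)) {
    name <- sprintf("psi(%s) p(%s)%s", deparse(psi[[2]]), deparse(det[[2]]),
                    if (autologistic) " +theta" else "")
  }
  structure(list(psi = psi, det = det, autologistic = isTRUE(autologistic),
                 prior_sd = prior_sd, name = name),
            class = "occu_spec")
}

#' Bind a model specification to detection data and covariates
#'
#' Builds the design arrays the marginalized likelihood consumes.  `y` may
#' contain `NA` for unrealised visits; a site-year with no realised visits
#' contributes only its state transition to the likelihood.
#'
#' @param spec an [occu_spec()].
#' @param y detection array `sites x years x visits` with values 0/1/NA.
#' @param site_covs site(-year) covariates: a data frame with one row per
#'   site (constant across years) or long format keyed by `site` and
#'   `year` columns.
#' @param survey_covs visit-level covariates: per-site, per site-year, or
#'   long format keyed by `site`, `year`, `visit`.  Detection-formula
#'   variables are looked up in `site_covs` first and `survey_covs`
#'   second, so site-level detection covariates (e.g. terrain roughness)
#'   need not be replicated per visit.
#' @return an `occu_design` with elements `y`, `Xpsi` (S x T x K),
#'   `W` (S x T x J x L), parameter template and bookkeeping masks.
#' @export
occu_design <- function(spec, y, site_covs = NULL, survey_covs = NULL) {
  stopifnot(inherits(spec, "occu_spec"))
  if (!is.array(y) || length(dim(y)) != 3L) {
    stop("`y` must be a sites x years x visits array", call. = FALSE)
  }
  bad <- !(y %in% c(0L, 1L)) & !is.na(y)
  if (any(bad)) stop("`y` values must be 0, 1 or NA", call. = FALSE)
  S <- dim(y)[1]; T <- dim(y)[2]; J <- dim(y)[3]

  Xpsi <- formula_array_site(spec$psi, site_covs, S, T)
  W <- formula_array_survey(spec$det, site_covs, survey_covs, S, T, J)
  K <- dim(Xpsi)[3]; L <- dim(W)[4]

  par_names <- c("beta0",
                 if (K) paste0("beta_", dimnames(Xpsi)[[3]]),
                 if (spec$autologistic) "theta",
                 paste0("alpha_", seq_len(T)),
                 if (L) paste0("gamma_", dimnames(W)[[4]]))
  miss <- is.na(y)
  structure(list(spec = spec, y = y, miss = miss,
                 surveyed = apply(!miss, c(1, 2), any),
                 Xpsi = Xpsi, W = W, S = S, T = T, J = J, K = K, L = L,
                 par_names = par_names, n_par = length(par_names)),
            class = "occu_design")
}

# Expand a covariate table onto a long index frame.  Tables may be
# per-site (S rows), per site-year (site + year columns), or per
# site-year-visit (site + year + visit columns); columns already present
# in `idx` are overwritten by later tables.
merge_onto_index <- function(idx, covs, S, T, J = NULL) {
  if (is.null(covs)) return(idx)
  covs <- as.data.frame(covs)
  key_cols <- intersect(c("site", "year", "visit"), names(covs))
  rows <- if (all(c("site", "year", "visit") %in% key_cols) &&
              !is.null(idx$visit)) {
    match(interaction(idx$site, idx$year, idx$visit, drop = FALSE),
          interaction(covs$site, covs$year, covs$visit, drop = FALSE))
  } else if (all(c("site", "year") %in% key_cols)) {
    match(interaction(idx$site, idx$year, drop = FALSE),
          interaction(covs$site, covs$year, drop = FALSE))
  } else if (nrow(covs) == S) {
    idx$site
  } else {
    stop(sprintf("covariate table has %d rows; expected %d per-site rows or `site`/`year`(/`visit`) key columns",
                 nrow(covs), S), call. = FALSE)
  }
  if (anyNA(rows)) {
    stop("covariate table does not cover every site-year(-visit)", call. = FALSE)
  }
  for (cl in setdiff(names(covs), c("site", "year", "visit"))) {
    idx[[cl]] <- covs[[cl]][rows]
  }
  idx
}

formula_array_site <- function(f, covs, S, T) {
  tl <- attr(stats::terms(f), "term.labels")
  if (!length(tl)) {
    return(array(0, c(S, T, 0L), dimnames = list(NULL, NULL, character())))
  }
  if (is.null(covs)) stop("psi formula references covariates but `site_covs` is NULL", call. = FALSE)
  idx <- expand.grid(site = seq_len(S), year = seq_len(T))
  long <- merge_onto_index(idx, covs, S, T)
  mm <- stats::model.matrix(f, long)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  array(mm, c(S, T, ncol(mm)), dimnames = list(NULL, NULL, colnames(mm)))
}

formula_array_survey <- function(f, site_covs, survey_covs, S, T, J) {
  tl <- attr(stats::terms(f), "term.labels")
  if (!length(tl)) {
    return(array(0, c(S, T, J, 0L), dimnames = list(NULL, NULL, NULL, character())))
  }
  if (is.null(site_covs) && is.null(survey_covs)) {
    stop("det formula references covariates but no covariate table was supplied",
         call. = FALSE)
  }
  idx <- expand.grid(site = seq_len(S), year = seq_len(T), visit = seq_len(J))
  long <- merge_onto_index(idx, site_covs, S, T, J)
  long <- merge_onto_index(long, survey_covs, S, T, J)
  mm <- stats::model.matrix(f, long)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  array(mm, c(S, T, J, ncol(mm)), dimnames = list(NULL, NULL, NULL, colnames(mm)))
}

# Split a parameter vector into the model's blocks.
split_pars <- function(par, design) {
  i <- 1L
  beta0 <- par[i]; i <- i + 1L
  beta <- if (design$K) par[i:(i + design$K - 1L)] else numeric(0); i <- i + design$K
  theta <- if (design$spec$autologistic) { th <- par[i]; i <- i + 1L; th } else 0
  alpha <- par[i:(i + design$T - 1L)]; i <- i + design$T
  gamma <- if (design$L) par[i:(i + design$L - 1L)] else numeric(0)
  list(beta0 = beta0, beta = beta, theta = theta, alpha = alpha, gamma = gamma)
}

# Occupancy and detection probabilities plus per-site-year detection-record
# likelihood factors for a parameter vector.  L1/L0 are the probabilities of
# the observed visit record given z = 1 / z = 0 (missing visits contribute
# factor 1).
occu_probs <- function(par, design) {
  b <- split_pars(par, design)
  S <- design$S; T <- design$T; J <- design$J
  eta <- matrix(b$beta0, S, T)
  if (design$K) {
    for (t in seq_len(T)) {
      eta[, t] <- eta[, t] + drop(matrix(design$Xpsi[, t, ], nrow = S) %*% b$beta)
    }
  }
  p <- array(NA_real_, c(S, T, J))
  L1 <- matrix(1, S, T); L0 <- matrix(1, S, T)
  for (t in seq_len(T)) {
    for (j in seq_len(J)) {
      lp <- rep(b$alpha[t], S)
      if (design$L) lp <- lp + drop(matrix(design$W[, t, j, ], nrow = S) %*% b$gamma)
      p[, t, j] <- invlogit(lp)
      yj <- design$y[, t, j]
      obs <- !is.na(yj)
      if (any(obs)) {
        pj <- p[obs, t, j]
        L1[obs, t] <- L1[obs, t] * ifelse(yj[obs] == 1L, pj, 1 - pj)
        L0[obs, t] <- L0[obs, t] * as.numeric(yj[obs] == 0L)
      }
    }
  }
  psi1 <- invlogit(eta[, 1])
  psi0 <- invlogit(eta)                       # transition given z_{t-1} = 0
  psiC <- invlogit(eta + b$theta)             # transition given z_{t-1} = 1
  list(b = b, eta = eta, psi1 = psi1, psi0 = psi0, psiC = psiC,
       p = p, L1 = L1, L0 = L0)
}

#' Per-site marginal log-likelihood by two-state forward recursion
#'
#' Marginalises the latent occupancy sequence analytically: a scaled
#' forward recursion over the two states per year, with missing visits
#' contributing factor one and unsurveyed years contributing only the
#' state transition.
#'
#' @param par named parameter vector in the design's layout
#'   (`design$par_names`).
#' @param design an [occu_design()].
#' @return numeric vector of per-site log-likelihood contributions.
#' @export
site_log_likelihood <- function(par, design) {
  pr <- occu_probs(par, design)
  forward_loglik(pr, design)
}

forward_loglik <- function(pr, design) {
  S <- design$S; T <- design$T
  f0 <- (1 - pr$psi1) * pr$L0[, 1]
  f1 <- pr$psi1 * pr$L1[, 1]
  s <- f0 + f1
  ll <- log(s)
  ok <- s > 0
  f0[ok] <- f0[ok] / s[ok]; f1[ok] <- f1[ok] / s[ok]
  if (T > 1L) for (t in 2:T) {
    g0 <- (f0 * (1 - pr$psi0[, t]) + f1 * (1 - pr$psiC[, t])) * pr$L0[, t]
    g1 <- (f0 * pr$psi0[, t] + f1 * pr$psiC[, t]) * pr$L1[, t]
    s <- g0 + g1
    ll <- ll + log(s)
    ok <- s > 0
    f0[ok] <- g0[ok] / s[ok]; f1[ok] <- g1[ok] / s[ok]
    f0[!ok] <- 0; f1[!ok] <- 0
  }
  ll
}

#' Smoothed latent-state marginals by forward-backward recursion
#'
#' `Pr(z[i,t] = 1 | all of site i's data)` at a given parameter vector.
#'
#' @inheritParams site_log_likelihood
#' @return `S x T` matrix of smoothed occupancy probabilities.
#' @export
smoothed_z <- function(par, design) {
  pr <- occu_probs(par, design)
  S <- design$S; T <- design$T
  F0 <- matrix(0, S, T); F1 <- matrix(0, S, T)
  f0 <- (1 - pr$psi1) * pr$L0[, 1]; f1 <- pr$psi1 * pr$L1[, 1]
  s <- pmax(f0 + f1, .Machine$double.xmin)
  F0[, 1] <- f0 / s; F1[, 1] <- f1 / s
  if (T > 1L) for (t in 2:T) {
    g0 <- (F0[, t - 1] * (1 - pr$psi0[, t]) + F1[, t - 1] * (1 - pr$psiC[, t])) * pr$L0[, t]
    g1 <- (F0[, t - 1] * pr$psi0[, t] + F1[, t - 1] * pr$psiC[, t]) * pr$L1[, t]
    s <- pmax(g0 + g1, .Machine$double.xmin)
    F0[, t] <- g0 / s; F1[, t] <- g1 / s
  }
  B0 <- matrix(1, S, T); B1 <- matrix(1, S, T)
  if (T > 1L) for (t in (T - 1L):1L) {
    b0 <- (1 - pr$psi0[, t + 1]) * pr$L0[, t + 1] * B0[, t + 1] +
      pr$psi0[, t + 1] * pr$L1[, t + 1] * B1[, t + 1]
    b1 <- (1 - pr$psiC[, t + 1]) * pr$L0[, t + 1] * B0[, t + 1] +
      pr$psiC[, t + 1] * pr$L1[, t + 1] * B1[, t + 1]
    s <- pmax(b0 + b1, .Machine$double.xmin)
    B0[, t] <- b0 / s; B1[, t] <- b1 / s
  }
  num <- F1 * B1
  den <- F0 * B0 + F1 * B1
  out <- num / pmax(den, .Machine$double.xmin)
  pmin(pmax(out, 0), 1)
}

# Model-marginal (not y-conditioned) occupancy probability per site-year:
# pi_1 = psi_1; pi_t = psi0_t (1 - pi_{t-1}) + psiC_t pi_{t-1}.
marginal_occupancy <- function(pr, design) {
  T <- design$T
  pi <- matrix(NA_real_, design$S, T)
  pi[, 1] <- pr$psi1
  if (T > 1L) for (t in 2:T) {
    pi[, t] <- pr$psi0[, t] * (1 - pi[, t - 1]) + pr$psiC[, t] * pi[, t - 1]
  }
  pi
}

#' Log-posterior of the auto-logistic occupancy model
#'
#' Sum of per-site marginal log-likelihoods plus independent
#' Normal(0, sd = `prior_sd`) log-priors over every parameter (intercepts,
#' coefficients, `theta` and year detection intercepts alike).  Non-finite
#' parameter vectors return `-Inf` (rejection) rather than erroring.
#'
#' @inheritParams site_log_likelihood
#' @return scalar log-posterior density (unnormalised).
#' @export
log_posterior <- function(par, design) {
  if (any(!is.finite(par))) return(-Inf)
  ll <- sum(site_log_likelihood(par, design))
  if (!is.finite(ll)) return(-Inf)
  ll + sum(stats::dnorm(par, 0, design$spec$prior_sd, log = TRUE))
}
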