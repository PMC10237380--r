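# Independent oracles used across the suite.  Each is a direct, brute-force
# or closed-form computation that shares no code with the implementation it
# checks.

# Site likelihood by explicit enumeration of all 2^T latent sequences.
brute_force_site_loglik <- function(yi, psi1, psi0, psiC, p) {
  T <- nrow(yi)
  tot <- 0
  for (m in 0:(2^T - 1)) {
    z <- as.integer(intToBits(m)[seq_len(T)])
    pr <- if (z[1] == 1) psi1 else 1 - psi1
    if (T > 1) for (t in 2:T) {
      pt <- if (z[t - 1] == 1) psiC[t] else psi0[t]
      pr <- pr * (if (z[t] == 1) pt else 1 - pt)
    }
    for (t in seq_len(T)) for (j in seq_len(ncol(yi))) {
      if (is.na(yi[t, j])) next
      pd <- z[t] * p[t, j]
      pr <- pr * (if (yi[t, j] == 1) pd else 1 - pd)
    }
    tot <- tot + pr
  }
  log(tot)
}

# Random small design + parameter vector for likelihood property tests.
random_occu_case <- function(S = 4, Tmax = 5, Jmax = 3, miss_frac = 0.2) {
  T <- sample(seq_len(Tmax), 1)
  J <- sample(seq_len(Jmax), 1)
  y <- array(stats::rbinom(S * T * J, 1, 0.4), c(S, T, J))
  y[array(stats::runif(S * T * J) < miss_frac, c(S, T, J))] <- NA
  xc <- data.frame(x = stats::rnorm(S))
  wc <- data.frame(w = stats::rnorm(S))
  spec <- occu_spec(~x, ~w, autologistic = TRUE)
  d <- occu_design(spec, y, xc, wc)
  par <- stats::rnorm(d$n_par)
  names(par) <- d$par_names
  list(design = d, par = par, y = y, x = xc, w = wc, T = T, J = J, S = S)
}

# Probabilities for one site computed by hand from a parameter vector (the
# same arithmetic the brute-force oracle consumes).
manual_site_probs <- function(case, i) {
  d <- case$design
  b <- autocc:::split_pars(case$par, d)
  eta <- b$beta0 + b$beta * case$x$x[i]
  p <- matrix(NA_real_, case$T, case$J)
  for (t in seq_len(case$T)) for (j in seq_len(case$J)) {
    p[t, j] <- stats::plogis(b$alpha[t] + b$gamma * case$w$w[i])
  }
  list(psi1 = stats::plogis(eta),
       psi0 = stats::plogis(rep(eta, case$T)),
       psiC = stats::plogis(rep(eta, case$T) + b$theta),
       p = p,
       yi = matrix(case$y[i, , ], case$T, case$J))
}

# Minimal hand-built occu_fit (fixed draws, no MCMC) for derived-parameter
# tests.
manual_fit <- function(design, draws) {
  structure(list(draws = draws, chain = rep(1L, nrow(draws)),
                 design = design, spec = design$spec,
                 rhat = rep(NA_real_, ncol(draws)), accept = 1,
                 converged = TRUE, iter = nrow(draws), warmup = 0L,
                 thin = 1L, seed = 0L),
            class = "occu_fit")
}

# Simulate + fit in one step with small defaults shared by several tests.
quick_fit <- function(S = 80, T = 3, J = 3, beta = 1.2, theta = 0.8,
                      alpha0 = 0.3, seed = 1, chains = 2, iter = 600,
                      warmup = 400, psi_formula = ~x) {
  pars <- sim_params(beta0 = 0.2, beta = c(x = beta), theta = theta,
                     alpha = rep(alpha0, T), gamma = numeric(0),
                     n_sites = S, n_years = T, visits_per_year = J,
                     removal_year = NA)
  set.seed(seed)
  x <- data.frame(x = stats::rnorm(S))
  sim <- simulate_detection_histories(pars, as.matrix(x), NULL,
                                      seed = seed + 1000L)
  fit <- suppressWarnings(
    fit_occu(occu_spec(psi_formula, ~1), sim$y, x, chains = chains,
             iter = iter, warmup = warmup, seed = seed + 2000L))
  list(fit = fit, sim = sim, x = x, pars = pars)
}
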