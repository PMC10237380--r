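test_that("degenerate occupancy and detection settings give all-1 / all-0 data", {
  pars1 <- sim_params(beta0 = 50, beta = numeric(0), theta = 0,
                      alpha = rep(50, 2), gamma = numeric(0), n_sites = 20,
                      n_years = 2, visits_per_year = 3, removal_year = NA)
  s1 <- simulate_detection_histories(pars1, seed = 1)
  expect_true(all(s1$y[!is.na(s1$y)] == 1L))

  pars0 <- sim_params(beta0 = -50, beta = numeric(0), theta = 0,
                      alpha = rep(0, 2), gamma = numeric(0), n_sites = 20,
                      n_years = 2, visits_per_year = 3, removal_year = NA)
  s0 <- simulate_detection_histories(pars0, seed = 1)
  expect_true(all(s0$y[!is.na(s0$y)] == 0L))
})

test_that("detection fraction matches the closed form 0.5(1 - 0.6^3)", {
  pars <- sim_params(beta0 = 0, beta = numeric(0), theta = 0,
                     alpha = qlogis(0.4), gamma = numeric(0),
                     n_sites = 10000, n_years = 1, visits_per_year = 3,
                     removal_year = NA)
  s <- simulate_detection_histories(pars, seed = 42)
  frac <- mean(apply(s$y, 1, function(r) any(r == 1)))
  expect_lt(abs(frac - 0.5 * (1 - 0.6^3)), 0.02)
})

test_that("the first-year missing pattern is applied as configured", {
  mp <- year1_missing_pattern()
  expect_identical(dim(mp), c(37L, 4L))
  expect_identical(sum(mp[, 1]), 76L)          # surveys in year 1
  expect_identical(sum(mp[, 1] > 0), 30L)      # transects surveyed
  pars <- sim_params(missing_pattern = mp)
  x <- matrix(rnorm(37), dimnames = list(NULL, "juniper_100"))
  w <- matrix(rnorm(37), dimnames = list(NULL, "tri"))
  s <- simulate_detection_histories(pars, x, w, seed = 3)
  realised <- apply(!is.na(s$y), c(1, 2), sum)
  expect_equal(realised, mp, ignore_attr = TRUE)
})

test_that("naive occupancy underestimates truth in expectation", {
  pars <- sim_params(beta0 = 0, beta = numeric(0), theta = 0.5,
                     alpha = rep(qlogis(0.45), 2), gamma = numeric(0),
                     n_sites = 120, n_years = 2, visits_per_year = 3,
                     removal_year = NA)
  naive <- true <- numeric(50)
  for (r in seq_len(50)) {
    s <- simulate_detection_histories(pars, seed = 1000 + r)
    naive[r] <- mean(apply(s$y, 1, function(v) any(v == 1, na.rm = TRUE)))
    true[r] <- mean(apply(s$z, 1, max))
  }
  expect_lt(mean(naive), mean(true))
})

test_that("positive carry-over induces year-to-year persistence", {
  pars <- sim_params(beta0 = 0, beta = numeric(0), theta = 1.5,
                     alpha = rep(0, 4), gamma = numeric(0), n_sites = 4000,
                     n_years = 4, visits_per_year = 1, removal_year = NA)
  s <- simulate_detection_histories(pars, seed = 9)
  z_prev <- as.vector(s$z[, 1:3]); z_next <- as.vector(s$z[, 2:4])
  p11 <- mean(z_next[z_prev == 1]); p01 <- mean(z_next[z_prev == 0])
  expect_gt(p11, p01)
})

test_that("simulation is bit-identical under a fixed seed", {
  pars <- sim_params()
  x <- matrix(rnorm(37), dimnames = list(NULL, "juniper_100"))
  w <- matrix(rnorm(37), dimnames = list(NULL, "tri"))
  a <- simulate_detection_histories(pars, x, w, seed = 7)
  b <- simulate_detection_histories(pars, x, w, seed = 7)
  expect_identical(a, b)
})

test_that("prey layers have the configured shapes and constant squirrels", {
  covs <- data.frame(juniper_100 = seq(0, 60, length.out = 37),
                     sagebrush = rep(15, 37))
  prey <- suppressWarnings(simulate_prey_layers(covs, n_years = 4, seed = 5))
  d <- function(x) {
    cf <- default_prey_coefficients()$deer
    cf[1] + cf[2] * x + cf[3] * x^2
  }
  expect_gt(d(10), d(0))
  expect_gt(d(10), d(30))
  sq <- attr(prey, "squirrel_by_year")
  expect_identical(ncol(sq), 4L)
  expect_true(all(sq == sq[, 1]))
  expect_true(all(prey$deer_mouse_density >= 0))
  expect_true(all(prey$songbird_abundance >= 0))
})

test_that("zero-noise quadratic prediction is exact and flooring warns", {
  covs <- data.frame(juniper_100 = c(0, 10, 30, 60), sagebrush = c(5, 10, 20, 40))
  cf <- list(deer = c(1, 2, -0.5), pocket = c(1, 0, 0))
  expect_warning(
    out <- predict_prey_covariates(covs, cf),
    "floored")
  expect_equal(out$deer_mouse_density,
               pmax(1 + 2 * covs$juniper_100 - 0.5 * covs$juniper_100^2, 0))
  expect_equal(out$pocket_mouse_density, rep(1, 4))
  expect_error(predict_prey_covariates(covs, list(deer = c(1, 0, 0))),
               "configuration|pocket")
})
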