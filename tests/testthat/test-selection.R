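make_screening_data <- function(seed = 1, S = 60) {
  set.seed(seed)
  base <- rnorm(S)
  covs <- data.frame(juniper_100 = base,
                     juniper_1000 = 0.5 * base + sqrt(0.75) * rnorm(S),
                     juniper_3000 = rnorm(S))
  pars <- sim_params(beta0 = 0.3, beta = c(juniper_100 = 1.5), theta = 1,
                     alpha = rep(0.3, 3), gamma = numeric(0), n_sites = S,
                     n_years = 3, visits_per_year = 3, removal_year = NA)
  sim <- simulate_detection_histories(pars,
                                      as.matrix(covs[, "juniper_100", drop = FALSE]),
                                      NULL, seed = seed + 500)
  list(y = sim$y, covs = covs)
}

test_that("the screening table is complete and carries the required columns", {
  dat <- make_screening_data(3)
  sc <- suppressWarnings(scale_screening(dat$y, dat$covs, names(dat$covs),
                                         chains = 2, iter = 400, warmup = 300,
                                         seed = 4))
  expect_identical(sort(sc$table$metric), sort(names(dat$covs)))
  expect_true(all(c("elpd", "se", "beta", "lo90", "hi90", "direction",
                    "delta_elpd", "delta_se") %in% names(sc$table)))
  expect_equal(sc$table$delta_elpd[1], 0)
  expect_true(sc$selected %in% names(dat$covs))
  # interpretability override hook
  sc2 <- suppressWarnings(scale_screening(dat$y, dat$covs, names(dat$covs),
                                          chains = 2, iter = 400, warmup = 300,
                                          seed = 4, override = "juniper_3000"))
  expect_identical(sc2$selected, "juniper_3000")
  expect_error(scale_screening(dat$y, dat$covs, c("juniper_100", "nope")),
               "nope")
})

test_that("identical covariate columns tie within ELPD noise", {
  dat <- make_screening_data(5)
  covs <- data.frame(a = dat$covs$juniper_100, b = dat$covs$juniper_100)
  expect_warning(
    sc <- scale_screening(dat$y, covs, c("a", "b"), chains = 2, iter = 500,
                          warmup = 300, seed = 6),
    "collinear")
  expect_equal(sc$table$delta_elpd[2], 0, tolerance = 1e-10)
  expect_equal(sc$table$delta_se[2], 0, tolerance = 1e-10)
})

test_that("a single-model candidate set reports one row with zero delta", {
  dat <- make_screening_data(7, S = 40)
  res <- suppressWarnings(run_candidate_set(
    list(null = occu_spec(~1, ~1)), dat$y, dat$covs, chains = 2, iter = 400,
    warmup = 300, seed = 8, ppc = FALSE))
  expect_identical(nrow(res$ranking), 1L)
  expect_equal(res$ranking$delta_elpd, 0)
  expect_error(run_candidate_set(list(), dat$y), "empty")
})

test_that("a strong juniper effect beats the null and prey-only models", {
  wins_null <- 0; wins_prey <- 0; R <- 5
  for (rep in seq_len(R)) {
    dat <- make_screening_data(100 + rep, S = 80)
    set.seed(400 + rep)
    covs <- dat$covs
    covs$songbird <- rnorm(80)            # no real effect
    models <- list(null = occu_spec(~1, ~1),
                   juniper = occu_spec(~juniper_100, ~1),
                   songbirds = occu_spec(~songbird, ~1))
    res <- suppressWarnings(run_candidate_set(models, dat$y, covs,
                                              chains = 2, iter = 500,
                                              warmup = 350,
                                              seed = 500 + rep, ppc = FALSE))
    rk <- res$ranking
    if (which(rk$model == "juniper") < which(rk$model == "null")) {
      wins_null <- wins_null + 1
    }
    if (which(rk$model == "juniper") < which(rk$model == "songbirds")) {
      wins_prey <- wins_prey + 1
    }
  }
  expect_gte(wins_null, 4)
  expect_gte(wins_prey, 4)
})

test_that("an absent interaction is covered by its 90% CrI", {
  covered <- 0; R <- 4
  for (rep in seq_len(R)) {
    dat <- make_screening_data(200 + rep, S = 80)
    set.seed(600 + rep)
    covs <- dat$covs
    covs$deer <- rnorm(80)
    spec <- occu_spec(~juniper_100 * deer, ~1)
    fit <- suppressWarnings(fit_occu(spec, dat$y, covs, chains = 2,
                                     iter = 600, warmup = 400,
                                     seed = 700 + rep))
    b <- fit$draws[, "beta_juniper_100:deer"]
    q <- quantile(b, c(0.05, 0.95))
    if (q[1] <= 0 && 0 <= q[2]) covered <- covered + 1
  }
  expect_gte(covered, 3)
})

test_that("the staged workflow runs end to end on a small bundle", {
  dat <- make_screening_data(11, S = 50)
  covs <- dat$covs
  set.seed(12)
  covs$dist_cliff <- rnorm(50); covs$dist_water <- rnorm(50)
  covs$dist_stream <- rnorm(50); covs$dist_road <- rnorm(50)
  covs$dist_dwelling <- rnorm(50)
  covs$deer_mouse_density <- rnorm(50); covs$pocket_mouse_density <- rnorm(50)
  covs$songbird_abundance <- rnorm(50); covs$ground_squirrel <- rbinom(50, 1, 0.4)
  covs$removed <- 0L
  covs$tri <- rnorm(50); covs$day_of_year <- rnorm(50)
  sets <- candidate_model_sets()
  expect_named(sets, c("detection", "structure", "prey"))
  expect_identical(length(sets$detection), 3L)
  expect_identical(length(sets$structure), 14L)
  expect_identical(length(sets$prey), 10L)
  # run a reduced structure stage to keep the suite fast
  small <- sets$structure[c("null", "juniper", "cliff")]
  res <- suppressWarnings(run_candidate_set(small, dat$y, covs, chains = 2,
                                            iter = 400, warmup = 300,
                                            seed = 13, ppc = TRUE))
  expect_identical(nrow(res$ranking), 3L)
  expect_true(all(res$ranking$bayes_p >= 0 & res$ranking$bayes_p <= 1))
  expect_true(all(c("model", "elpd", "delta_elpd", "bayes_p", "converged")
                  %in% names(res$ranking)))
})
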