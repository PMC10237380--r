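# Staged model selection: detection screening, spatial-scale screening,
# habitat-structure and prey candidate sets, each ranked by PSIS-LOO.

coef_summary <- function(fit) {
  dr <- fit$draws
  data.frame(parameter = colnames(dr),
             mean = colMeans(dr),
             sd = apply(dr, 2L, stats::sd),
             lo90 = apply(dr, 2L, stats::quantile, 0.05),
             hi90 = apply(dr, 2L, stats::quantile, 0.95),
             direction = apply(dr, 2L, posterior_direction),
             row.names = NULL)
}

fit_and_loo <- function(spec, y, site_covs, survey_covs, chains, iter,
                        warmup, seed, ppc = FALSE, ppc_draws = 400L) {
  fit <- fit_occu(spec, y, site_covs, survey_covs, chains = chains,
                  iter = iter, warmup = warmup, seed = seed)
  ll <- pointwise_loglik(fit)
  loo <- suppressWarnings(psis_loo(ll))
  p_val <- NA_real_
  if (ppc) {
    ids <- round(seq(1, nrow(fit$draws), length.out = min(ppc_draws, nrow(fit$draws))))
    p_val <- freeman_tukey_ppc(fit, seed = child_seed(seed, 7L),
                               draw_ids = ids)$p_value
  }
  list(fit = fit, loo = loo, ppc_p = p_val)
}

#' Screen spatial scales / metrics of juniper cover
#'
#' Fits univariate habitat-use models (one covariate column each, shared
#' detection structure) for every supplied metric column, ranks them by
#' PSIS-LOO elpd, and reports each coefficient with its 90% equal-tailed
#' credible interval and posterior direction.  The selected metric is the
#' top-ranked one unless `override` names another column — the documented
#' interpretability hook for carrying a competitive but more interpretable
#' metric forward.
#'
#' @param y detection array.
#' @param site_covs covariate table containing all `metric_cols`.
#' @param metric_cols character vector of columns to screen (e.g. percent
#'   cover at 100..3000 m, category proportions, clustering index).
#' @param det shared detection formula.
#' @param survey_covs detection covariates (if `det` needs them).
#' @param autologistic include theta in every screened model.
#' @param chains,iter,warmup,seed MCMC settings.
#' @param override optional column name to select regardless of rank.
#' @return list with `table` (one row per metric, ranked) and `selected`.
#' @export
scale_screening <- function(y, site_covs, metric_cols, det = ~1,
                            survey_covs = NULL, autologistic = TRUE,
                            chains = 3L, iter = 1200L, warmup = 600L,
                            seed = 1L, override = NULL) {
  missing_cols <- setdiff(metric_cols, names(site_covs))
  if (length(missing_cols)) {
    stop(sprintf("metric columns not in covariate table: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  cm <- stats::cor(as.matrix(site_covs[metric_cols]))
  if (any(abs(cm[upper.tri(cm)]) > 0.999)) {
    warning("near-collinear metric columns; ELPD ties expected")
  }
  res <- vector("list", length(metric_cols))
  for (k in seq_along(metric_cols)) {
    col <- metric_cols[k]
    spec <- occu_spec(psi = stats::as.formula(paste("~", col)), det = det,
                      autologistic = autologistic, name = col)
    # common random numbers across metrics: comparisons see the same MCMC
    # noise, so identical covariates tie exactly
    r <- fit_and_loo(spec, y, site_covs, survey_covs, chains, iter, warmup,
                     seed = child_seed(seed, 1L))
    cs <- coef_summary(r$fit)
    bi <- cs[cs$parameter == paste0("beta_", col), ]
    res[[k]] <- data.frame(metric = col, elpd = r$loo$elpd, se = r$loo$se,
                           beta = bi$mean, lo90 = bi$lo90, hi90 = bi$hi90,
                           direction = bi$direction,
                           max_k = max(r$loo$pareto_k),
                           converged = r$fit$converged)
    res[[k]]$pointwise <- I(list(r$loo$pointwise))
  }
  tab <- do.call(rbind, res)
  ord <- order(-tab$elpd, seq_len(nrow(tab)))
  tab <- tab[ord, ]
  top <- tab$pointwise[[1]]
  tab$delta_elpd <- vapply(tab$pointwise, function(pw) sum(pw - top), numeric(1))
  tab$delta_se <- vapply(tab$pointwise, function(pw) {
    sqrt(length(pw) * stats::var(pw - top))
  }, numeric(1))
  tab$pointwise <- NULL
  rownames(tab) <- NULL
  selected <- if (!is.null(override)) override else tab$metric[1]
  list(table = tab, selected = selected)
}

#' Fit and rank a candidate model set
#'
#' Fits every model in a named list of [occu_spec()]s to the same data,
#' ranks by PSIS-LOO elpd (ties broken by fewer parameters, then list
#' order), and reports ELPD differences to the top model, Freeman-Tukey
#' Bayesian p-values, posterior directions for every coefficient, and
#' convergence flags (a non-converged model is reported flagged, never
#' dropped).
#'
#' @param models named list of `occu_spec`s.
#' @param y detection array.
#' @param site_covs,survey_covs covariate tables.
#' @param chains,iter,warmup,seed MCMC settings.
#' @param ppc compute Bayesian p-values?
#' @param keep_fits return the fitted objects (memory-heavy)?
#' @return list with `ranking` (data frame), `coefficients` (per-model
#'   coefficient tables), and optionally `fits`.
#' @export
run_candidate_set <- function(models, y, site_covs = NULL, survey_covs = NULL,
                              chains = 3L, iter = 1500L, warmup = 750L,
                              seed = 1L, ppc = TRUE, keep_fits = FALSE) {
  if (!length(models)) stop("empty model list", call. = FALSE)
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- vapply(models, function(m) m$name, character(1))
  }
  fits <- list(); loos <- list(); ppc_p <- numeric(length(models))
  npar <- integer(length(models)); conv <- logical(length(models))
  for (k in seq_along(models)) {
    # one shared seed across the set (common random numbers for ranking)
    r <- fit_and_loo(models[[k]], y, site_covs, survey_covs, chains, iter,
                     warmup, seed = child_seed(seed, 1L), ppc = ppc)
    loos[[k]] <- r$loo; ppc_p[k] <- r$ppc_p
    npar[k] <- r$fit$design$n_par; conv[k] <- r$fit$converged
    fits[[k]] <- if (keep_fits) r$fit else coef_summary(r$fit)
  }
  names(loos) <- names(models); names(fits) <- names(models)
  elpd <- vapply(loos, function(l) l$elpd, numeric(1))
  ord <- order(-elpd, npar, seq_along(models))
  top <- loos[[ord[1]]]
  ranking <- do.call(rbind, lapply(ord, function(k) {
    dif <- loos[[k]]$pointwise - top$pointwise
    data.frame(model = names(models)[k], elpd = loos[[k]]$elpd,
               se = loos[[k]]$se, delta_elpd = sum(dif),
               delta_se = sqrt(length(dif) * stats::var(dif)),
               n_par = npar[k], bayes_p = ppc_p[k],
               max_k = max(loos[[k]]$pareto_k), converged = conv[k])
  }))
  rownames(ranking) <- NULL
  out <- list(ranking = ranking,
              coefficients = if (keep_fits) lapply(fits, coef_summary) else fits,
              loos = loos)
  if (keep_fits) out$fits <- fits
  out
}

#' Candidate model sets for the staged workflow
#'
#' Builds the three stages of the analysis as named lists of model
#' specifications: detection screening (null / time of year / terrain
#' roughness, all on an intercept-only use model), the habitat-structure
#' set (null, juniper cover, distances to cliff / water / stream / road /
#' dwelling, the additive pairs, small-mammal density, and the removal
#' treatment), and the prey set built around a chosen structure model
#' (each prey measure alone, additive with the structure model,
#' interactive, and all prey groups additive).
#'
#' @param juniper name of the juniper metric column carried forward.
#' @param det detection formula carried forward from detection screening.
#' @param structure_terms character version of the best structure model's
#'   psi terms (for the prey stage).
#' @return named list of `occu_spec` lists: `detection`, `structure`,
#'   `prey`.
#' @export
candidate_model_sets <- function(juniper = "juniper_100", det = ~tri,
                                 structure_terms = juniper) {
  f <- function(x) stats::as.formula(paste("~", x))
  detection <- list(
    "p(.)" = occu_spec(~1, ~1),
    "p(day)" = occu_spec(~1, ~day_of_year),
    "p(TRI)" = occu_spec(~1, ~tri))
  structure <- list(
    "null" = occu_spec(~1, det),
    "juniper" = occu_spec(f(juniper), det),
    "cliff" = occu_spec(~dist_cliff, det),
    "water" = occu_spec(~dist_water, det),
    "stream" = occu_spec(~dist_stream, det),
    "road" = occu_spec(~dist_road, det),
    "dwelling" = occu_spec(~dist_dwelling, det),
    "cliff+juniper" = occu_spec(f(paste("dist_cliff +", juniper)), det),
    "cliff+stream" = occu_spec(~dist_cliff + dist_stream, det),
    "road+juniper" = occu_spec(f(paste("dist_road +", juniper)), det),
    "water+juniper" = occu_spec(f(paste("dist_water +", juniper)), det),
    "dwelling+juniper" = occu_spec(f(paste("dist_dwelling +", juniper)), det),
    "small_mammals" = occu_spec(~deer_mouse_density + pocket_mouse_density, det),
    "removal" = occu_spec(~removed, det))
  sm <- structure_terms
  prey <- list(
    "sm" = occu_spec(f(sm), det),
    "small_mammals" = occu_spec(~deer_mouse_density + pocket_mouse_density, det),
    "songbirds" = occu_spec(~songbird_abundance, det),
    "squirrels" = occu_spec(~ground_squirrel, det),
    "small_mammals+sm" = occu_spec(f(paste(sm, "+ deer_mouse_density + pocket_mouse_density")), det),
    "songbirds+sm" = occu_spec(f(paste(sm, "+ songbird_abundance")), det),
    "squirrels+sm" = occu_spec(f(paste(sm, "+ ground_squirrel")), det),
    "small_mammals*sm" = occu_spec(f(paste(sm, "* deer_mouse_density")), det),
    "songbirds*sm" = occu_spec(f(paste(sm, "* songbird_abundance")), det),
    "all_prey" = occu_spec(f(paste(sm, "+ deer_mouse_density + pocket_mouse_density",
                                   "+ songbird_abundance + ground_squirrel")), det))
  list(detection = detection, structure = structure, prey = prey)
}

#' Run the staged selection workflow
#'
#' Detection screening first (best detection structure carried forward),
#' then the habitat-structure set, then the prey set built around the top
#' structure model.  Each stage is ranked by PSIS-LOO.
#'
#' @param y detection array.
#' @param site_covs,survey_covs covariate tables.
#' @param juniper juniper metric column name (from scale screening).
#' @param chains,iter,warmup,seed MCMC settings.
#' @return list of stage results (`detection`, `structure`, `prey`), each a
#'   [run_candidate_set()] result, plus the carried-forward choices.
#' @export
staged_selection <- function(y, site_covs, survey_covs = NULL,
                             juniper = "juniper_100", chains = 3L,
                             iter = 1500L, warmup = 750L, seed = 1L) {
  sets <- candidate_model_sets(juniper = juniper)
  det_res <- run_candidate_set(sets$detection, y, site_covs, survey_covs,
                               chains, iter, warmup, seed = child_seed(seed, 1L),
                               ppc = FALSE)
  best_det <- det_res$ranking$model[1]
  det_formula <- switch(best_det, "p(.)" = ~1, "p(day)" = ~day_of_year,
                        "p(TRI)" = ~tri)
  sets <- candidate_model_sets(juniper = juniper, det = det_formula)
  str_res <- run_candidate_set(sets$structure, y, site_covs, survey_covs,
                               chains, iter, warmup, seed = child_seed(seed, 2L))
  best_str <- str_res$ranking$model[1]
  best_terms <- deparse(sets$structure[[best_str]]$psi[[2]])
  sets <- candidate_model_sets(juniper = juniper, det = det_formula,
                               structure_terms = best_terms)
  prey_res <- run_candidate_set(sets$prey, y, site_covs, survey_covs,
                                chains, iter, warmup, seed = child_seed(seed, 3L))
  list(detection = det_res, structure = str_res, prey = prey_res,
       best_detection = best_det, best_structure = best_str)
}
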