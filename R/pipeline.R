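# End-to-end pipeline plumbing: simulate a full synthetic study, derive
# covariates, and write/read a bundle of plain-text artefacts.  All
# randomness flows from a single seed through child_seed() streams.

#' Derive the full site covariate table from grids and transects
#'
#' Percent juniper cover at each requested radius, cover-category
#' proportions at 100 m, the nearest-neighbour clustering index, distances
#' to cliff/water/stream/road/dwelling, terrain roughness, and the removal
#' indicator.  With a list of per-year grids the cover-derived columns are
#' time-varying (post-removal years see the cut landscape); geometry-only
#' columns (distances, TRI) are computed once.
#'
#' @param grids a `landscape_grid` or a list of them, one per year.
#' @param transects a `transect_set`.
#' @param features a feature list from [generate_features()], or `NULL` to
#'   skip distance-to-feature columns.
#' @param n_years number of seasons (recycled if `grids` is not a list).
#' @param radii buffer radii (m) for percent cover columns.
#' @param category_radius,clustering_radius,tri_radius radii (m) for the
#'   respective summaries.
#' @param removal_year first post-removal year index (NA = none).
#' @param block_size cover-category block size (m).
#' @return long data frame, one row per site-year, columns `site`, `year`,
#'   `juniper_<r>`, `p0`/`p_lt10`/`p_10to20`/`p_gt20`, `clustering`,
#'   `dist_*`, `tri`, `removed`.
#' @export
build_covariate_table <- function(grids, transects, features = NULL,
                                  n_years = 1L, radii = c(100, 250, 500, 1000),
                                  category_radius = 100,
                                  clustering_radius = 500, tri_radius = 100,
                                  removal_year = NA, block_size = NULL) {
  if (inherits(grids, "landscape_grid")) {
    grids <- rep(list(grids), n_years)
  }
  n_years <- length(grids)
  trs <- transects$transects
  S <- length(trs)
  if (is.null(block_size)) {
    cs <- grids[[1]]$cell_size
    block_size <- ceiling(30 / cs) * cs  # nearest multiple of cell size >= 30 m
  }

  # geometry-only columns: computed on the year-1 grid
  g1 <- grids[[1]]
  static <- lapply(trs, function(tr) {
    v <- tr$vertices
    out <- data.frame(site = tr$id,
                      dist_cliff = cliff_distance(g1, v),
                      tri = tri_index(g1, v, tri_radius, clip = TRUE),
                      treated = tr$treated, stratum = tr$stratum)
    if (!is.null(features)) {
      out$dist_water <- distance_to_feature(v, features$water)
      out$dist_stream <- distance_to_feature(v, features$stream)
      out$dist_road <- distance_to_feature(v, features$road)
      out$dist_dwelling <- distance_to_feature(v, features$dwelling)
    }
    out
  })
  static <- do.call(rbind, static)
  # a landscape without cliffs gets the largest finite distance as stand-in
  if (any(!is.finite(static$dist_cliff))) {
    fin <- static$dist_cliff[is.finite(static$dist_cliff)]
    static$dist_cliff[!is.finite(static$dist_cliff)] <-
      if (length(fin)) max(fin) * 2 else sqrt(sum((dim(g1$cover) * g1$cell_size)^2))
  }

  rows <- list()
  for (t in seq_len(n_years)) {
    g <- grids[[t]]
    per_site <- lapply(trs, function(tr) {
      v <- tr$vertices
      cov_cols <- vapply(radii, function(r) {
        as.numeric(percent_cover_buffer(g, v, r, clip = TRUE))
      }, numeric(1))
      names(cov_cols) <- paste0("juniper_", radii)
      cp <- category_proportions(g, v, category_radius, block_size = block_size,
                                 clip = TRUE)
      ci <- suppressWarnings(clustering_index(g, v, clustering_radius, clip = TRUE))
      c(cov_cols, cp, clustering = if (is.na(ci)) 1 else ci)
    })
    per_site <- as.data.frame(do.call(rbind, per_site))
    per_site$site <- static$site
    per_site$year <- t
    per_site$removed <- as.integer(static$treated &
                                     !is.na(removal_year) & t >= removal_year)
    rows[[t]] <- cbind(per_site, static[, setdiff(names(static), "site"),
                                        drop = FALSE])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate survey-visit covariates (day of year)
#'
#' Visit dates inside the May 1 - Jul 15 survey window, at least 14 days
#' apart within a year.
#'
#' @param S,T,J design dimensions.
#' @param seed integer RNG seed.
#' @return long data frame `site`, `year`, `visit`, `day_of_year`.
#' @export
simulate_survey_covariates <- function(S, T, J, seed = 1L) {
  set.seed(as.integer(seed))
  grid <- expand.grid(site = seq_len(S), year = seq_len(T), visit = seq_len(J))
  doy <- matrix(NA_real_, S * T, J)
  for (r in seq_len(S * T)) {
    first <- stats::runif(1, 121, 196 - 14 * (J - 1))
    doy[r, ] <- first + 14 * (seq_len(J) - 1) + stats::runif(J, 0, 7)
  }
  grid$day_of_year <- as.vector(doy)
  grid
}

#' Simulate a complete synthetic study
#'
#' Landscape, stratified transects, feature sets, time-varying covariates
#' (with the removal treatment cutting cover inside treated-transect
#' buffers from `removal_year` on), prey layers, survey covariates, and
#' detection histories for one species from the auto-logistic occupancy
#' model.  Default dimensions mirror the emulated design: 37 transects,
#' 4 years, up to 3 visits with the incomplete first-year pattern, and a
#' removal treatment on 18 transects before the final year.
#'
#' @param seed single integer; every stage derives its stream from it.
#' @param params a [sim_params()].
#' @param shape,cell_size,fill_fraction landscape settings.
#' @param n_per_stratum transects per cover stratum (sums to
#'   `params$n_sites`).
#' @param n_treated transects receiving the removal treatment.
#' @param radii percent-cover radii for the covariate table.
#' @param use_missing_pattern apply the first-year incomplete visit
#'   pattern?
#' @return a `study_bundle`: grids (by year), transects, features,
#'   covariates (long, standardized and raw), prey layers, survey
#'   covariates, detection array `y`, latent truth `z`, params and seeds.
#' @export
simulate_study <- function(seed = 1L, params = sim_params(),
                           shape = c(300L, 300L), cell_size = 20,
                           fill_fraction = 0.18,
                           n_per_stratum = c(17L, 12L, 8L), n_treated = 18L,
                           radii = c(100, 250, 500, 1000),
                           use_missing_pattern = TRUE) {
  stopifnot(sum(n_per_stratum) == params$n_sites)
  grid <- generate_landscape(child_seed(seed, 1L), shape = shape,
                             cell_size = cell_size,
                             fill_fraction = fill_fraction)
  transects <- place_transects(grid, n_per_stratum, seed = child_seed(seed, 2L),
                               n_treated = n_treated)
  features <- generate_features(grid, seed = child_seed(seed, 3L))

  T <- params$n_years
  grids <- rep(list(grid), T)
  if (!is.na(params$removal_year)) {
    post <- apply_removal(grid, transects)
    for (t in params$removal_year:T) grids[[t]] <- post
  }
  covs <- build_covariate_table(grids, transects, features,
                                radii = radii,
                                removal_year = params$removal_year)
  # synthetic mean sagebrush cover: declines weakly with juniper, for the
  # pocket-mouse quadratic
  set.seed(child_seed(seed, 4L))
  sage_site <- pmax(stats::rnorm(params$n_sites, 18, 4) -
                      0.1 * covs$juniper_100[covs$year == 1], 1)
  covs$sagebrush <- sage_site[covs$site]

  prey <- simulate_prey_layers(covs[covs$year == 1,
                                    c("juniper_100", "sagebrush")],
                               n_years = T, seed = child_seed(seed, 5L))
  for (cl in names(prey)) covs[[cl]] <- prey[[cl]][covs$site]

  survey <- simulate_survey_covariates(params$n_sites, T,
                                       params$visits_per_year,
                                       seed = child_seed(seed, 6L))

  # standardize everything numeric except identifiers/categoricals;
  # degenerate constant columns (e.g. a category proportion absent from
  # this landscape) pass through rather than aborting the pipeline
  num_cols <- names(covs)[vapply(covs, is.numeric, logical(1))]
  const_cols <- num_cols[vapply(covs[num_cols],
                                function(x) stats::sd(x) == 0, logical(1))]
  std <- standardize_covariates(covs,
                                exclude = c("site", "year", "removed",
                                            "ground_squirrel", "treated",
                                            const_cols))
  survey_std <- standardize_covariates(survey,
                                       exclude = c("site", "year", "visit"))

  if (use_missing_pattern && is.null(params$missing_pattern)) {
    params$missing_pattern <- year1_missing_pattern(
      n_sites = params$n_sites, n_years = T,
      visits_per_year = params$visits_per_year)
  }

  # psi covariates: standardized columns named in params$beta (long S x T)
  X <- NULL
  if (length(params$beta)) {
    X <- array(NA_real_, c(params$n_sites, T, length(params$beta)),
               dimnames = list(NULL, NULL, names(params$beta)))
    for (k in seq_along(params$beta)) {
      cl <- names(params$beta)[k]
      for (t in seq_len(T)) {
        X[, t, k] <- std$table[[cl]][std$table$year == t]
      }
    }
  }
  Wd <- NULL
  if (length(params$gamma)) {
    Wd <- array(NA_real_, c(params$n_sites, T, params$visits_per_year,
                            length(params$gamma)),
                dimnames = list(NULL, NULL, NULL, names(params$gamma)))
    for (k in seq_along(params$gamma)) {
      cl <- names(params$gamma)[k]
      if (cl %in% names(std$table)) {
        for (t in seq_len(T)) for (j in seq_len(params$visits_per_year)) {
          Wd[, t, j, k] <- std$table[[cl]][std$table$year == t]
        }
      } else {
        sv <- survey_std$table
        for (t in seq_len(T)) for (j in seq_len(params$visits_per_year)) {
          Wd[, t, j, k] <- sv[[cl]][sv$year == t & sv$visit == j]
        }
      }
    }
  }

  sim <- simulate_detection_histories(params, X, Wd,
                                      seed = child_seed(seed, 7L))
  structure(list(grids = grids, transects = transects, features = features,
                 covariates = std$table, covariates_raw = covs,
                 standardization = list(means = std$means, sds = std$sds),
                 survey_covariates = survey_std$table,
                 survey_covariates_raw = survey,
                 prey = prey, y = sim$y, z = sim$z, psi = sim$psi, p = sim$p,
                 params = params, seed = seed),
            class = "study_bundle")
}

#' Detection history as a long data frame
#'
#' @param y `sites x years x visits` array.
#' @return data frame `site`, `year`, `visit`, `y` (NA rows = unrealised
#'   visits, retained so the design is explicit).
#' @export
detection_history_to_df <- function(y) {
  d <- dim(y)
  out <- expand.grid(site = seq_len(d[1]), year = seq_len(d[2]),
                     visit = seq_len(d[3]))
  out$y <- as.vector(y)
  out
}

#' @rdname detection_history_to_df
#' @param df long data frame with `site`, `year`, `visit`, `y`.
#' @return `detection_history_from_df()`: the 3-d array.
#' @export
detection_history_from_df <- function(df) {
  S <- max(df$site); T <- max(df$year); J <- max(df$visit)
  y <- array(NA_integer_, c(S, T, J))
  y[cbind(df$site, df$year, df$visit)] <- df$y
  y
}

#' Write a study bundle to a directory of plain-text artefacts
#'
#' Detection histories and covariates as CSV, grids as ESRI ASCII rasters,
#' truth and parameters as a JSON sidecar, and a manifest with seeds and
#' content hashes so a run can be audited and reproduced.
#'
#' @param bundle a `study_bundle`.
#' @param dir output directory (created if needed).
#' @param force overwrite existing outputs?
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    stop("output directory is non-empty; use `force = TRUE` to overwrite",
         call. = FALSE)
  }
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("write_bundle() needs the jsonlite package", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(detection_history_to_df(bundle$y),
                   file.path(dir, "detections.csv"), row.names = FALSE)
  utils::write.csv(bundle$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$survey_covariates,
                   file.path(dir, "survey_covariates.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$transects),
                   file.path(dir, "transects.csv"), row.names = FALSE)
  write_ascii_grid(bundle$grids[[1]]$cover, file.path(dir, "cover_year1.asc"),
                   bundle$grids[[1]]$cell_size, bundle$grids[[1]]$origin)
  last <- length(bundle$grids)
  write_ascii_grid(bundle$grids[[last]]$cover,
                   file.path(dir, "cover_final.asc"),
                   bundle$grids[[last]]$cell_size, bundle$grids[[last]]$origin)
  write_ascii_grid(bundle$grids[[1]]$dem, file.path(dir, "dem.asc"),
                   bundle$grids[[1]]$cell_size, bundle$grids[[1]]$origin)
  truth <- list(z = bundle$z, params = bundle$params[
    c("beta0", "beta", "theta", "alpha", "gamma", "removal_year")],
    # named vectors serialise to JSON objects only as lists
    standardization = list(means = as.list(bundle$standardization$means),
                           sds = as.list(bundle$standardization$sds)),
    seed = bundle$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE, force = TRUE)
  files <- setdiff(list.files(dir), "manifest.json")
  manifest <- list(seed = bundle$seed,
                   files = lapply(stats::setNames(files, files), function(f) {
                     unname(tools::md5sum(file.path(dir, f)))
                   }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
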