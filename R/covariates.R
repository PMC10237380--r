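# Landscape covariate extraction.  All geometry is planar metres; buffer
# membership uses the cell-centre-in-buffer rule throughout, so every value
# here can be checked by direct cell enumeration.

buffer_mask <- function(grid, vertices, radius, clip = FALSE) {
  validate_landscape(grid)
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  v <- as.matrix(vertices)
  nr <- nrow(grid$cover); nc <- ncol(grid$cover); cs <- grid$cell_size
  xmin <- grid$origin[1]; ymin <- grid$origin[2]
  xmax <- xmin + nc * cs; ymax <- ymin + nr * cs
  out_of_bounds <- min(v[, 1]) - radius < xmin || max(v[, 1]) + radius > xmax ||
                   min(v[, 2]) - radius < ymin || max(v[, 2]) + radius > ymax
  if (out_of_bounds && !clip) {
    stop("buffer extends beyond the grid; use `clip = TRUE` to compute over in-bounds cells",
         call. = FALSE)
  }
  cc <- cell_centers(grid)
  # restrict to the bounding box before exact distances
  ci <- which(cc$x >= min(v[, 1]) - radius - cs & cc$x <= max(v[, 1]) + radius + cs)
  ri <- which(cc$y >= min(v[, 2]) - radius - cs & cc$y <= max(v[, 2]) + radius + cs)
  m <- matrix(FALSE, nr, nc)
  if (length(ri) && length(ci)) {
    X <- outer(rep(1, length(ri)), cc$x[ci])
    Y <- outer(cc$y[ri], rep(1, length(ci)))
    d <- dist_to_polyline(X, Y, v)
    m[ri, ci] <- d <= radius
  }
  attr(m, "clipped") <- out_of_bounds
  m
}

#' Percent juniper cover within a buffer of a transect
#'
#' 100 x (cover cells with centre within `radius` of the transect polyline) /
#' (all cells with centre within `radius`).
#'
#' @param grid a `landscape_grid`.
#' @param vertices 2-column matrix of transect vertex coordinates (m).
#' @param radius buffer radius in metres.
#' @param clip if `TRUE`, a buffer that leaves the grid is computed over its
#'   in-bounds cells (flagged via attribute `"clipped"`); otherwise an error.
#' @return percent cover in `[0, 100]`.
#' @export
percent_cover_buffer <- function(grid, vertices, radius, clip = FALSE) {
  m <- buffer_mask(grid, vertices, radius, clip = clip)
  n <- sum(m)
  if (n == 0L) stop("buffer contains no cell centres", call. = FALSE)
  out <- 100 * sum(grid$cover[m]) / n
  attr(out, "clipped") <- attr(m, "clipped")
  out
}

#' Proportions of cover categories within a buffer
#'
#' Aggregates the binary cover grid to `block_size` x `block_size` blocks
#' (30 m Landsat-style pixels by default), computes block percent cover,
#' classifies blocks as 0%, (0,10)%, [10,20]% or >20% cover, and returns
#' the within-buffer proportion of each class (blocks weighted by centre-in-
#' buffer membership).  Proportions sum to 1.
#'
#' @inheritParams percent_cover_buffer
#' @param block_size block side (m); must be a multiple of the cell size.
#' @return named numeric vector `c(p0, p_lt10, p_10to20, p_gt20)`.
#' @export
category_proportions <- function(grid, vertices, radius, block_size = 30,
                                 clip = FALSE) {
  validate_landscape(grid)
  cs <- grid$cell_size
  k <- block_size / cs
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf("`block_size` (%g m) must be a multiple of the cell size (%g m); nearest multiples are %g and %g",
                 block_size, cs, floor(k) * cs, ceiling(k) * cs), call. = FALSE)
  }
  k <- as.integer(round(k))
  nr <- nrow(grid$cover) %/% k; nc <- ncol(grid$cover) %/% k
  if (nr == 0L || nc == 0L) stop("grid smaller than one block", call. = FALSE)
  sub <- grid$cover[seq_len(nr * k), seq_len(nc * k), drop = FALSE]
  # block means via row/col aggregation
  bl <- matrix(0, nr, nc)
  ri <- rep(seq_len(nr), each = k); ci <- rep(seq_len(nc), each = k)
  bl <- rowsum(t(rowsum(sub, ri)), ci) / (k * k)
  bl <- t(bl)  # nr x nc block percent-cover/100
  bpc <- 100 * bl
  bgrid <- structure(list(cover = matrix(0L, nr, nc), dem = matrix(0, nr, nc),
                          cell_size = block_size, origin = grid$origin),
                     class = "landscape_grid")
  bm <- buffer_mask(bgrid, vertices, radius, clip = clip)
  if (!any(bm)) stop("buffer contains no block centres", call. = FALSE)
  x <- bpc[bm]
  p <- c(p0 = mean(x == 0),
         p_lt10 = mean(x > 0 & x < 10),
         p_10to20 = mean(x >= 10 & x <= 20),
         p_gt20 = mean(x > 20))
  p
}

#' Per-cell slope (degrees) by Horn's finite difference
#'
#' 3x3 Horn stencil on the DEM; border cells are `NA`.
#' @param dem elevation matrix (m), row 1 southernmost.
#' @param cell_size cell side (m).
#' @return matrix of slope in degrees.
#' @export
horn_slope <- function(dem, cell_size) {
  nr <- nrow(dem); nc <- ncol(dem)
  sl <- matrix(NA_real_, nr, nc)
  if (nr < 3L || nc < 3L) return(sl)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  z <- function(di, dj) dem[i + di, j + dj, drop = FALSE]
  gx <- ((z(1, 1) + 2 * z(0, 1) + z(-1, 1)) -
         (z(1, -1) + 2 * z(0, -1) + z(-1, -1))) / (8 * cell_size)
  gy <- ((z(1, -1) + 2 * z(1, 0) + z(1, 1)) -
         (z(-1, -1) + 2 * z(-1, 0) + z(-1, 1))) / (8 * cell_size)
  sl[i, j] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  sl
}

#' Distance from a transect to the nearest cliff
#'
#' Cliffs are DEM cells whose Horn slope exceeds `slope_threshold_deg`
#' (60 degrees by default).  Returns the minimum Euclidean distance (m) from
#' the transect polyline to any cliff-cell centre, or `Inf` — the documented
#' "no cliff on this landscape" sentinel — when no cell exceeds the
#' threshold (e.g. a flat DEM).
#'
#' @param grid a `landscape_grid`.
#' @param vertices transect vertex matrix (m).
#' @param slope_threshold_deg slope threshold in (0, 90).
#' @return distance in metres, or `Inf` if no cliff cells exist.
#' @export
cliff_distance <- function(grid, vertices, slope_threshold_deg = 60) {
  validate_landscape(grid)
  if (slope_threshold_deg <= 0 || slope_threshold_deg >= 90) {
    stop("`slope_threshold_deg` must be in (0, 90)", call. = FALSE)
  }
  sl <- horn_slope(grid$dem, grid$cell_size)
  idx <- which(!is.na(sl) & sl > slope_threshold_deg, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(Inf)
  cc <- cell_centers(grid)
  px <- cc$x[idx[, 2]]; py <- cc$y[idx[, 1]]
  min(dist_to_polyline(px, py, as.matrix(vertices)))
}

#' Minimum distance from a transect to a feature set
#'
#' @param vertices transect vertex matrix (m).
#' @param features list of feature geometries: 2-column vertex matrices
#'   (1 row = point, >1 rows = polyline).
#' @return minimum distance in metres (0 iff intersecting).
#' @export
distance_to_feature <- function(vertices, features) {
  if (!length(features)) stop("feature set is empty", call. = FALSE)
  min(vapply(features, function(f) {
    dist_polyline_polyline(as.matrix(vertices), as.matrix(f))
  }, numeric(1)))
}

#' Average nearest-neighbour clustering ratio of tree cells near a transect
#'
#' Observed mean nearest-neighbour distance among tree-cell centres within
#' `radius` of the transect, divided by the expectation under complete
#' spatial randomness at the same density, `0.5 / sqrt(lambda)` with
#' `lambda` = points per unit buffer area.  Ratios below 1 indicate
#' clustering, above 1 dispersion.
#'
#' @inheritParams percent_cover_buffer
#' @return the ratio, or `NA` (with a warning) when fewer than two tree
#'   cells fall in the buffer.
#' @export
clustering_index <- function(grid, vertices, radius, clip = FALSE) {
  m <- buffer_mask(grid, vertices, radius, clip = clip)
  idx <- which(m & grid$cover == 1L, arr.ind = TRUE)
  if (nrow(idx) < 2L) {
    warning("fewer than two tree cells in buffer; clustering index undefined")
    return(NA_real_)
  }
  cc <- cell_centers(grid)
  pts <- cbind(cc$x[idx[, 2]], cc$y[idx[, 1]])
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  obs <- mean(apply(d, 1L, min))
  area <- sum(m) * grid$cell_size^2
  lambda <- nrow(pts) / area
  exp_csr <- 0.5 / sqrt(lambda)
  obs / exp_csr
}

#' Terrain roughness index over a transect buffer
#'
#' Per-cell TRI is the mean absolute elevation difference between a cell and
#' its 8 neighbours (Riley-style mean-absolute-difference variant); the
#' transect value is the mean of per-cell TRI over buffer cells with a full
#' neighbourhood.
#'
#' @inheritParams percent_cover_buffer
#' @return TRI in metres.
#' @export
tri_index <- function(grid, vertices, radius, clip = FALSE) {
  m <- buffer_mask(grid, vertices, radius, clip = clip)
  tri <- tri_cells(grid$dem)
  vals <- tri[m & !is.na(tri)]
  if (!length(vals)) stop("no interior cells in buffer for TRI", call. = FALSE)
  mean(vals)
}

# Per-cell TRI matrix (NA on the border).
tri_cells <- function(dem) {
  nr <- nrow(dem); nc <- ncol(dem)
  out <- matrix(NA_real_, nr, nc)
  if (nr < 3L || nc < 3L) return(out)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  z0 <- dem[i, j, drop = FALSE]
  acc <- matrix(0, length(i), length(j))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    acc <- acc + abs(dem[i + di, j + dj, drop = FALSE] - z0)
  }
  out[i, j] <- acc / 8
  out
}

#' Predict prey covariates from habitat measurements
#'
#' Applies the configured quadratic density models (deer mouse on juniper
#' cover within 100 m, pocket mouse on mean sagebrush cover), computes the
#' pooled unadjusted songbird relative-abundance index (mean raw count over
#' a transect's point-count stations and visits), and passes ground-squirrel
#' presence through as a categorical column.  Negative predicted densities
#' are floored at zero with a warning.
#'
#' @param site_covs data frame with columns `juniper_100` (percent) and
#'   `sagebrush` (percent); one row per site(-year).
#' @param prey_coefficients list with numeric `deer = c(a, b, c)` and
#'   `pocket = c(a, b, c)` giving `a + b*x + c*x^2` on the percent scale.
#' @param songbird_counts optional matrix of raw point counts (rows =
#'   sites, columns = station x visit); its row means become
#'   `songbird_abundance`.
#' @param squirrel optional 0/1 vector of ground-squirrel presence.
#' @return data frame of prey covariate columns.
#' @export
predict_prey_covariates <- function(site_covs, prey_coefficients,
                                    songbird_counts = NULL, squirrel = NULL) {
  if (is.null(prey_coefficients$deer) || is.null(prey_coefficients$pocket)) {
    stop("prey coefficient configuration missing `deer` and/or `pocket`",
         call. = FALSE)
  }
  quad <- function(cf, x) cf[1] + cf[2] * x + cf[3] * x^2
  deer <- quad(prey_coefficients$deer, site_covs$juniper_100)
  pock <- quad(prey_coefficients$pocket, site_covs$sagebrush)
  if (any(deer < 0) || any(pock < 0)) {
    warning(sprintf("%d negative predicted densities floored at 0",
                    sum(deer < 0) + sum(pock < 0)))
  }
  out <- data.frame(deer_mouse_density = pmax(deer, 0),
                    pocket_mouse_density = pmax(pock, 0))
  if (!is.null(songbird_counts)) {
    out$songbird_abundance <- rowMeans(as.matrix(songbird_counts), na.rm = TRUE)
  }
  if (!is.null(squirrel)) out$ground_squirrel <- as.integer(squirrel)
  out
}

#' Standardize covariate columns to mean 0, SD 1
#'
#' Sample (n-1) standard deviation; categorical/identifier columns listed in
#' `exclude` pass through untouched.  The returned means and SDs allow an
#' exact inverse transform and the standardization of new data with stored
#' statistics.
#'
#' @param table data frame of covariates.
#' @param exclude character vector of column names left untouched.
#' @param stats optional list `(means, sds)` from a previous call; when
#'   supplied those statistics are applied instead of recomputing.
#' @return list with `table`, `means`, `sds`.
#' @export
standardize_covariates <- function(table, exclude = character(), stats = NULL) {
  num <- vapply(table, is.numeric, logical(1))
  cols <- setdiff(names(table)[num], exclude)
  if (is.null(stats)) {
    means <- vapply(table[cols], mean, numeric(1))
    sds <- vapply(table[cols], stats::sd, numeric(1))
    bad <- cols[sds == 0 | !is.finite(sds)]
    if (length(bad)) {
      stop(sprintf("zero-variance column(s) cannot be standardized: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  } else {
    means <- stats$means[cols]; sds <- stats$sds[cols]
  }
  out <- table
  for (cl in cols) out[[cl]] <- (table[[cl]] - means[[cl]]) / sds[[cl]]
  list(table = out, means = means, sds = sds)
}

#' @rdname standardize_covariates
#' @param std a list returned by [standardize_covariates()].
#' @return `unstandardize_covariates()`: the table on the original scale.
#' @export
unstandardize_covariates <- function(std) {
  out <- std$table
  for (cl in names(std$means)) {
    out[[cl]] <- out[[cl]] * std$sds[[cl]] + std$means[[cl]]
  }
  out
}
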