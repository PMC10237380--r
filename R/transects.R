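#' Default juniper-cover strata for transect placement
#'
#' The three cover categories used to stratify survey transects:
#' 1-10%, 10-20% and >20% juniper cover within 100 m.
#' @return named list of `(lo, hi]` percent-cover ranges.
#' @export
default_strata <- function() {
  list("1-10%" = c(1, 10), "10-20%" = c(10, 20), ">20%" = c(20, 100))
}

#' Place stratified 800-m survey transects on a landscape
#'
#' Draws random straight transects (random start point and bearing, length
#' `transect_length`) and accepts one when its `buffer_radius`-buffer
#' percent juniper cover falls inside the requested stratum and the whole
#' buffer lies on the grid; mirrors GIS placement from random points
#' stratified by cover category.
#'
#' @param grid a `landscape_grid`.
#' @param n_per_stratum integer vector, transects per stratum, same length
#'   as `strata`.
#' @param strata named list of `(lo, hi]` percent-cover ranges
#'   (default [default_strata()]).
#' @param seed integer RNG seed (placement is deterministic given the seed).
#' @param transect_length transect length in metres (800).
#' @param buffer_radius radius (m) at which the stratum condition is
#'   evaluated (100).
#' @param n_treated number of transects randomly flagged for the removal
#'   treatment (0 = none).
#' @param max_tries rejection-sampling attempts per transect before the
#'   stratum is declared unsatisfiable.
#' @return a `transect_set`: list of transects, each with `id`, `vertices`
#'   (2-column matrix, m), `stratum`, `treated`, and `cover100` (the percent
#'   cover at acceptance time).
#' @export
place_transects <- function(grid, n_per_stratum, strata = default_strata(),
                            seed = 1L, transect_length = 800,
                            buffer_radius = 100, n_treated = 0L,
                            max_tries = 4000L) {
  validate_landscape(grid)
  if (length(n_per_stratum) != length(strata)) {
    stop("`n_per_stratum` must match `strata` in length", call. = FALSE)
  }
  set.seed(as.integer(seed))
  nr <- nrow(grid$cover); nc <- ncol(grid$cover); cs <- grid$cell_size
  xmax <- grid$origin[1] + nc * cs; ymax <- grid$origin[2] + nr * cs
  pad <- buffer_radius + 1e-9

  transects <- list(); id <- 0L
  for (s in seq_along(strata)) {
    rng <- strata[[s]]
    for (k in seq_len(n_per_stratum[s])) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        x0 <- stats::runif(1, grid$origin[1] + pad, xmax - pad)
        y0 <- stats::runif(1, grid$origin[2] + pad, ymax - pad)
        ang <- stats::runif(1, 0, 2 * pi)
        x1 <- x0 + transect_length * cos(ang)
        y1 <- y0 + transect_length * sin(ang)
        if (x1 < grid$origin[1] + pad || x1 > xmax - pad ||
            y1 < grid$origin[2] + pad || y1 > ymax - pad) next
        v <- rbind(c(x0, y0), c(x1, y1))
        pc <- percent_cover_buffer(grid, v, buffer_radius)
        if (pc > rng[1] && pc <= rng[2]) {
          id <- id + 1L
          transects[[id]] <- list(id = id, vertices = v,
                                  stratum = names(strata)[s],
                                  treated = FALSE, cover100 = pc)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf("stratum unsatisfiable: no location with cover in (%g, %g]%% found for stratum \"%s\"",
                     rng[1], rng[2], names(strata)[s]), call. = FALSE)
      }
    }
  }
  if (n_treated > 0L) {
    if (n_treated > length(transects)) {
      stop("`n_treated` exceeds the number of transects", call. = FALSE)
    }
    tr_id <- sample(seq_along(transects), n_treated)
    for (i in tr_id) transects[[i]]$treated <- TRUE
  }
  structure(list(transects = transects, buffer_radius = buffer_radius),
            class = "transect_set")
}

#' @export
as.data.frame.transect_set <- function(x, ...) {
  do.call(rbind, lapply(x$transects, function(tr) {
    data.frame(id = tr$id, stratum = tr$stratum, treated = tr$treated,
               cover100 = tr$cover100,
               x0 = tr$vertices[1, 1], y0 = tr$vertices[1, 2],
               x1 = tr$vertices[nrow(tr$vertices), 1],
               y1 = tr$vertices[nrow(tr$vertices), 2])
  }))
}

#' @export
length.transect_set <- function(x) length(x$transects)

#' Generate simple landscape feature sets (streams, ponds, roads, dwellings)
#'
#' Random planar features used for the distance-to-feature covariates:
#' streams are meandering polylines, ponds and dwellings are points, roads
#' are long straight polylines.  Purely synthetic plumbing for the
#' generator; geometry is planar metres.
#'
#' @param grid a `landscape_grid`.
#' @param seed integer RNG seed.
#' @param n_streams,n_ponds,n_roads,n_dwellings feature counts.
#' @return named list of feature sets; each set is a list of 2-column
#'   vertex matrices (a 1-row matrix is a point).
#' @export
generate_features <- function(grid, seed = 1L, n_streams = 3L, n_ponds = 4L,
                              n_roads = 2L, n_dwellings = 2L) {
  validate_landscape(grid)
  set.seed(as.integer(seed))
  nr <- nrow(grid$cover); nc <- ncol(grid$cover); cs <- grid$cell_size
  xmax <- nc * cs; ymax <- nr * cs
  meander <- function() {
    n <- 12L
    x <- seq(0, xmax, length.out = n)
    y <- cumsum(stats::rnorm(n, 0, ymax / 15))
    y <- stats::runif(1, 0.2, 0.8) * ymax + y - mean(y)
    cbind(x, pmin(pmax(y, 0), ymax))
  }
  pts <- function(n) lapply(seq_len(n), function(i) {
    cbind(stats::runif(1, 0, xmax), stats::runif(1, 0, ymax))
  })
  streams <- lapply(seq_len(n_streams), function(i) meander())
  roads <- lapply(seq_len(n_roads), function(i) {
    a <- stats::runif(1, 0, pi)
    cx <- stats::runif(1, 0.2, 0.8) * xmax; cy <- stats::runif(1, 0.2, 0.8) * ymax
    L <- sqrt(xmax^2 + ymax^2)
    v <- rbind(c(cx - L * cos(a), cy - L * sin(a)), c(cx + L * cos(a), cy + L * sin(a)))
    v[, 1] <- pmin(pmax(v[, 1], 0), xmax); v[, 2] <- pmin(pmax(v[, 2], 0), ymax)
    v
  })
  ponds <- pts(n_ponds)
  dwellings <- pts(n_dwellings)
  list(stream = streams, water = c(streams, ponds), road = roads,
       dwelling = dwellings)
}
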