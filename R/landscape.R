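#' Synthetic clustered tree-cover landscape with a smooth DEM
#'
#' Generates a binary tree-cover grid and a co-registered elevation model on
#' a planar metric grid.  Tree cells are placed by thresholding a clustered
#' intensity surface (Gaussian kernels around Poisson parent points, a
#' Matern-style parent-offspring construction), which reproduces the patchy
#' "dense stands along ridgetops and in drainages" character of juniper
#' woodland rather than salt-and-pepper noise.  The threshold is the
#' empirical quantile of the intensity surface, so the realised cover
#' fraction matches `fill_fraction` to within one cell.
#'
#' @param seed integer RNG seed; output is bit-identical for a fixed seed.
#' @param shape integer vector `c(nrow, ncol)` of grid cells.
#' @param cell_size cell side length in metres.
#' @param cluster_intensity expected number of cluster parents per km^2.
#' @param fill_fraction target tree-cover fraction in `[0, 1]`.
#' @param cluster_sd standard deviation (m) of the offspring kernel around
#'   each parent; controls patch size.
#' @param relief_amplitude half-range (m) of the synthetic terrain relief.
#' @param dem_ridge_wavelength wavelength (m) of the dominant ridge/drainage
#'   pattern in the DEM.
#' @return an object of class `landscape_grid`: list with `cover` (0/1
#'   matrix), `dem` (matrix, metres), `cell_size`, and `origin` (x0, y0 of
#'   the lower-left grid corner, metres).
#' @export
generate_landscape <- function(seed, shape = c(300L, 300L), cell_size = 10,
                               cluster_intensity = 60, fill_fraction = 0.2,
                               cluster_sd = 60, relief_amplitude = 120,
                               dem_ridge_wavelength = 1500) {
  if (length(shape) != 2L || any(shape < 1) || any(shape != round(shape))) {
    stop("`shape` must be two positive integers (nrow, ncol)", call. = FALSE)
  }
  stopifnot_scalar_number(cell_size, "cell_size")
  if (cell_size <= 0) stop("`cell_size` must be > 0", call. = FALSE)
  stopifnot_scalar_number(fill_fraction, "fill_fraction")
  if (fill_fraction < 0 || fill_fraction > 1) {
    stop("`fill_fraction` must be in [0, 1]", call. = FALSE)
  }
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  width <- nc * cell_size; height <- nr * cell_size

  set.seed(as.integer(seed))
  # cell centres, row 1 = southernmost row (y smallest)
  xc <- (seq_len(nc) - 0.5) * cell_size
  yc <- (seq_len(nr) - 0.5) * cell_size

  cover <- matrix(0L, nr, nc)
  if (fill_fraction > 0) {
    area_km2 <- width * height / 1e6
    n_par <- max(1L, stats::rpois(1, cluster_intensity * area_km2))
    px <- stats::runif(n_par, 0, width)
    py <- stats::runif(n_par, 0, height)
    pw <- stats::rgamma(n_par, shape = 2, rate = 2)  # unequal patch weights
    inten <- matrix(0, nr, nc)
    for (k in seq_len(n_par)) {
      dx2 <- outer(rep(1, nr), (xc - px[k])^2)
      dy2 <- outer((yc - py[k])^2, rep(1, nc))
      inten <- inten + pw[k] * exp(-(dx2 + dy2) / (2 * cluster_sd^2))
    }
    # small i.i.d. jitter breaks ties and roughens patch edges
    inten <- inten + stats::runif(nr * nc, 0, 1e-3 * max(inten, 1e-12))
    if (fill_fraction >= 1) {
      cover[] <- 1L
    } else {
      thr <- stats::quantile(inten, probs = 1 - fill_fraction, names = FALSE)
      cover[inten > thr] <- 1L
      # quantile ties can leave the count off by a few cells; fix exactly
      target <- round(fill_fraction * nr * nc)
      excess <- sum(cover) - target
      if (excess > 0) {
        on <- which(cover == 1L)
        cover[on[order(inten[on])[seq_len(excess)]]] <- 0L
      } else if (excess < 0) {
        off <- which(cover == 0L)
        cover[off[order(inten[off], decreasing = TRUE)[seq_len(-excess)]]] <- 1L
      }
    }
  }

  # DEM: broad sinusoidal ridges/drainages plus smooth random undulation
  ph <- stats::runif(4, 0, 2 * pi)
  th <- stats::runif(1, 0, pi)
  gx <- outer(rep(1, nr), xc); gy <- outer(yc, rep(1, nc))
  u <- gx * cos(th) + gy * sin(th)
  v <- -gx * sin(th) + gy * cos(th)
  w <- 2 * pi / dem_ridge_wavelength
  dem <- 1400 +
    relief_amplitude * (0.6 * sin(w * u + ph[1]) +
                        0.3 * sin(2.3 * w * v + ph[2]) +
                        0.1 * sin(1.7 * w * (u + v) + ph[3]))
  out <- structure(list(cover = cover, dem = dem, cell_size = cell_size,
                        origin = c(0, 0)),
                   class = "landscape_grid")
  validate_landscape(out)
  out
}

validate_landscape <- function(g) {
  stopifnot(inherits(g, "landscape_grid"))
  if (!all(g$cover %in% c(0L, 1L))) stop("cover values must be 0/1", call. = FALSE)
  if (!all(is.finite(g$dem))) stop("dem must be finite", call. = FALSE)
  if (!identical(dim(g$cover), dim(g$dem))) {
    stop("cover and dem must have identical shape", call. = FALSE)
  }
  if (g$cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  invisible(g)
}

#' Cell-centre coordinates of a landscape grid
#'
#' @param grid a `landscape_grid`.
#' @return list with vectors `x` (ncol) and `y` (nrow), plus full-grid
#'   matrices `X`, `Y` of centre coordinates in metres.
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$cover); nc <- ncol(grid$cover); cs <- grid$cell_size
  x <- grid$origin[1] + (seq_len(nc) - 0.5) * cs
  y <- grid$origin[2] + (seq_len(nr) - 0.5) * cs
  list(x = x, y = y,
       X = outer(rep(1, nr), x), Y = outer(y, rep(1, nc)))
}

#' Write / read a grid layer as ESRI ASCII raster
#'
#' Plain-text raster interchange (`.asc`): a 6-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows north to
#' south.  Used for all grid I/O so that every artefact of a run is
#' human-readable text.
#'
#' @param mat numeric matrix (row 1 = southernmost row).
#' @param path file path.
#' @param cell_size,origin grid geometry in metres.
#' @export
write_ascii_grid <- function(mat, path, cell_size, origin = c(0, 0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(mat)),
    sprintf("nrows %d", nrow(mat)),
    sprintf("xllcorner %.6f", origin[1]),
    sprintf("yllcorner %.6f", origin[2]),
    sprintf("cellsize %.6f", cell_size),
    "NODATA_value -9999"), con)
  # file rows run north -> south
  utils::write.table(mat[rev(seq_len(nrow(mat))), , drop = FALSE], con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @return `read_ascii_grid()`: list with `mat`, `cell_size`, `origin`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  val <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  mat <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(mat) <- NULL
  list(mat = mat[rev(seq_len(nrow(mat))), , drop = FALSE],
       cell_size = unname(val["cellsize"]),
       origin = unname(c(val["xllcorner"], val["yllcorner"])))
}

#' Apply a juniper-removal treatment to a landscape
#'
#' Sets cover cells within `radius` of each treated transect to 0,
#' mirroring near-complete hand-cutting of juniper inside treated transect
#' buffers.  Used to build the post-removal cover grid from which
#' time-varying covariates are recomputed.
#'
#' @param grid a `landscape_grid`.
#' @param transects a `transect_set` (see [place_transects()]).
#' @param radius buffer radius in metres (default 100).
#' @return a new `landscape_grid` with treated-buffer cover removed.
#' @export
apply_removal <- function(grid, transects, radius = 100) {
  validate_landscape(grid)
  cc <- cell_centers(grid)
  out <- grid
  for (tr in transects$transects) {
    if (!isTRUE(tr$treated)) next
    d <- dist_to_polyline(cc$X, cc$Y, tr$vertices)
    out$cover[d <= radius & out$cover == 1L] <- 0L
  }
  out
}
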