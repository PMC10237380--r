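flat_grid <- function(nr = 40, nc = 40, cover = 0L, cell = 10, dem = 0) {
  structure(list(cover = matrix(as.integer(cover), nr, nc),
                 dem = matrix(dem, nr, nc), cell_size = cell,
                 origin = c(0, 0)),
            class = "landscape_grid")
}
mid_transect <- function(g, len = 100) {
  ext <- dim(g$cover) * g$cell_size
  rbind(c(ext[2] / 2 - len / 2, ext[1] / 2), c(ext[2] / 2 + len / 2, ext[1] / 2))
}

test_that("buffer percent cover: extremes, direct-count oracle, bounds", {
  g1 <- flat_grid(cover = 1L)
  tr <- mid_transect(g1)
  expect_equal(percent_cover_buffer(g1, tr, 120), 100, ignore_attr = TRUE)
  g0 <- flat_grid(cover = 0L)
  expect_equal(percent_cover_buffer(g0, tr, 120), 0, ignore_attr = TRUE)

  set.seed(4)
  g <- flat_grid(nr = 100, nc = 100, cell = 10)
  g$cover[] <- rbinom(1e4, 1, 0.25)
  trc <- mid_transect(g)
  # radius spanning the whole grid, clipped at the edges
  pc <- percent_cover_buffer(g, trc, 2000, clip = TRUE)
  expect_lt(abs(pc - 25), 1)
  # oracle: direct count over an independently constructed buffer mask
  cc <- cell_centers(g)
  d <- pmin(sqrt((cc$X - trc[1, 1])^2 + (cc$Y - trc[1, 2])^2),
            sqrt((cc$X - trc[2, 1])^2 + (cc$Y - trc[2, 2])^2))
  seg <- cc$X >= trc[1, 1] & cc$X <= trc[2, 1]
  d[seg] <- pmin(d[seg], abs(cc$Y - trc[1, 2])[seg])
  inb <- d <= 400
  expect_equal(as.numeric(percent_cover_buffer(g, trc, 400)),
               100 * sum(g$cover[inb]) / sum(inb))

  expect_error(percent_cover_buffer(g, trc, 2000), "clip")
  expect_error(percent_cover_buffer(g, trc, -5), "radius")
})

test_that("adding a tree cell inside the buffer never lowers percent cover", {
  set.seed(8)
  g <- flat_grid(nr = 60, nc = 60)
  g$cover[] <- rbinom(3600, 1, 0.2)
  tr <- mid_transect(g)
  base <- percent_cover_buffer(g, tr, 150)
  empties <- which(g$cover == 0L)
  for (k in sample(empties, 20)) {
    g2 <- g
    g2$cover[k] <- 1L
    expect_gte(percent_cover_buffer(g2, tr, 150), base)
  }
})

test_that("category proportions classify blocks correctly and sum to one", {
  # uniform blocks: every 3x3-cell block (30 m) has 2/9 = 22.2% cover
  g <- flat_grid(nr = 60, nc = 60, cell = 10)
  g$cover[(row(g$cover) %% 3 == 0) & (col(g$cover) %% 3 %in% c(0, 1))] <- 1L
  tr <- mid_transect(g)
  p <- category_proportions(g, tr, 150)
  expect_equal(sum(p), 1)
  expect_equal(unname(p["p_gt20"]), 1)

  g0 <- flat_grid(nr = 60, nc = 60, cell = 10)
  p0 <- category_proportions(g0, mid_transect(g0), 150)
  expect_equal(unname(p0["p0"]), 1)

  # checkerboard of 0% and ~15% blocks, emulated on a 10-m grid with
  # 9-cell (30 m) blocks
  gf <- flat_grid(nr = 60, nc = 60, cell = 10)
  bi <- (floor((row(gf$cover) - 1) / 3) + floor((col(gf$cover) - 1) / 3)) %% 2 == 0
  # in "on" blocks set 1 of 9 cells -> 11.1% (inside [10, 20])
  on <- bi & (row(gf$cover) %% 3 == 1) & (col(gf$cover) %% 3 == 1)
  gf$cover[on] <- 1L
  pf <- category_proportions(gf, mid_transect(gf), 250, clip = TRUE)
  expect_equal(unname(pf["p_10to20"]), 0.5, tolerance = 0.05)
  expect_equal(unname(pf["p0"]), 0.5, tolerance = 0.05)
  expect_equal(sum(pf), 1)

  expect_error(category_proportions(gf, mid_transect(gf), 150, block_size = 25),
               "multiple")
})

test_that("uniformly >20% block cover forces p_gt20 = 1 (consistency)", {
  g <- flat_grid(nr = 60, nc = 60, cell = 10)
  g$cover[row(g$cover) %% 3 != 0] <- 1L   # 2/3 cover everywhere
  tr <- mid_transect(g)
  expect_gt(as.numeric(percent_cover_buffer(g, tr, 150)), 20)
  expect_equal(unname(category_proportions(g, tr, 150)["p_gt20"]), 1)
})

test_that("cliff distance: sentinel on flat/shallow DEMs, analytic on ramps", {
  flat <- flat_grid(nr = 50, nc = 50, dem = 100)
  tr <- mid_transect(flat)
  expect_identical(cliff_distance(flat, tr), Inf)

  # planar ramp, rise/run 1.0 = 45 degrees: below the 60-degree threshold
  r45 <- flat_grid(nr = 50, nc = 50, cell = 10)
  r45$dem <- outer(rep(1, 50), (1:50) * 10 * 1.0)
  expect_identical(cliff_distance(r45, tr), Inf)

  # rise/run 2.0 = 63.4 degrees: every interior cell is cliff; the nearest
  # interior cell centre to the transect midline is directly adjacent
  r63 <- flat_grid(nr = 50, nc = 50, cell = 10)
  r63$dem <- outer(rep(1, 50), (1:50) * 10 * 2.0)
  slope_deg <- atan(2.0) * 180 / pi
  expect_gt(slope_deg, 60)
  d <- cliff_distance(r63, tr)
  # transect runs along y = 250; cell-centre rows sit at 245 and 255, so
  # the nearest interior cliff-cell centre is 5 m away
  expect_equal(d, 5)

  # invariance to adding a constant
  r63b <- r63; r63b$dem <- r63$dem + 500
  expect_equal(cliff_distance(r63b, tr), d)
})

test_that("distance to feature matches geometry and brute force", {
  tr <- rbind(c(0, 0), c(800, 0))
  crossing <- list(rbind(c(400, -50), c(400, 50)))
  expect_equal(distance_to_feature(tr, crossing), 0)
  point <- list(cbind(400, 250))
  expect_equal(distance_to_feature(tr, point), 250)
  expect_error(distance_to_feature(tr, list()), "empty")

  set.seed(12)
  cloud <- lapply(1:30, function(i) cbind(runif(1, -500, 1300), runif(1, -600, 600)))
  bf <- min(vapply(cloud, function(p) {
    autocc:::dist_point_segment(p[1], p[2], 0, 0, 800, 0)
  }, numeric(1)))
  expect_equal(distance_to_feature(tr, cloud), bf)
})

test_that("clustering index separates lattices, clusters and CSR", {
  # perfect lattice of isolated trees: dispersed, ratio > 1; oracle by
  # direct NN computation
  g <- flat_grid(nr = 60, nc = 60, cell = 10)
  g$cover[(row(g$cover) %% 5 == 2) & (col(g$cover) %% 5 == 2)] <- 1L
  tr <- mid_transect(g)
  ci <- clustering_index(g, tr, 250)
  expect_gt(ci, 1)
  idx <- which(autocc:::buffer_mask(g, tr, 250) & g$cover == 1L, arr.ind = TRUE)
  cc <- cell_centers(g)
  pts <- cbind(cc$x[idx[, 2]], cc$y[idx[, 1]])
  dm <- as.matrix(dist(pts)); diag(dm) <- Inf
  obs <- mean(apply(dm, 1, min))
  lam <- nrow(pts) / (sum(autocc:::buffer_mask(g, tr, 250)) * 100)
  expect_equal(ci, obs / (0.5 / sqrt(lam)))

  # large CSR simulation: ratio ~ 1 (cell-centre discretisation tolerated)
  set.seed(3)
  gc <- flat_grid(nr = 120, nc = 120, cell = 10)
  gc$cover[] <- rbinom(120^2, 1, 0.05)
  cic <- clustering_index(gc, mid_transect(gc), 500)
  expect_lt(abs(cic - 1), 0.15)

  gl <- flat_grid(nr = 30, nc = 30)
  gl$cover[1, 1] <- 1L
  expect_warning(ci1 <- clustering_index(gl, mid_transect(gl), 200, clip = TRUE),
                 "fewer than two")
  expect_true(is.na(ci1))
})

test_that("TRI is zero on flat terrain and analytic on a linear ramp", {
  flat <- flat_grid(nr = 40, nc = 40, dem = 250)
  expect_equal(tri_index(flat, mid_transect(flat), 100), 0)

  s <- 3.7   # metres of rise per cell along x
  ramp <- flat_grid(nr = 40, nc = 40, cell = 10)
  ramp$dem <- outer(rep(1, 40), (1:40) * s)
  # stencil: 3 neighbours differ by s (left), 3 by s (right), 2 by 0
  expect_equal(tri_index(ramp, mid_transect(ramp), 100), 6 * s / 8)

  # i.i.d. N(0, sigma^2) elevations: E|z_a - z_b| = 2 sigma / sqrt(pi)
  set.seed(5)
  sigma <- 4
  gn <- flat_grid(nr = 150, nc = 150, cell = 10)
  gn$dem <- matrix(rnorm(150^2, 0, sigma), 150, 150)
  expect_equal(tri_index(gn, mid_transect(gn), 600, clip = TRUE),
               2 * sigma / sqrt(pi), tolerance = 0.05)
})

test_that("standardization: convention, idempotence, round trip, errors", {
  tb <- data.frame(a = c(0, 10), b = c(1, -1))
  std <- standardize_covariates(tb)
  expect_equal(std$table$a, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(2)
  tb2 <- data.frame(x = rnorm(50, 5, 3), y = runif(50), id = 1:50)
  std2 <- standardize_covariates(tb2, exclude = "id")
  expect_equal(colMeans(std2$table[c("x", "y")]), c(x = 0, y = 0),
               tolerance = 1e-9)
  expect_equal(vapply(std2$table[c("x", "y")], sd, numeric(1)),
               c(x = 1, y = 1), tolerance = 1e-9)
  expect_identical(std2$table$id, tb2$id)
  # round trip
  back <- unstandardize_covariates(std2)
  expect_equal(back$x, tb2$x, tolerance = 1e-9)
  # re-application with stored stats is the identity on standardized data
  again <- standardize_covariates(std2$table, exclude = "id",
                                  stats = list(means = c(x = 0, y = 0),
                                               sds = c(x = 1, y = 1)))
  expect_equal(again$table$x, std2$table$x, tolerance = 1e-12)

  tb3 <- data.frame(ok = rnorm(5), flatcol = rep(3, 5))
  expect_error(standardize_covariates(tb3), "flatcol")
})

test_that("songbird index is the arithmetic mean of raw counts", {
  covs <- data.frame(juniper_100 = 5, sagebrush = 10)
  out <- predict_prey_covariates(covs, default_prey_coefficients(),
                                 songbird_counts = matrix(c(4, 6, 8), 1))
  expect_equal(out$songbird_abundance, 6)
})

test_that("synthetic prey quadratic peaks where configured (grid-search oracle)", {
  cf <- default_prey_coefficients(deer_peak = 10)
  grid <- seq(0, 60, by = 0.01)
  dens <- cf$deer[1] + cf$deer[2] * grid + cf$deer[3] * grid^2
  expect_equal(grid[which.max(dens)], 10, tolerance = 0.011)
})
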