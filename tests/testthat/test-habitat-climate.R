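# Use-versus-availability habitat characterisation: bounding boxes,
# quantile binning, zonal tabulation, chi-square goodness of fit,
# representation flags and breeding-site intersection.

# hand-built 6x6 categorical raster with known counts per class
hand_raster <- function() {
  vals <- matrix(rep(0:9, length.out = 36), 6, 6)  # column-major fill
  flyway_raster(vals, xll = 140, yll = -36, cell = 1)
}

test_that("movement bounding boxes span their inputs", {
  ln <- data.frame(lon1 = c(144, 145), lat1 = c(-35, -33),
                   lon2 = c(146, 147), lat2 = c(-31, -34))
  bb <- movement_bbox(ln)
  expect_equal(c(bb$xmin, bb$xmax, bb$ymin, bb$ymax), c(144, 147, -35, -31))
  expect_true(all(ln$lon1 >= bb$xmin & ln$lon2 <= bb$xmax))
  # two points span their box
  pts <- data.frame(lon = c(144, 147), lat = c(-35, -31))
  bb2 <- movement_bbox(pts)
  expect_equal(c(bb2$xmin, bb2$xmax), c(144, 147))
  # degenerate box errors unless padded
  one <- data.frame(lon = 145, lat = -33)
  expect_error(movement_bbox(one), "degenerate")
  bb3 <- movement_bbox(one, margin_deg = 0.5)
  expect_equal(bb3$xmax - bb3$xmin, 1)
})

test_that("quantile bin edges follow the reference-region quantiles", {
  set.seed(51)
  r <- flyway_raster(matrix(runif(2500), 50, 50), xll = 140, yll = -40, cell = 0.1)
  edges <- quantile_bin_edges(r, n_bins = 10, reference = "raster")
  expect_equal(edges, seq(0.1, 0.9, by = 0.1), tolerance = 0.03)
  # binning a region by its own quantiles gives near-uniform proportions
  # (the background row of an elevation-style table: ~0.11 per bin)
  bb <- movement_bbox(data.frame(lon = c(141, 144), lat = c(-39, -36)))
  e9 <- quantile_bin_edges(r, n_bins = 9, reference = "bbox", bbox = bb)
  tab <- tabulate_region(r, bb, edges = e9)
  expect_equal(tab$prop, rep(1 / 9, 9), tolerance = 0.02)
  # constant raster: no quantiles to take
  rc <- flyway_raster(matrix(1, 5, 5), xll = 0, yll = 0, cell = 1)
  expect_error(quantile_bin_edges(rc, n_bins = 3, reference = "raster"),
               "distinct")
})

test_that("zonal tabulation counts cells exactly on a hand-built grid", {
  r <- hand_raster()
  # full-extent bbox: the marginal class distribution (classes 0-5 appear
  # 4 times, 6-9 appear 3 times in 36 cells)
  bb <- structure(list(xmin = 140, xmax = 146, ymin = -36, ymax = -30),
                  class = "flyway_bbox")
  tab <- tabulate_region(r, bb, classes = 0:9)
  expect_equal(tab$count, c(4L, 4L, 4L, 4L, 4L, 4L, 3L, 3L, 3L, 3L))
  expect_equal(sum(tab$prop), 1, tolerance = 1e-12)
  # a bbox covering exactly the first column: cells 0..5, one each
  bb1 <- structure(list(xmin = 140, xmax = 141, ymin = -36, ymax = -30),
                   class = "flyway_bbox")
  tab1 <- tabulate_region(r, bb1, classes = 0:9)
  expect_equal(tab1$count, c(rep(1L, 6), rep(0L, 4)))
  # single-class region
  bbc <- structure(list(xmin = 140, xmax = 141, ymin = -36, ymax = -35),
                   class = "flyway_bbox")
  tabc <- tabulate_region(r, bbc, classes = 0:9)
  expect_equal(tabc$prop[1], 1)
  # empty region errors
  bb0 <- structure(list(xmin = 0, xmax = 1, ymin = 0, ymax = 1),
                   class = "flyway_bbox")
  expect_error(tabulate_region(r, bb0, classes = 0:9), "no valid")
})

test_that("nodata cells are excluded from tabulations", {
  vals <- matrix(1, 4, 4); vals[1, 1] <- NA; vals[2, 2] <- 2
  r <- flyway_raster(vals, xll = 0, yll = 0, cell = 1)
  bb <- structure(list(xmin = 0, xmax = 4, ymin = 0, ymax = 4),
                  class = "flyway_bbox")
  tab <- tabulate_region(r, bb, classes = c(1, 2))
  expect_equal(sum(tab$count), 15)
})

test_that("chi-square GOF matches hand computation and stats::chisq.test", {
  out <- chisq_gof(c(10, 20, 30), rep(1 / 3, 3))
  expect_equal(out$statistic, 10)   # E = 20 each: (100 + 0 + 100)/20
  expect_equal(out$df, 2)
  expect_equal(out$p_value, pchisq(10, 2, lower.tail = FALSE))
  # exact proportionality gives zero
  expect_equal(chisq_gof(c(5, 10, 25), c(5, 10, 25) / 40)$statistic, 0)
  # any 10-bin comparison has df = 9
  expect_equal(chisq_gof(rep(7, 10), rep(0.1, 10))$df, 9)
  # agreement with the textbook implementation on random tables
  set.seed(52)
  for (i in 1:100) {
    k <- sample(3:12, 1)
    obs <- rpois(k, lambda = sample(5:50, 1)) + 1
    pr <- rgamma(k, 1) + 0.05; pr <- pr / sum(pr)
    mine <- chisq_gof(obs, pr)
    ref <- suppressWarnings(stats::chisq.test(obs, p = pr))
    expect_lt(abs(mine$statistic - unname(ref$statistic)), 1e-9)
    expect_equal(mine$df, unname(ref$parameter))
    expect_lt(abs(mine$p_value - ref$p.value), 1e-9)
  }
  # zero-expected bin with observations: infinite statistic, warning
  expect_warning(z <- chisq_gof(c(5, 5), c(1, 0)), "infinite")
  expect_equal(z$statistic, Inf)
  expect_error(chisq_gof(c(1, 2), c(0.5, 0.4, 0.1)), "misaligned")
  expect_error(chisq_gof(c(1, 2), c(0.7, 0.7)), "sum to 1")
})

test_that("representation flags use the relative-difference threshold", {
  # the flatness-table pattern: 0.33 used vs 0.13 available -> over;
  # 0.11 used vs 0.24 available -> under; equal -> neutral
  expect_equal(representation_flags(0.33, 0.13), "over")
  expect_equal(representation_flags(0.11, 0.24), "under")
  expect_equal(representation_flags(0.2, 0.2), "neutral")
  expect_equal(representation_flags(c(0.23, 0.17, 0.2), rep(0.2, 3)),
               c("neutral", "neutral", "neutral"))
  expect_equal(representation_flags(c(0.25, 0.15), rep(0.2, 2), threshold = 0.2),
               c("over", "under"))
  expect_warning(f <- representation_flags(0.1, 0), "absent")
  expect_equal(f, "over")
})

test_that("covariate comparison assembles aligned tables with flags", {
  set.seed(53)
  env <- generate_environment(seed = 54)
  used <- make_rect_region(-80, 80, -80, 80, cell = 5, grid_x = c(-300, 300),
                           grid_y = c(-300, 300), center = c(146.5, -32.5))
  bb <- structure(list(xmin = 142, xmax = 151, ymin = -37, ymax = -28),
                  class = "flyway_bbox")
  cmp <- compare_covariate(env$flatness, used, bb, kind = "categorical")
  expect_equal(sum(cmp$table$prop_inside), 1, tolerance = 1e-9)
  expect_equal(sum(cmp$table$prop_bbox), 1, tolerance = 1e-9)
  expect_equal(cmp$chisq$df, nrow(cmp$table) - 1)
  expect_true(all(cmp$table$flag %in% c("over", "under", "neutral")))
  cmp2 <- compare_covariate(env$elevation, used, bb, kind = "quantile",
                            n_bins = 9, reference = "bbox")
  expect_equal(cmp2$table$prop_bbox, rep(1 / 9, 9), tolerance = 0.02)
})

test_that("breeding-site intersection honours the buffer", {
  reg <- make_rect_region(0, 50, 0, 50, cell = 1, grid_x = c(-100, 100),
                          grid_y = c(-100, 100))
  ctr <- unproject_laea(25, 25, 146, -33)       # region centroid
  near <- unproject_laea(55, 25, 146, -33)      # ~5 km outside the east edge
  far <- unproject_laea(90, 90, 146, -33)
  sites <- data.frame(name = c("inside", "near", "far"),
                      lon = c(ctr[1], near[1], far[1]),
                      lat = c(ctr[2], near[2], far[2]),
                      stringsAsFactors = FALSE)
  expect_equal(intersect_sites(reg, sites)$name, "inside")
  # the haversine distance from the near site to the region edge is ~5 km,
  # so a 10 km buffer admits it and a 2 km buffer does not
  expect_equal(intersect_sites(reg, sites, buffer_km = 10)$name,
               c("inside", "near"))
  expect_equal(intersect_sites(reg, sites, buffer_km = 2)$name, "inside")
  expect_equal(nrow(intersect_sites(reg, sites[0, ])), 0)
})

test_that("ESRI ASCII rasters round-trip through files", {
  set.seed(55)
  vals <- matrix(round(runif(30, 0, 100), 3), 5, 6)
  vals[2, 3] <- NA
  r <- flyway_raster(vals, xll = 140.25, yll = -36.5, cell = 0.25)
  f <- tempfile(fileext = ".asc")
  write_esri_ascii(r, f)
  r2 <- read_esri_ascii(f)
  expect_equal(r2$values, r$values, tolerance = 1e-9)
  expect_equal(r2$xll, r$xll)
  expect_equal(r2$cell, r$cell)
  expect_equal(r2$nrow, 5); expect_equal(r2$ncol, 6)
})
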