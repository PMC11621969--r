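# Kernel utilization distribution and route contours: line sampling, href,
# grid KDE, mass-defined contours, representativeness, overlap and the href
# sensitivity table.

line_row <- function(lon1, lat1, lon2, lat2, id = "b01") {
  data.frame(individual_id = id, lon1 = lon1, lat1 = lat1,
             lon2 = lon2, lat2 = lat2, stringsAsFactors = FALSE)
}

gauss_points <- function(n, sd = 1, seed = 1, center = c(146, -33)) {
  set.seed(seed)
  out <- data.frame(x = rnorm(n, sd = sd), y = rnorm(n, sd = sd),
                    lon = NA_real_, lat = NA_real_,
                    individual_id = rep(sprintf("b%02d", 1:4), length.out = n))
  ll <- unproject_laea(out$x, out$y, center[1], center[2])
  out$lon <- ll[, 1]; out$lat <- ll[, 2]
  attr(out, "center") <- center
  class(out) <- c("flyway_points", "data.frame")
  out
}

test_that("line sampling yields floor(length/spacing) + 1 points per line", {
  # a ~100 km line: 11 points at 10 km spacing
  p2 <- gc_destination(146, -33, 0, 100)
  pts <- sample_points_on_lines(line_row(146, -33, p2[1], p2[2]), spacing_km = 10)
  expect_equal(nrow(pts), 11)
  # both endpoints present
  expect_equal(pts$lon[1], 146); expect_equal(pts$lat[1], -33)
  expect_equal(pts$lon[11], p2[1], tolerance = 1e-9)
  # zero-length line contributes a single point
  pts0 <- sample_points_on_lines(line_row(146, -33, 146, -33))
  expect_equal(nrow(pts0), 1)
  # counting oracle over a random line set
  set.seed(31)
  lens <- runif(15, 0.5, 300)
  rows <- do.call(rbind, lapply(lens, function(L) {
    d <- gc_destination(146, -33, runif(1, -pi, pi), L)
    line_row(146, -33, d[1], d[2])
  }))
  pts_all <- sample_points_on_lines(rows, spacing_km = 10)
  expect_equal(nrow(pts_all), sum(floor(lens / 10) + 1))
})

test_that("href follows the ad hoc formula", {
  # unit variances, n = 64: h = 64^(-1/6) = 1/2
  set.seed(32)
  pts <- data.frame(x = as.numeric(scale(rnorm(64))), y = as.numeric(scale(rnorm(64))))
  expect_equal(href_adhoc(pts), 0.5, tolerance = 1e-12)
  # direct one-line oracle on a random cloud
  pts2 <- data.frame(x = rnorm(200, sd = 30), y = rnorm(200, sd = 55))
  expect_equal(href_adhoc(pts2),
               sqrt((var(pts2$x) + var(pts2$y)) / 2) * 200^(-1 / 6),
               tolerance = 1e-12)
  # homogeneity: scaling coordinates by c scales h by c
  pts3 <- data.frame(x = pts2$x * 3.7, y = pts2$y * 3.7)
  expect_equal(href_adhoc(pts3), 3.7 * href_adhoc(pts2), tolerance = 1e-10)
  expect_error(href_adhoc(data.frame(x = c(1, 1), y = c(2, 2))), "degenerate")
  expect_error(href_adhoc(data.frame(x = 1, y = 2)), ">= 2")
})

test_that("the UD integrates to one and follows the Gaussian kernel shape", {
  pts <- gauss_points(2000, sd = 20, seed = 33)
  h <- href_adhoc(pts)
  ud <- kde_ud(pts, h)
  expect_equal(sum(ud$z) * ud$cell^2, 1, tolerance = 1e-6)
  expect_true(all(ud$z >= 0))
  # single point: mode cell contains the point; density falls off as
  # exp(-d^2 / 2h^2) from it
  one <- gauss_points(1, seed = 34)
  ud1 <- kde_ud(one, h = 5, cell_km = 0.5)
  imax <- which(ud1$z == max(ud1$z), arr.ind = TRUE)
  expect_lt(abs(ud1$x[imax[1]] - one$x), 0.5)
  expect_lt(abs(ud1$y[imax[2]] - one$y), 0.5)
  ix <- imax[1]; iy <- imax[2]
  d <- ud1$x[ix + 20] - one$x
  ratio <- ud1$z[ix + 20, iy] / ud1$z[ix, iy]
  d0 <- ud1$x[ix] - one$x
  expect_equal(ratio, exp(-(d^2 - d0^2) / (2 * 25)), tolerance = 1e-6)
  # a too-coarse grid warns
  expect_warning(kde_ud(pts, h = 2, cell_km = 5), "under-resolved")
})

test_that("contours contain their stated mass and nest across levels", {
  pts <- gauss_points(10000, sd = 50, seed = 35)
  ud <- kde_ud(pts, href_adhoc(pts))
  ct <- ud_contours(ud)
  m50 <- ct$levels[["50"]]$mass
  expect_gte(m50, 0.48); expect_lte(m50, 0.52)
  for (lv in c(95, 90, 80, 70, 60, 50))
    expect_lt(abs(ct$levels[[as.character(lv)]]$mass - lv / 100), 0.02)
  # nesting: each mask is contained in the next level up
  lvls <- c("50", "60", "70", "80", "90", "95")
  for (i in 1:5) {
    inner <- ct$levels[[lvls[i]]]$region$mask
    outer <- ct$levels[[lvls[i + 1]]]$region$mask
    expect_true(all(outer[inner]))
  }
  expect_lte(ct$levels[["50"]]$area_km2, ct$levels[["95"]]$area_km2)
  # polygons exist and are in lon/lat range
  poly <- ct$levels[["50"]]$polygons
  expect_gt(length(poly), 0)
  expect_true(all(abs(poly[[1]]$lat) <= 90))
})

test_that("contour mass error stays within 0.02 on random UDs at cell <= h/3", {
  for (seed in 36:38) {
    set.seed(seed)
    n <- sample(500:2000, 1)
    sd_ <- runif(1, 5, 80)
    pts <- gauss_points(n, sd = sd_, seed = seed)
    # mixture: shift half the points to break symmetry
    pts$x[1:(n / 2)] <- pts$x[1:(n / 2)] + runif(1, 0, 3 * sd_)
    h <- href_adhoc(pts)
    ud <- kde_ud(pts, h, cell_km = h / 3.2)
    ct <- ud_contours(ud, c(90, 50))
    expect_lt(abs(ct$levels[["50"]]$mass - 0.5), 0.02)
    expect_lt(abs(ct$levels[["90"]]$mass - 0.9), 0.02)
  }
})

test_that("the KED50 of a single-point UD is a disc of the half-mass radius", {
  one <- gauss_points(1, seed = 39)
  h <- 8
  ud <- kde_ud(one, h = h, cell_km = h / 8)
  reg <- contour_region(ud_contours(ud, 50), 50)
  r_expect <- h * sqrt(2 * log(2))
  expect_equal(reg$area_km2, pi * r_expect^2, tolerance = 0.05)
})

test_that("representativeness counts fixes inside the region", {
  reg <- make_rect_region(0, 1, 0, 1)
  # construct fixes: 500 inside the unit square, 500 well outside
  set.seed(40)
  inside_xy <- cbind(runif(500, 0.05, 0.95), runif(500, 0.05, 0.95))
  outside_xy <- cbind(runif(500, 1.5, 2.5), runif(500, 1.5, 2.5))
  ll <- unproject_laea(c(inside_xy[, 1], outside_xy[, 1]),
                       c(inside_xy[, 2], outside_xy[, 2]), 146, -33)
  fixes <- data.frame(individual_id = rep(c("a", "b"), each = 500),
                      location_long = ll[, 1], location_lat = ll[, 2])
  out <- representativeness(fixes, reg)
  expect_equal(out$pooled, 0.5)
  expect_equal(out$per_individual$fraction, c(1, 0))
  # all inside / none inside
  fa <- fixes[1:500, ]
  expect_equal(representativeness(fa, reg)$pooled, 1)
  expect_equal(representativeness(fixes[501:1000, ], reg)$pooled, 0)
})

test_that("region overlap fractions follow the geometry", {
  sq <- make_rect_region(0, 1, 0, 1)
  right <- make_rect_region(0.5, 1, 0, 1)
  far <- make_rect_region(2, 2.5, 2, 2.5)
  expect_equal(ked50_overlap(sq, sq), c(frac_a = 1, frac_b = 1))
  expect_equal(ked50_overlap(sq, far), c(frac_a = 0, frac_b = 0))
  ov <- ked50_overlap(sq, right)
  expect_equal(ov[["frac_a"]], 0.5, tolerance = 0.01)
  expect_equal(ov[["frac_b"]], 1.0, tolerance = 0.01)
  empty <- make_rect_region(5, 5, 5, 5)  # no cells
  expect_error(ked50_overlap(empty, sq), "empty region")
})

test_that("href sensitivity reports all seven variants consistently", {
  pts <- gauss_points(800, sd = 30, seed = 41)
  tab <- href_sensitivity(pts)
  expect_equal(nrow(tab), 7)
  h_global <- href_adhoc(pts)
  expect_equal(tab$h_km[tab$variant == "global"], h_global)
  expect_equal(tab$h_km[tab$variant == "global70"], 0.7 * h_global)
  expect_equal(tab$h_km[tab$variant == "global30"], 0.3 * h_global)
  # proportion of points inside the KED50 is non-decreasing in h on a
  # convex unimodal cloud (tolerance one grid-mass quantum)
  hs <- c(0.5, 1, 2, 4) * h_global
  props <- vapply(hs, function(h) {
    reg <- contour_region(ud_contours(kde_ud(pts, h), 50), 50)
    mean(point_in_region(pts$lon, pts$lat, reg))
  }, numeric(1))
  expect_true(all(diff(props) >= -0.02))
})
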