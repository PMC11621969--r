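# Kernel utilization distribution of long-distance movement lines and
# probability-contour route demarcation (the KED50 core route). Lines are
# discretised to points at fixed arc-length spacing, projected to a local
# equal-area plane in km, smoothed with an isotropic bivariate Gaussian
# kernel at the ad hoc (href) bandwidth, and the smallest super-level sets
# containing each probability mass are extracted on the grid.

#' Sample points along great-circle movement lines
#'
#' Discretises each line at fixed arc-length spacing, always including both
#' endpoints (the final point is placed at the true endpoint, so a line of
#' length L yields `floor(L/spacing) + 1` points). Zero-length lines
#' contribute a single point. Points are projected to a local Lambert
#' azimuthal equal-area frame (km) centred on their centroid.
#'
#' @param lines Line table with `lon1`, `lat1`, `lon2`, `lat2` (and
#'   optionally `individual_id`), as from [extract_long_distance()].
#' @param spacing_km Arc-length spacing (default 10 km).
#' @param center Optional projection centre `c(lon, lat)`; default the
#'   unweighted centroid of the sampled points.
#' @return Data.frame of class `flyway_points` with `x`, `y` (km), `lon`,
#'   `lat`, `individual_id`; attribute `center` holds the projection centre.
#' @export
sample_points_on_lines <- function(lines, spacing_km = 10, center = NULL) {
  if (!nrow(lines)) stop("no lines to sample")
  ids <- if ("individual_id" %in% names(lines)) lines$individual_id
         else rep("all", nrow(lines))
  pts <- vector("list", nrow(lines))
  for (i in seq_len(nrow(lines))) {
    len <- haversine_km(lines$lon1[i], lines$lat1[i], lines$lon2[i], lines$lat2[i])
    if (len <= 0) {
      ll <- cbind(lon = lines$lon1[i], lat = lines$lat1[i])
    } else {
      k <- floor(len / spacing_km)
      frac <- pmin(1, (0:k) * spacing_km / len)
      frac[length(frac)] <- 1
      ll <- gc_interpolate(lines$lon1[i], lines$lat1[i],
                           lines$lon2[i], lines$lat2[i], frac)
    }
    pts[[i]] <- data.frame(lon = ll[, 1], lat = ll[, 2],
                           individual_id = ids[i], stringsAsFactors = FALSE)
  }
  pp <- do.call(rbind, pts)
  if (is.null(center)) center <- c(mean(pp$lon), mean(pp$lat))
  xy <- project_laea(pp$lon, pp$lat, center[1], center[2])
  out <- data.frame(x = xy[, 1], y = xy[, 2], lon = pp$lon, lat = pp$lat,
                    individual_id = pp$individual_id, stringsAsFactors = FALSE)
  attr(out, "center") <- center
  class(out) <- c("flyway_points", "data.frame")
  out
}

#' Ad hoc (reference) kernel bandwidth
#'
#' The bivariate ad hoc smoothing parameter
#' `href = sqrt((var_x + var_y)/2) * n^(-1/6)` computed from the sample
#' variances of the projected coordinates.
#'
#' @param points A `flyway_points` data.frame (or anything with `x`, `y`).
#' @return Bandwidth in km.
#' @export
href_adhoc <- function(points) {
  n <- nrow(points)
  if (n < 2) stop("need >= 2 points for href")
  h <- sqrt((stats::var(points$x) + stats::var(points$y)) / 2) * n^(-1 / 6)
  if (!is.finite(h) || h <= 0) stop("degenerate point set: href is zero")
  h
}

#' Kernel utilization distribution on a grid
#'
#' Isotropic bivariate Gaussian kernel density of the projected points,
#' evaluated on a regular grid extending the point bounding box by
#' `margin` times its span on each side (at least 3 bandwidths, so kernel
#' mass is captured), and renormalised to integrate to exactly 1 over the
#' grid.
#'
#' @param points A `flyway_points` data.frame.
#' @param h Bandwidth in km (> 0), e.g. from [href_adhoc()].
#' @param margin Bounding-box extension factor (default 0.5).
#' @param cell_km Grid cell size (default `h/4`); a warning is issued if the
#'   grid is too coarse to resolve the kernel (`cell_km > h`).
#' @param max_cells Cap on cells per axis (default 600); the cell size is
#'   coarsened with a warning if exceeded.
#' @return Object of class `flyway_ud`: grid vectors `x`, `y` (cell centres,
#'   km), density matrix `z` (`length(x)` x `length(y)`), `h`, `cell`, `n`
#'   points, projection `center` (lon/lat).
#' @export
kde_ud <- function(points, h, margin = 0.5, cell_km = NULL, max_cells = 600) {
  stopifnot(h > 0)
  if (is.null(cell_km)) cell_km <- h / 4
  xr <- range(points$x); yr <- range(points$y)
  pad_x <- max(margin * diff(xr), 3 * h)
  pad_y <- max(margin * diff(yr), 3 * h)
  xr <- xr + c(-pad_x, pad_x); yr <- yr + c(-pad_y, pad_y)
  need <- max(diff(xr), diff(yr)) / cell_km
  if (need > max_cells) {
    cell_km <- max(diff(xr), diff(yr)) / max_cells
    warning(sprintf("grid capped at %d cells per axis; cell size coarsened to %.2f km",
                    max_cells, cell_km))
  }
  if (cell_km > h)
    warning("grid cell larger than bandwidth; density surface under-resolved")
  gx <- seq(xr[1] + cell_km / 2, xr[2], by = cell_km)
  gy <- seq(yr[1] + cell_km / 2, yr[2], by = cell_km)
  A <- stats::dnorm(outer(gx, points$x, "-"), sd = h)
  B <- stats::dnorm(outer(gy, points$y, "-"), sd = h)
  z <- A %*% t(B) / nrow(points)
  z <- z / (sum(z) * cell_km^2)
  structure(list(x = gx, y = gy, z = z, h = h, cell = cell_km,
                 n = nrow(points), center = attr(points, "center")),
            class = "flyway_ud")
}

#' @export
print.flyway_ud <- function(x, ...) {
  cat(sprintf("flyway_ud: %d x %d grid of %.2f km cells, h = %.2f km, n = %d points\n",
              length(x$x), length(x$y), x$cell, x$h, x$n))
  invisible(x)
}

# region = a grid mask with its projection, the unit of all membership tests
.make_region <- function(ud, mask) {
  structure(list(x = ud$x, y = ud$y, cell = ud$cell, mask = mask,
                 center = ud$center,
                 area_km2 = sum(mask) * ud$cell^2),
            class = "flyway_region")
}

#' Test membership of lon/lat points in a contour region
#'
#' Membership is evaluated on the contour's density grid (cell-centre
#' resolution): a point belongs to the region if it falls in a grid cell of
#' the super-level set.
#'
#' @param lon,lat Coordinates (degrees).
#' @param region A `flyway_region` (e.g. `contours$levels[["50"]]$region`).
#' @return Logical vector.
#' @export
point_in_region <- function(lon, lat, region) {
  xy <- project_laea(lon, lat, region$center[1], region$center[2])
  ix <- round((xy[, 1] - region$x[1]) / region$cell) + 1
  iy <- round((xy[, 2] - region$y[1]) / region$cell) + 1
  ok <- ix >= 1 & ix <= length(region$x) & iy >= 1 & iy <= length(region$y)
  out <- logical(length(lon))
  out[ok] <- region$mask[cbind(ix[ok], iy[ok])]
  out
}

#' Probability contours of a utilization distribution
#'
#' For each level L, finds the density threshold t such that the total mass
#' of grid cells with density >= t is the smallest mass >= L/100, and takes
#' the super-level set as the contour region (polygonised for output via
#' marching squares). Levels follow the conventional 95/90/80/70/60/50 set;
#' the 50% contour (KED50) is the core-use route.
#'
#' @param ud A `flyway_ud`.
#' @param levels Percent levels (default `c(95, 90, 80, 70, 60, 50)`).
#' @return Object of class `flyway_contours`: list `levels` keyed by level
#'   with `level`, `threshold`, `mass` (contained probability), `area_km2`,
#'   `region` (a `flyway_region`) and `polygons` (list of lon/lat rings).
#' @export
ud_contours <- function(ud, levels = c(95, 90, 80, 70, 60, 50)) {
  cell2 <- ud$cell^2
  zv <- sort(as.vector(ud$z), decreasing = TRUE)
  cmass <- cumsum(zv) * cell2
  out <- vector("list", length(levels))
  names(out) <- as.character(levels)
  for (i in seq_along(levels)) {
    L <- levels[i] / 100
    k <- which(cmass >= L)[1]
    if (is.na(k)) k <- length(zv)  # grid holds all mass; numerically ~1
    t <- zv[k]
    mask <- ud$z >= t
    mass <- sum(ud$z[mask]) * cell2
    cl <- grDevices::contourLines(ud$x, ud$y, ud$z, levels = t)
    polys <- lapply(cl, function(p) {
      ll <- unproject_laea(p$x, p$y, ud$center[1], ud$center[2])
      data.frame(lon = ll[, 1], lat = ll[, 2])
    })
    out[[i]] <- list(level = levels[i], threshold = t, mass = mass,
                     area_km2 = sum(mask) * cell2,
                     region = .make_region(ud, mask), polygons = polys)
  }
  structure(list(levels = out, h = ud$h, center = ud$center),
            class = "flyway_contours")
}

#' Extract one contour region
#' @param contours A `flyway_contours`.
#' @param level Percent level (default 50, the core route).
#' @return A `flyway_region`.
#' @export
contour_region <- function(contours, level = 50) {
  lv <- contours$levels[[as.character(level)]]
  if (is.null(lv)) stop("level not present in contour set")
  lv$region
}

#' Representativeness of a route polygon
#'
#' The fraction of GPS fixes that fall inside a region, per individual and
#' pooled over all fixes of the species.
#'
#' @param fixes FixTable with `location_long`, `location_lat`,
#'   `individual_id`.
#' @param region A `flyway_region` (typically the KED50).
#' @return List with `per_individual` (data.frame `individual_id`, `n`,
#'   `fraction`), `mean`, `sd` (across individuals) and `pooled` (fraction
#'   over all fixes).
#' @export
representativeness <- function(fixes, region) {
  if (!nrow(fixes)) stop("no fixes")
  inside <- point_in_region(fixes$location_long, fixes$location_lat, region)
  per <- do.call(rbind, lapply(split(inside, fixes$individual_id), function(v) {
    data.frame(n = length(v), fraction = mean(v))
  }))
  per <- data.frame(individual_id = rownames(per), per,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(per_individual = per, mean = mean(per$fraction),
       sd = stats::sd(per$fraction), pooled = mean(inside))
}

#' Mutual overlap of two contour regions
#'
#' Fractions `area(A intersect B)/area(A)` and `area(A intersect B)/area(B)`,
#' evaluated by testing each region's cell centres for membership in the
#' other (regions may live on different grids/projections).
#'
#' @param region_a,region_b `flyway_region` objects.
#' @return Named numeric vector `c(frac_a, frac_b)`.
#' @export
ked50_overlap <- function(region_a, region_b) {
  frac_of <- function(a, b) {
    idx <- which(a$mask, arr.ind = TRUE)
    if (!nrow(idx)) stop("empty region: overlap fraction undefined")
    ll <- unproject_laea(a$x[idx[, 1]], a$y[idx[, 2]], a$center[1], a$center[2])
    mean(point_in_region(ll[, 1], ll[, 2], b))
  }
  c(frac_a = frac_of(region_a, region_b), frac_b = frac_of(region_b, region_a))
}

#' Sensitivity of the KED50 to the smoothing parameter
#'
#' Rebuilds the utilization distribution and KED50 under the conventional
#' set of href variants - the global ad hoc value, 70% of the minimum
#' per-individual href, the mean and median per-individual href, and 30%,
#' 50% and 70% of the global value - reporting for each the bandwidth, the
#' KED50 area and the proportion of the sampled long-distance points inside.
#'
#' @param points A `flyway_points` data.frame (with `individual_id`).
#' @param margin,cell_km Passed to [kde_ud()]; `cell_km = NULL` uses `h/4`
#'   per variant.
#' @return Data.frame with `variant`, `h_km`, `ked50_area_km2`,
#'   `prop_points_inside`.
#' @export
href_sensitivity <- function(points, margin = 0.5, cell_km = NULL) {
  h_global <- href_adhoc(points)
  per <- split(points, points$individual_id)
  h_ind <- numeric(0)
  for (nm in names(per)) {
    h_ind[nm] <- tryCatch(href_adhoc(per[[nm]]), error = function(e) {
      warning(sprintf("individual %s: degenerate point set skipped in href sensitivity", nm))
      NA_real_
    })
  }
  h_ind <- h_ind[!is.na(h_ind)]
  variants <- c(global = h_global,
                min70 = if (length(h_ind)) 0.7 * min(h_ind) else NA_real_,
                mean_indiv = if (length(h_ind)) mean(h_ind) else NA_real_,
                median_indiv = if (length(h_ind)) stats::median(h_ind) else NA_real_,
                global30 = 0.3 * h_global,
                global50 = 0.5 * h_global,
                global70 = 0.7 * h_global)
  rows <- vector("list", length(variants))
  for (i in seq_along(variants)) {
    h <- variants[i]
    if (is.na(h)) next
    ud <- kde_ud(points, h, margin = margin, cell_km = cell_km)
    reg <- contour_region(ud_contours(ud, 50), 50)
    rows[[i]] <- data.frame(variant = names(variants)[i], h_km = h,
                            ked50_area_km2 = reg$area_km2,
                            prop_points_inside = mean(point_in_region(points$lon, points$lat, reg)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Write contour polygons as GeoJSON
#'
#' Polygons are written in WGS84 lon/lat, one feature per contour level
#' (multi-ring levels become MultiPolygon-style coordinate arrays).
#'
#' @param contours A `flyway_contours`.
#' @param path Output path (.geojson).
#' @return `path`, invisibly.
#' @export
write_contours_geojson <- function(contours, path) {
  features <- lapply(contours$levels, function(lv) {
    rings <- lapply(lv$polygons, function(p) {
      coords <- cbind(p$lon, p$lat)
      if (nrow(coords) && any(coords[1, ] != coords[nrow(coords), ]))
        coords <- rbind(coords, coords[1, ])
      list(lapply(seq_len(nrow(coords)), function(i) c(coords[i, 1], coords[i, 2])))
    })
    list(type = "Feature",
         properties = list(level = lv$level, area_km2 = lv$area_km2,
                           mass = lv$mass),
         geometry = list(type = "MultiPolygon", coordinates = rings))
  })
  gj <- list(type = "FeatureCollection", features = unname(features))
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 8), path)
  invisible(path)
}
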