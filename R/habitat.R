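# Habitat and climate characterisation: compare the distribution of a
# raster covariate inside the core route (KED50) against the background of
# the species' whole movement range (bounding box), with chi-square
# goodness-of-fit tests, over/under-representation flags and breeding-site
# intersection.

#' Bounding box of a movement dataset
#'
#' Axis-aligned lon/lat rectangle around a line table (`lon1`/`lat1`/
#' `lon2`/`lat2`), FixTable (`location_long`/`location_lat`) or plain
#' `lon`/`lat` columns, optionally padded.
#'
#' @param x Lines, fixes or points data.frame.
#' @param margin_deg Padding added to every side (degrees, default 0).
#' @return Object of class `flyway_bbox`: list `xmin`, `xmax`, `ymin`,
#'   `ymax`. A degenerate (zero-area) box without margin is an error.
#' @export
movement_bbox <- function(x, margin_deg = 0) {
  if (all(c("lon1", "lat1", "lon2", "lat2") %in% names(x))) {
    lon <- c(x$lon1, x$lon2); lat <- c(x$lat1, x$lat2)
  } else if (all(c("location_long", "location_lat") %in% names(x))) {
    lon <- x$location_long; lat <- x$location_lat
  } else if (all(c("lon", "lat") %in% names(x))) {
    lon <- x$lon; lat <- x$lat
  } else stop("cannot find coordinate columns")
  if (!length(lon)) stop("no coordinates")
  bb <- list(xmin = min(lon) - margin_deg, xmax = max(lon) + margin_deg,
             ymin = min(lat) - margin_deg, ymax = max(lat) + margin_deg)
  if (bb$xmin >= bb$xmax || bb$ymin >= bb$ymax)
    stop("degenerate bounding box; supply margin_deg > 0")
  structure(bb, class = "flyway_bbox")
}

.region_membership <- function(lon, lat, region) {
  if (inherits(region, "flyway_bbox")) {
    lon >= region$xmin & lon <= region$xmax & lat >= region$ymin & lat <= region$ymax
  } else if (inherits(region, "flyway_region")) {
    point_in_region(lon, lat, region)
  } else stop("region must be a flyway_bbox or flyway_region")
}

#' Quantile bin edges for a continuous raster
#'
#' Inner bin edges at the `1/n .. (n-1)/n` quantiles of the raster values
#' inside a reference region: the movement bounding box (elevation-style
#' binning) or the full raster extent (rainfall-style binning). Tied edges
#' are collapsed with a warning; fewer distinct values than bins is an
#' error.
#'
#' @param raster A `flyway_raster`.
#' @param n_bins Number of bins (default 9).
#' @param reference `"bbox"` or `"raster"`.
#' @param bbox `flyway_bbox`, required when `reference = "bbox"`.
#' @return Sorted numeric vector of `n_bins - 1` (or fewer, after collapse)
#'   inner edges.
#' @export
quantile_bin_edges <- function(raster, n_bins = 9,
                               reference = c("bbox", "raster"), bbox = NULL) {
  reference <- match.arg(reference)
  cells <- raster_cells(raster)
  v <- cells$value
  if (reference == "bbox") {
    if (is.null(bbox)) stop("reference = 'bbox' requires a bbox")
    v <- v[.region_membership(cells$lon, cells$lat, bbox)]
  }
  v <- v[!is.na(v)]
  if (!length(v)) stop("reference region contains no valid raster cells")
  if (length(unique(v)) < n_bins)
    stop("fewer distinct raster values than requested bins")
  edges <- stats::quantile(v, probs = seq_len(n_bins - 1) / n_bins, names = FALSE)
  ue <- unique(edges)
  if (length(ue) < length(edges))
    warning("tied quantile edges collapsed; fewer bins than requested")
  ue
}

#' Tabulate raster values within a region
#'
#' Counts valid raster cells (cell-centre membership test) per class of a
#' categorical raster or per bin of a continuous one, with proportions
#' normalised over the valid cells in the region.
#'
#' @param raster A `flyway_raster`.
#' @param region A `flyway_bbox` or `flyway_region` (e.g. the KED50).
#' @param edges Inner bin edges for a continuous raster (e.g. from
#'   [quantile_bin_edges()]); `NULL` treats the raster as categorical.
#' @param classes Class values for a categorical raster (default: all
#'   distinct valid values in the whole raster, sorted).
#' @return Data.frame with `bin` (label), `count`, `prop`.
#' @export
tabulate_region <- function(raster, region, edges = NULL, classes = NULL) {
  cells <- raster_cells(raster)
  inside <- .region_membership(cells$lon, cells$lat, region)
  v <- cells$value[inside]
  v <- v[!is.na(v)]
  if (!length(v)) stop("region contains no valid raster cells")
  if (is.null(edges)) {
    if (is.null(classes)) classes <- sort(unique(cells$value[!is.na(cells$value)]))
    cnt <- as.integer(table(factor(v, levels = classes)))
    lab <- as.character(classes)
  } else {
    edges <- sort(edges)
    bins <- findInterval(v, edges) + 1L
    nb <- length(edges) + 1L
    cnt <- as.integer(table(factor(bins, levels = seq_len(nb))))
    full <- c(-Inf, edges, Inf)
    lab <- sprintf("(%s, %s]", format(full[-length(full)], digits = 6, trim = TRUE),
                   format(full[-1], digits = 6, trim = TRUE))
  }
  data.frame(bin = lab, count = cnt, prop = cnt / sum(cnt),
             stringsAsFactors = FALSE)
}

#' Pearson chi-square goodness-of-fit test
#'
#' `X^2 = sum (O_i - E_i)^2 / E_i` with `E_i = p_i * sum(O)`, `df = n - 1`,
#' upper-tail p-value. A bin with expected proportion 0 but a nonzero
#' observed count makes the statistic `+Inf` (with a warning) rather than
#' erroring; empty-expected, empty-observed bins contribute 0.
#'
#' @param observed Non-negative counts per bin.
#' @param expected_prop Expected proportions per bin (sum to 1; aligned
#'   with `observed`).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chisq_gof <- function(observed, expected_prop) {
  if (length(observed) != length(expected_prop))
    stop("observed and expected bins are misaligned")
  if (sum(observed) <= 0) stop("no observations")
  if (abs(sum(expected_prop) - 1) > 1e-6)
    stop("expected proportions must sum to 1")
  N <- sum(observed)
  E <- expected_prop * N
  bad <- E == 0 & observed > 0
  if (any(bad)) {
    warning("observed counts in zero-expected bins; statistic is infinite")
    stat <- Inf
  } else {
    keep <- E > 0
    stat <- sum((observed[keep] - E[keep])^2 / E[keep])
  }
  df <- length(observed) - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Over/under-representation flags
#'
#' Flags each bin `"over"` when the used proportion is at least
#' `(1 + threshold)` times the background proportion, `"under"` when at most
#' `(1 - threshold)` times it, else `"neutral"`. The 20% default quantifies
#' "substantial" representation differences and is configurable. A bin
#' absent from the background but used is flagged `"over"` with a warning.
#'
#' @param prop_inside,prop_bbox Aligned proportions (used vs background).
#' @param threshold Relative difference threshold (default 0.2).
#' @return Character vector of flags.
#' @export
representation_flags <- function(prop_inside, prop_bbox, threshold = 0.2) {
  if (length(prop_inside) != length(prop_bbox)) stop("misaligned proportions")
  flag <- rep("neutral", length(prop_inside))
  zero_bg <- prop_bbox == 0
  if (any(zero_bg & prop_inside > 0)) {
    warning("bins used but absent from the background; flagged 'over'")
    flag[zero_bg & prop_inside > 0] <- "over"
  }
  nb <- !zero_bg
  flag[nb & prop_inside >= (1 + threshold) * prop_bbox] <- "over"
  flag[nb & prop_inside <= (1 - threshold) * prop_bbox] <- "under"
  flag
}

#' Use-versus-availability comparison of a covariate
#'
#' Tabulates a raster inside the used region (KED50) and inside the
#' background bounding box, aligns the bins, flags representation, and runs
#' the chi-square goodness of fit of the used counts against the background
#' proportions.
#'
#' @param raster A `flyway_raster`.
#' @param used A `flyway_region` (the KED50).
#' @param bbox A `flyway_bbox` (the whole movement range).
#' @param kind `"categorical"` (e.g. a 0-9 flatness index) or `"quantile"`
#'   (continuous, quantile-binned).
#' @param n_bins Bins for `kind = "quantile"` (default 9).
#' @param reference Quantile reference region, `"bbox"` (elevation-style)
#'   or `"raster"` (rainfall-style deciles over the whole layer).
#' @param flag_threshold Passed to [representation_flags()].
#' @param classes Optional explicit class values for categorical rasters.
#' @return List of class `flyway_covariate_comparison` with `table` (per
#'   bin: `bin`, `count_inside`, `prop_inside`, `count_bbox`, `prop_bbox`,
#'   `flag`) and `chisq` (`statistic`, `df`, `p_value`).
#' @export
compare_covariate <- function(raster, used, bbox,
                              kind = c("categorical", "quantile"),
                              n_bins = 9, reference = c("bbox", "raster"),
                              flag_threshold = 0.2, classes = NULL) {
  kind <- match.arg(kind); reference <- match.arg(reference)
  edges <- NULL
  if (kind == "quantile") {
    edges <- quantile_bin_edges(raster, n_bins = n_bins, reference = reference,
                                bbox = bbox)
  } else if (is.null(classes)) {
    cells <- raster_cells(raster)
    classes <- sort(unique(cells$value[!is.na(cells$value)]))
  }
  tin <- tabulate_region(raster, used, edges = edges, classes = classes)
  tbb <- tabulate_region(raster, bbox, edges = edges, classes = classes)
  stopifnot(identical(tin$bin, tbb$bin))
  tab <- data.frame(bin = tin$bin,
                    count_inside = tin$count, prop_inside = tin$prop,
                    count_bbox = tbb$count, prop_bbox = tbb$prop,
                    stringsAsFactors = FALSE)
  tab$flag <- representation_flags(tab$prop_inside, tab$prop_bbox,
                                   threshold = flag_threshold)
  structure(list(table = tab,
                 chisq = chisq_gof(tab$count_inside, tab$prop_bbox)),
            class = "flyway_covariate_comparison")
}

#' @export
print.flyway_covariate_comparison <- function(x, ...) {
  tab <- x$table
  tab$prop_inside <- round(tab$prop_inside, 3)
  tab$prop_bbox <- round(tab$prop_bbox, 3)
  print(tab, row.names = FALSE)
  p <- x$chisq$p_value
  cat(sprintf("chi-square GOF: stat. = %.4g, df = %d, p-value %s\n",
              x$chisq$statistic, x$chisq$df,
              if (is.finite(p) && p < 2.2e-16) "< 2.2e-16" else sprintf("= %.4g", p)))
  invisible(x)
}

#' Breeding sites intersecting a route
#'
#' Sites whose (optionally buffered) location intersects the region, in
#' input order. With a buffer, a site is included when it lies within
#' `buffer_km` (great-circle) of any cell of the region.
#'
#' @param region A `flyway_region`.
#' @param sites Data.frame with `name`, `lon`, `lat`.
#' @param buffer_km Buffer radius (default 0).
#' @return Subset of `sites`.
#' @export
intersect_sites <- function(region, sites, buffer_km = 0) {
  if (!nrow(sites)) return(sites)
  inside <- point_in_region(sites$lon, sites$lat, region)
  if (buffer_km > 0 && any(!inside)) {
    idx <- which(region$mask, arr.ind = TRUE)
    ll <- unproject_laea(region$x[idx[, 1]], region$y[idx[, 2]],
                         region$center[1], region$center[2])
    for (i in which(!inside)) {
      dmin <- min(haversine_km(sites$lon[i], sites$lat[i], ll[, 1], ll[, 2]))
      if (dmin <= buffer_km) inside[i] <- TRUE
    }
  }
  sites[inside, , drop = FALSE]
}
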