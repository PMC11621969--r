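# Trajectory preparation: tracking CSV ingestion, post-dispersal filtering,
# and construction of species-specific 24-hour displacement-line series.

FIX_COLUMNS <- c("individual_id", "species", "timestamp", "location_long",
                 "location_lat", "capture_site", "dispersal_date")

.local_time <- function(timestamp, tz_offset_h) timestamp + tz_offset_h * 3600
.local_date <- function(timestamp, tz_offset_h)
  as.Date(.local_time(timestamp, tz_offset_h), tz = "UTC")

#' Read a Movebank-style tracking CSV
#'
#' Parses, validates and orders a GPS fix table. Rows with unparseable
#' timestamps or out-of-range coordinates are dropped and reported (line
#' numbers in the `bad_rows` attribute); if more than `max_bad_fraction` of
#' rows are bad the read aborts. Exact duplicate rows, and repeated
#' timestamps within a bird, are removed so timestamps are strictly
#' increasing per individual.
#'
#' @param path CSV file path.
#' @param column_map Named character vector mapping the canonical column
#'   names (`individual_id`, `species`, `timestamp`, `location_long`,
#'   `location_lat`, `capture_site`, `dispersal_date`) to the file's column
#'   names. Missing optional columns (`species`, `capture_site`,
#'   `dispersal_date`) are filled with `NA`.
#' @param max_bad_fraction Abort threshold for the fraction of invalid rows
#'   (default 0.05).
#' @return FixTable data.frame sorted by (individual, timestamp), with
#'   attributes `n_dropped_duplicates` and `bad_rows`.
#' @export
read_tracking_csv <- function(path, column_map = NULL, max_bad_fraction = 0.05) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  cm <- stats::setNames(FIX_COLUMNS, FIX_COLUMNS)
  if (!is.null(column_map)) cm[names(column_map)] <- column_map
  required <- c("individual_id", "timestamp", "location_long", "location_lat")
  miss <- setdiff(cm[required], names(raw))
  if (length(miss)) stop("mapped columns absent from file: ",
                         paste(miss, collapse = ", "))
  out <- data.frame(row = seq_len(nrow(raw)), stringsAsFactors = FALSE)
  for (col in FIX_COLUMNS) {
    out[[col]] <- if (cm[[col]] %in% names(raw)) raw[[cm[[col]]]] else NA_character_
  }
  ts <- as.POSIXct(gsub("T", " ", sub("Z$", "", out$timestamp)), tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%d"))
  lon <- suppressWarnings(as.numeric(out$location_long))
  lat <- suppressWarnings(as.numeric(out$location_lat))
  bad <- is.na(ts) | is.na(lon) | is.na(lat) |
    lon < -180 | lon > 180 | lat < -90 | lat > 90 | is.na(out$individual_id)
  if (any(bad)) {
    frac <- mean(bad)
    if (frac > max_bad_fraction)
      stop(sprintf("%.1f%% of rows invalid (lines %s%s); aborting",
                   100 * frac,
                   paste(utils::head(out$row[bad] + 1, 10), collapse = ", "),
                   if (sum(bad) > 10) ", ..." else ""))
    warning(sprintf("dropped %d invalid row(s) (file lines: %s)", sum(bad),
                    paste(out$row[bad] + 1, collapse = ", ")))
  }
  fixes <- data.frame(individual_id = out$individual_id,
                      species = out$species,
                      timestamp = ts,
                      location_long = lon,
                      location_lat = lat,
                      capture_site = out$capture_site,
                      dispersal_date = out$dispersal_date,
                      stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  n0 <- nrow(fixes)
  fixes <- unique(fixes)
  fixes <- fixes[order(fixes$individual_id, fixes$timestamp), , drop = FALSE]
  dup_ts <- duplicated(fixes[c("individual_id", "timestamp")])
  fixes <- fixes[!dup_ts, , drop = FALSE]
  n_dropped <- n0 - nrow(fixes)
  if (n_dropped > 0)
    message(sprintf("read_tracking_csv: dropped %d duplicate row(s)", n_dropped))
  rownames(fixes) <- NULL
  attr(fixes, "n_dropped_duplicates") <- n_dropped
  attr(fixes, "bad_rows") <- out$row[bad]
  fixes
}

#' Write a FixTable as CSV
#'
#' Inverse of [read_tracking_csv()] for valid tables: timestamps are written
#' as ISO-8601 UTC and coordinates at full precision, so a read/write round
#' trip preserves content.
#'
#' @param fixes FixTable data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracking_csv <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out$location_long <- formatC(fixes$location_long, digits = 15, format = "g")
  out$location_lat <- formatC(fixes$location_lat, digits = 15, format = "g")
  utils::write.csv(out[FIX_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a FixTable to post-dispersal data
#'
#' Removes fixes on or before each bird's dispersal date, then removes
#' entirely any bird with data on strictly fewer than `min_days + 1`
#' distinct days afterwards (i.e. birds are kept only if more than
#' `min_days` days of post-dispersal data are available). When a bird has no
#' recorded dispersal date it is inferred as the first day whose mean daily
#' position lies more than `dispersal_radius_km` from the capture site; a
#' bird with neither a dispersal date nor locatable capture site, or that
#' never leaves the dispersal radius, is excluded with a warning.
#'
#' @param fixes FixTable.
#' @param min_days Minimum days of post-dispersal data, exclusive
#'   (default 30).
#' @param dispersal_radius_km Residency radius for dispersal-date inference
#'   (default 10 km).
#' @param capture_sites Optional data.frame (`name`, `lon`, `lat`) locating
#'   capture sites for dispersal-date inference.
#' @param tz_offset_h Local-time offset (hours) used to assign fixes to days
#'   (default 10).
#' @return Filtered FixTable.
#' @export
filter_post_dispersal <- function(fixes, min_days = 30, dispersal_radius_km = 10,
                                  capture_sites = NULL, tz_offset_h = 10) {
  keep <- vector("list", 0)
  for (id in unique(fixes$individual_id)) {
    fb <- fixes[fixes$individual_id == id, , drop = FALSE]
    ddate <- suppressWarnings(as.Date(fb$dispersal_date[!is.na(fb$dispersal_date)][1]))
    if (is.na(ddate)) {
      site <- fb$capture_site[1]
      cap <- if (!is.null(capture_sites) && !is.na(site) &&
                 site %in% capture_sites$name) {
        capture_sites[capture_sites$name == site, c("lon", "lat")]
      } else NULL
      if (is.null(cap)) {
        warning(sprintf("bird %s: no dispersal date and no capture-site coordinates; excluded", id))
        next
      }
      ld <- .local_date(fb$timestamp, tz_offset_h)
      daily <- stats::aggregate(fb[c("location_long", "location_lat")],
                                list(date = ld), mean)
      d <- haversine_km(daily$location_long, daily$location_lat,
                        cap$lon[1], cap$lat[1])
      far <- which(d > dispersal_radius_km)
      if (!length(far)) {
        warning(sprintf("bird %s: never moved > %g km from capture site; no dispersal date inferable; excluded",
                        id, dispersal_radius_km))
        next
      }
      ddate <- daily$date[far[1]]
    }
    ld <- .local_date(fb$timestamp, tz_offset_h)
    fb <- fb[ld > ddate, , drop = FALSE]
    n_days <- length(unique(.local_date(fb$timestamp, tz_offset_h)))
    if (n_days > min_days) keep[[length(keep) + 1]] <- fb
  }
  if (!length(keep)) return(fixes[0, , drop = FALSE])
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

#' Build daily displacement-line series
#'
#' Reduces each bird's fixes to one anchor position per 24-hour window: the
#' fix nearest the anchor instant (local midnight for diurnal species,
#' local midday for nocturnal ones) within `tolerance_h` hours. Days with no
#' qualifying fix are retained as explicit missing records, so dates run
#' contiguously from the first to the last anchored day. The step for day D
#' is the great-circle distance from its anchor to day D+1's anchor (the
#' day's displacement line); the turning angle at day D is the signed change
#' in great-circle bearing from the previous day's line, wrapped to
#' `(-pi, pi]`.
#'
#' @param fixes FixTable (sorted or not; sorted internally).
#' @param day_anchor `"midnight"` or `"midday"`.
#' @param tz_offset_h Local-time offset from UTC in hours (default 10).
#' @param tolerance_h Half-width of the anchor matching window (default 3).
#' @return Data.frame (DailyStepSeries, class `flyway_steps`) with columns
#'   `individual_id`, `date`, `lon`, `lat`, `step_km`, `turn_rad`,
#'   `missing`. Empty input gives an empty series.
#' @export
build_daily_lines <- function(fixes, day_anchor = c("midnight", "midday"),
                              tz_offset_h = 10, tolerance_h = 3) {
  day_anchor <- match.arg(day_anchor)
  empty <- data.frame(individual_id = character(), date = as.Date(character()),
                      lon = numeric(), lat = numeric(), step_km = numeric(),
                      turn_rad = numeric(), missing = logical(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("flyway_steps", "data.frame")
  if (!nrow(fixes)) return(empty)
  anchor_frac <- if (day_anchor == "midnight") 0 else 0.5
  out <- vector("list", 0)
  for (id in unique(fixes$individual_id)) {
    fb <- fixes[fixes$individual_id == id, , drop = FALSE]
    fb <- fb[order(fb$timestamp), , drop = FALSE]
    lt <- as.numeric(.local_time(fb$timestamp, tz_offset_h))
    ld_range <- range(.local_date(fb$timestamp, tz_offset_h))
    dates <- seq(ld_range[1], ld_range[2], by = "day")
    instants <- as.numeric(as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")) +
      anchor_frac * 86400
    # nearest fix to each anchor instant
    idx <- findInterval(instants, lt)
    cand_lo <- pmax(idx, 1); cand_hi <- pmin(idx + 1, length(lt))
    d_lo <- abs(lt[cand_lo] - instants)
    d_hi <- abs(lt[cand_hi] - instants)
    pick <- ifelse(d_hi < d_lo, cand_hi, cand_lo)
    dist <- pmin(d_lo, d_hi)
    ok <- idx >= 0 & dist <= tolerance_h * 3600
    lon <- ifelse(ok, fb$location_long[pick], NA_real_)
    lat <- ifelse(ok, fb$location_lat[pick], NA_real_)
    nd <- length(dates)
    step <- rep(NA_real_, nd); brg <- rep(NA_real_, nd)
    if (nd >= 2) {
      i <- seq_len(nd - 1)
      both <- ok[i] & ok[i + 1]
      step[i][both] <- haversine_km(lon[i][both], lat[i][both],
                                    lon[i + 1][both], lat[i + 1][both])
      brg[i][both] <- gc_bearing(lon[i][both], lat[i][both],
                                 lon[i + 1][both], lat[i + 1][both])
    }
    turn <- rep(NA_real_, nd)
    if (nd >= 2) {
      j <- 2:nd
      has_turn <- !is.na(brg[j]) & !is.na(brg[j - 1])
      turn[j][has_turn] <- wrap_angle(brg[j][has_turn] - brg[j - 1][has_turn])
    }
    out[[length(out) + 1]] <- data.frame(
      individual_id = id, date = dates, lon = lon, lat = lat,
      step_km = step, turn_rad = turn, missing = !ok,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("flyway_steps", "data.frame")
  res
}

#' Summarise daily displacement-line series
#'
#' Pooled and per-bird summaries of the observed (non-missing) daily lines:
#' counts, mean, median and sample standard deviation (n-1 denominator) of
#' step length. These statistics feed the median + 2 SD long-distance
#' threshold.
#'
#' @param series A DailyStepSeries data.frame (possibly several birds).
#' @return List with `pooled` (one-row data.frame) and `per_bird`.
#' @export
series_summary <- function(series) {
  if (!nrow(series)) stop("empty series")
  obs <- series$step_km[!is.na(series$step_km)]
  if (!length(obs)) stop("no observed daily lines")
  if (length(obs) < 2) stop("need >= 2 observed lines for a sample SD")
  pooled <- data.frame(n_days = nrow(series),
                       n_lines = length(obs),
                       n_missing = sum(series$missing),
                       mean_km = mean(obs),
                       median_km = stats::median(obs),
                       sd_km = stats::sd(obs))
  per_bird <- do.call(rbind, lapply(split(series, series$individual_id), function(s) {
    o <- s$step_km[!is.na(s$step_km)]
    data.frame(individual_id = s$individual_id[1], n_days = nrow(s),
               n_lines = length(o), n_missing = sum(s$missing),
               mean_km = if (length(o)) mean(o) else NA_real_,
               median_km = if (length(o)) stats::median(o) else NA_real_,
               sd_km = if (length(o) >= 2) stats::sd(o) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per_bird) <- NULL
  list(pooled = pooled, per_bird = per_bird)
}
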