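# Synthetic telemetry generator. Produces daily movement tracks from a
# movement HMM (optionally corridor-oriented and wet/dry modulated),
# duty-cycled GPS fixes around them, corridor-structured environmental
# rasters and breeding-site tables, so the whole analysis pipeline can be
# exercised without external tracking data.

#' Default synthetic-world configuration
#'
#' The stated world for the synthetic fixtures: 8 birds per species tracked
#' for 7 years (2555 days) from 1 July 2016, a ~900 km SW-NE corridor,
#' hourly duty cycle with 10% daily dropout and 1 km fix scatter, flight
#' headings concentrated along the corridor axis (von Mises concentration
#' 5), a 100 km corridor buffer, and long-distance transitions suppressed by
#' a factor 0.2 in dry water years.
#'
#' @return Named list of defaults.
#' @export
sim_config <- function() {
  list(
    n_birds_per_species = 8L,
    n_days = 2555L,
    start_date = as.Date("2016-07-01"),
    corridor = default_corridor(),
    interval_min = 60,
    gap_prob = 0.1,
    jitter_km = 1,
    corridor_conc = 5,
    corridor_buffer_km = 100,
    dry_factor = 0.2,
    tz_offset_h = 10,
    year_classification = default_year_classification()
  )
}

# Scale a transition row's long-distance entry probability by `factor`,
# renormalising the remaining entries proportionally.
.suppress_long_entry <- function(Gamma, long, factor) {
  G <- Gamma
  for (i in seq_len(nrow(G))) {
    old <- G[i, long]
    if (old <= 0 || old >= 1) next
    G[i, long] <- old * factor
    G[i, -long] <- G[i, -long] * (1 - old * factor) / (1 - old)
  }
  G
}

#' Simulate a daily displacement track from a movement HMM
#'
#' Samples a latent state sequence from the Markov chain, step lengths from
#' each state's gamma distribution (with optional zero mass) and turning
#' angles from its von Mises distribution, and integrates daily anchor
#' positions on the sphere. When a `corridor` is supplied, the heading on
#' long-distance days is redrawn as von Mises around the local corridor
#' bearing (direction chosen towards the farther corridor end, so tracks
#' shuttle along the axis), and birds straying beyond the corridor buffer
#' head back towards the axis; short-distance days follow the plain
#' turning-angle process, so residency locales cluster near the endpoint of
#' the last flight.
#'
#' @param params A `flyway_hmm_params` object; the state with the largest
#'   step mean is the long-distance (flight) state.
#' @param n_days Number of daily displacement lines to simulate (>= 2).
#' @param corridor Optional waypoint polyline (`lon`, `lat`); `NULL` gives a
#'   pure (isotropic) realisation of the HMM.
#' @param seed Integer seed; identical seeds give identical output.
#' @param start Start position `c(lon, lat)`; default: a random point on the
#'   corridor axis, or (146, -33) without a corridor.
#' @param start_date First day (`Date`).
#' @param year_classification Optional wet/dry table as in
#'   [default_year_classification()]; in dry water years the probability of
#'   entering the long-distance state is multiplied by `dry_factor`.
#' @param dry_factor Dry-year suppression of long-distance entry (default 0.2).
#' @param corridor_conc von Mises concentration of flight headings around the
#'   corridor bearing (default 5).
#' @param corridor_buffer_km Corridor half-width (km) beyond which flights
#'   re-aim at the axis (default 100).
#' @return Data.frame of class `flyway_track` with one row per day: `date`,
#'   start anchor `lon`/`lat`, end anchor `lon_end`/`lat_end`, `step_km`,
#'   `turn_rad` (realised turning angle, `NA` on day 1), and the latent
#'   `state`.
#' @export
simulate_daily_track <- function(params, n_days, corridor = NULL, seed = NULL,
                                 start = NULL, start_date = as.Date("2016-07-01"),
                                 year_classification = NULL, dry_factor = 0.2,
                                 corridor_conc = 5, corridor_buffer_km = 100) {
  validate_hmm_params(params)
  if (n_days < 2) stop("n_days must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_states
  long <- long_distance_state(params)
  dates <- start_date + seq_len(n_days) - 1

  # per-day transition matrix: wet (or unclassified) years use Gamma as is
  dry_day <- rep(FALSE, n_days)
  if (!is.null(year_classification)) {
    wy <- assign_water_year(dates)
    cls <- year_classification$class[match(wy, year_classification$water_year)]
    dry_day <- !is.na(cls) & cls == "dry"
  }
  G_wet <- params$Gamma
  G_dry <- .suppress_long_entry(G_wet, long, dry_factor)

  states <- integer(n_days)
  states[1] <- sample.int(n, 1, prob = params$delta)
  for (t in 2:n_days) {
    G <- if (dry_day[t]) G_dry else G_wet
    states[t] <- sample.int(n, 1, prob = G[states[t - 1], ])
  }

  sr <- gamma_shape_rate(params$step_mean, params$step_sd)
  steps <- stats::rgamma(n_days, shape = sr$shape[states], rate = sr$rate[states])
  zm <- params$zero_mass[states]
  if (any(zm > 0)) steps[stats::runif(n_days) < zm] <- 0

  turns <- numeric(n_days)
  for (s in seq_len(n)) {
    idx <- which(states == s)
    if (length(idx)) turns[idx] <- rvonmises(length(idx), params$angle_mean[s],
                                             params$angle_conc[s])
  }

  if (is.null(start)) {
    start <- if (!is.null(corridor)) {
      L <- corridor_length_km(corridor)
      as.numeric(corridor_point_at(corridor, stats::runif(1, 0.1 * L, 0.9 * L)))
    } else c(146, -33)
  }

  lon <- numeric(n_days + 1); lat <- numeric(n_days + 1)
  lon[1] <- start[1]; lat[1] <- start[2]
  heading <- numeric(n_days)
  h_prev <- if (!is.null(corridor)) {
    corridor_nearest(start[1], start[2], corridor)$bearing_rad
  } else stats::runif(1, -pi, pi)
  L_tot <- if (!is.null(corridor)) corridor_length_km(corridor) else NA_real_
  for (t in seq_len(n_days)) {
    h <- if (t == 1) h_prev else heading[t - 1] + turns[t]
    if (!is.null(corridor) && states[t] == long) {
      cn <- corridor_nearest(lon[t], lat[t], corridor)
      if (cn$dist_km > corridor_buffer_km) {
        axis_pt <- corridor_point_at(corridor, cn$along_km)
        aim <- gc_bearing(lon[t], lat[t], axis_pt[1], axis_pt[2])
      } else {
        toward_end <- stats::runif(1) < (1 - cn$along_km / L_tot)
        aim <- if (toward_end) cn$bearing_rad else cn$bearing_rad + pi
      }
      h <- aim + rvonmises(1, 0, corridor_conc)
    }
    h <- wrap_angle(h)
    heading[t] <- h
    dest <- gc_destination(lon[t], lat[t], h, steps[t])
    lon[t + 1] <- dest[1]; lat[t + 1] <- dest[2]
  }

  realised_turn <- c(NA_real_, wrap_angle(diff(heading)))
  out <- data.frame(date = dates,
                    lon = lon[seq_len(n_days)], lat = lat[seq_len(n_days)],
                    lon_end = lon[-1], lat_end = lat[-1],
                    step_km = steps, turn_rad = realised_turn,
                    state = states)
  class(out) <- c("flyway_track", "data.frame")
  out
}

#' Simulate duty-cycled GPS fixes around a daily track
#'
#' Fix timestamps run at a regular interval through each local day; each
#' fix position is interpolated along the day's great-circle displacement
#' and scattered uniformly within a disc of radius `jitter_km` (so daily
#' anchors are recoverable to within the jitter radius). Whole days are
#' dropped independently with probability `gap_prob`; a final fix at the end
#' anchor of the last day closes the series.
#'
#' @param track A `flyway_track` from [simulate_daily_track()].
#' @param interval_min Fix interval in minutes (> 0).
#' @param gap_prob Daily dropout probability in `[0, 1]`.
#' @param jitter_km Radius (km) of uniform positional scatter around the
#'   interpolated path.
#' @param individual_id,species,capture_site,dispersal_date Metadata copied
#'   into every row.
#' @param tz_offset_h Local-time offset from UTC in hours (timestamps are
#'   written in UTC; local midnight is `00:00 - tz_offset_h`).
#' @param seed Optional integer seed.
#' @return Data.frame (FixTable) with columns `individual_id`, `species`,
#'   `timestamp` (POSIXct UTC), `location_long`, `location_lat`,
#'   `capture_site`, `dispersal_date`, sorted by timestamp.
#' @export
simulate_gps_fixes <- function(track, interval_min = 60, gap_prob = 0.1,
                               jitter_km = 1, individual_id = "bird_01",
                               species = "SNI", capture_site = "capture_site",
                               dispersal_date = NULL, tz_offset_h = 10,
                               seed = NULL) {
  if (!nrow(track)) stop("track is empty")
  if (interval_min <= 0) stop("interval_min must be positive")
  if (gap_prob < 0 || gap_prob > 1) stop("gap_prob must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dispersal_date)) dispersal_date <- track$date[1]

  n_days <- nrow(track)
  keep <- stats::runif(n_days + 1) >= gap_prob
  offs_min <- seq(0, max(0, 24 * 60 - interval_min), by = interval_min)
  frac <- offs_min / (24 * 60)

  rows <- vector("list", n_days + 1)
  day_start_utc <- as.POSIXct(paste(track$date, "00:00:00"), tz = "UTC") -
    tz_offset_h * 3600
  for (t in seq_len(n_days)) {
    if (!keep[t]) next
    pos <- gc_interpolate(track$lon[t], track$lat[t],
                          track$lon_end[t], track$lat_end[t], frac)
    rows[[t]] <- data.frame(timestamp = day_start_utc[t] + offs_min * 60,
                            location_long = pos[, 1], location_lat = pos[, 2])
  }
  if (keep[n_days + 1]) {
    rows[[n_days + 1]] <- data.frame(
      timestamp = day_start_utc[n_days] + 24 * 3600,
      location_long = track$lon_end[n_days], location_lat = track$lat_end[n_days])
  }
  fixes <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(fixes) || !nrow(fixes)) {
    fixes <- data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                        location_long = numeric(), location_lat = numeric())
  } else if (jitter_km > 0) {
    m <- nrow(fixes)
    r <- jitter_km * sqrt(stats::runif(m))
    theta <- stats::runif(m, -pi, pi)
    dest <- gc_destination(fixes$location_long, fixes$location_lat, theta, r)
    fixes$location_long <- dest[, "lon"]
    fixes$location_lat <- dest[, "lat"]
  }
  out <- data.frame(individual_id = rep(individual_id, nrow(fixes)),
                    species = rep(species, nrow(fixes)),
                    timestamp = fixes$timestamp,
                    location_long = fixes$location_long,
                    location_lat = fixes$location_lat,
                    capture_site = rep(capture_site, nrow(fixes)),
                    dispersal_date = rep(as.character(dispersal_date), nrow(fixes)),
                    stringsAsFactors = FALSE)
  out[order(out$timestamp), , drop = FALSE]
}

#' Simulate a multi-bird tracking dataset
#'
#' Convenience wrapper running [simulate_daily_track()] and
#' [simulate_gps_fixes()] for several birds of one species with the defaults
#' of [sim_config()]. Per-bird seeds are derived deterministically from
#' `seed`.
#'
#' @param n_birds Number of birds.
#' @param species `"SNI"` or `"RSB"` (selects the preset and the id prefix).
#' @param seed Integer seed.
#' @param config Configuration list as from [sim_config()]; individual
#'   elements can be overridden before the call.
#' @param params Optional `flyway_hmm_params` overriding the species preset.
#' @return List with `fixes` (pooled FixTable) and `tracks` (list of
#'   `flyway_track`, one per bird, latent states included).
#' @export
simulate_tracking_data <- function(n_birds = 8, species = "SNI", seed = 1,
                                   config = sim_config(), params = NULL) {
  if (is.null(params)) params <- species_preset(species)
  tracks <- vector("list", n_birds)
  fixes <- vector("list", n_birds)
  for (b in seq_len(n_birds)) {
    sb <- (seed * 1000L + b) %% .Machine$integer.max
    id <- sprintf("%s_%02d", species, b)
    tr <- simulate_daily_track(params, config$n_days, corridor = config$corridor,
                               seed = sb, start_date = config$start_date,
                               year_classification = config$year_classification,
                               dry_factor = config$dry_factor,
                               corridor_conc = config$corridor_conc,
                               corridor_buffer_km = config$corridor_buffer_km)
    tracks[[b]] <- tr
    fixes[[b]] <- simulate_gps_fixes(tr, interval_min = config$interval_min,
                                     gap_prob = config$gap_prob,
                                     jitter_km = config$jitter_km,
                                     individual_id = id, species = species,
                                     tz_offset_h = config$tz_offset_h)
  }
  names(tracks) <- sprintf("%s_%02d", species, seq_len(n_birds))
  list(fixes = do.call(rbind, fixes), tracks = tracks)
}

#' Generate a corridor-structured synthetic environment
#'
#' Builds three co-registered rasters emulating the environmental setting of
#' an inland flyway: a categorical terrain-flatness index (classes 0-9, high
#' within the corridor buffer), continuous elevation (low, < 350 m, along the
#' corridor; a high "range" band of 600-1100 m east of it), and annual
#' rainfall as a smooth west-east gradient placing the corridor in the mid
#' deciles.
#'
#' @param grid Grid spec: list with `xll`, `yll` (lower-left corner, deg),
#'   `cell` (deg), `nrow`, `ncol`. Default: corridor bounding box padded by
#'   3 degrees at 0.1 degree resolution.
#' @param corridor Waypoint polyline (`lon`, `lat`).
#' @param seed Integer seed (bit-identical rasters per seed).
#' @param buffer_km Corridor half-width (default 100 km).
#' @param range_band_km Distances east of the axis delimiting the
#'   high-elevation band (default 150-400 km).
#' @return List of class `flyway_rasterset` with `flatness`, `elevation`,
#'   `rainfall` rasters (see [flyway_raster()]) sharing one grid.
#' @export
generate_environment <- function(grid = NULL, corridor = default_corridor(),
                                 seed = 1, buffer_km = 100,
                                 range_band_km = c(150, 400)) {
  if (is.null(grid)) {
    pad <- 3
    xr <- range(corridor[, 1]) + c(-pad, pad)
    yr <- range(corridor[, 2]) + c(-pad, pad)
    cell <- 0.1
    grid <- list(xll = xr[1], yll = yr[1], cell = cell,
                 nrow = ceiling(diff(yr) / cell), ncol = ceiling(diff(xr) / cell))
  }
  set.seed(seed)
  cx <- grid$xll + (seq_len(grid$ncol) - 0.5) * grid$cell
  cy <- grid$yll + (seq_len(grid$nrow) - 0.5) * grid$cell
  lon <- rep(cx, each = grid$nrow)
  lat <- rep(cy, times = grid$ncol)
  ncell <- length(lon)

  cn <- corridor_nearest(lon, lat, corridor)
  axis_pt <- corridor_point_at(corridor, cn$along_km)
  brg <- gc_bearing(axis_pt[, 1], axis_pt[, 2], lon, lat)
  east <- sin(brg) > 0
  in_buffer <- cn$dist_km <= buffer_km
  in_range <- east & cn$dist_km >= range_band_km[1] & cn$dist_km <= range_band_km[2]

  elev <- pmax(0, 140 + 0.2 * cn$dist_km + stats::rnorm(ncell, 0, 30))
  elev[in_buffer] <- stats::runif(sum(in_buffer), 80, 300)
  elev[in_range] <- stats::runif(sum(in_range), 600, 1100)

  flat <- pmin(7, pmax(0, round(6.5 - 5 * (cn$dist_km - buffer_km) / 600 +
                                  stats::rnorm(ncell, 0, 1.2))))
  flat[in_buffer] <- sample(c(8L, 9L), sum(in_buffer), replace = TRUE,
                            prob = c(0.35, 0.65))
  flat[in_range] <- pmin(2, flat[in_range])

  lon_frac <- (lon - grid$xll) / (grid$ncol * grid$cell)
  rain <- pmax(0, 100 + 1200 * lon_frac + stats::rnorm(ncell, 0, 30))

  as_layer <- function(v) flyway_raster(matrix(v, grid$nrow, grid$ncol),
                                        xll = grid$xll, yll = grid$yll,
                                        cell = grid$cell)
  structure(list(flatness = as_layer(flat), elevation = as_layer(elev),
                 rainfall = as_layer(rain)),
            class = "flyway_rasterset")
}

#' Generate synthetic breeding-site tables
#'
#' Places `n_on_corridor` sites within the corridor buffer and `n_off` sites
#' well outside it (1.5-3 buffer widths from the axis), with unique names.
#'
#' @param n_on_corridor,n_off Site counts (>= 0).
#' @param corridor Waypoint polyline.
#' @param seed Integer seed.
#' @param buffer_km Corridor half-width (default 100 km).
#' @return Data.frame with columns `name`, `lon`, `lat`, `on_corridor`.
#' @export
generate_breeding_sites <- function(n_on_corridor, n_off,
                                    corridor = default_corridor(), seed = 1,
                                    buffer_km = 100) {
  stopifnot(n_on_corridor >= 0, n_off >= 0)
  set.seed(seed)
  L <- corridor_length_km(corridor)
  place <- function(k, dmin, dmax) {
    if (k == 0) return(NULL)
    out <- matrix(NA_real_, k, 2)
    for (i in seq_len(k)) {
      repeat {
        ax <- corridor_point_at(corridor, stats::runif(1, 0, L))
        d <- stats::runif(1, dmin, dmax)
        p <- gc_destination(ax[1], ax[2], stats::runif(1, -pi, pi), d)
        dd <- corridor_distance_km(p[1], p[2], corridor)
        if (dd >= dmin * 0.99 && dd <= dmax) { out[i, ] <- p; break }
      }
    }
    out
  }
  on_pts <- place(n_on_corridor, 0, 0.8 * buffer_km)
  off_pts <- place(n_off, 1.5 * buffer_km, 3 * buffer_km)
  pts <- rbind(on_pts, off_pts)
  if (is.null(pts)) {
    return(data.frame(name = character(), lon = numeric(), lat = numeric(),
                      on_corridor = logical(), stringsAsFactors = FALSE))
  }
  data.frame(name = sprintf("site_%02d", seq_len(nrow(pts))),
             lon = pts[, 1], lat = pts[, 2],
             on_corridor = rep(c(TRUE, FALSE), c(n_on_corridor, n_off)),
             stringsAsFactors = FALSE)
}
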