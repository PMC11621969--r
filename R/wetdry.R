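# Wet/dry water-year stratification of long-distance movements. Wet/dry
# labels are configuration input (derived externally from rainfall
# deficiency); this module assigns water years, stratifies line counts and
# rebuilds per-stratum KED50s.

.normalise_wy <- function(x) gsub("–", "-", x)

#' Assign the water year of a date
#'
#' Water years run from the first of `start_month` (default July) to the
#' end of the following June-equivalent; a date in `[1 Jul Y, 30 Jun Y+1]`
#' is labelled `"Y-Y+1"`.
#'
#' @param date `Date` (or coercible) vector.
#' @param start_month First month of the water year (default 7).
#' @return Character labels `"YYYY-YYYY"`.
#' @export
assign_water_year <- function(date, start_month = 7) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  y0 <- ifelse(m >= start_month, y, y - 1)
  sprintf("%d-%d", y0, y0 + 1)
}

#' Validate a wet/dry classification table
#'
#' @param classification Data.frame with `water_year` (`"YYYY-YYYY"`,
#'   consecutive-year pairs; en dashes accepted) and `class`
#'   (`"wet"`/`"dry"`); each label classified at most once.
#' @return The normalised classification, invisibly usable.
#' @export
validate_year_classification <- function(classification) {
  cl <- classification
  cl$water_year <- .normalise_wy(cl$water_year)
  parts <- regmatches(cl$water_year,
                      regexec("^([0-9]{4})-([0-9]{4})$", cl$water_year))
  ok <- vapply(parts, function(p) length(p) == 3 &&
                 as.integer(p[3]) == as.integer(p[2]) + 1, logical(1))
  if (!all(ok)) stop("malformed water-year labels: ",
                     paste(cl$water_year[!ok], collapse = ", "))
  if (anyDuplicated(cl$water_year))
    stop("water years classified more than once")
  if (!all(cl$class %in% c("wet", "dry")))
    stop("classes must be 'wet' or 'dry'")
  cl
}

#' Wet/dry stratified counts of long-distance lines
#'
#' Assigns each long-distance line to its water year, maps the years to
#' wet/dry classes and reports counts and percentages per class (full
#' precision retained; `percent` is also given rounded to one decimal as
#' conventionally reported).
#'
#' @param lines Long-distance line table with a `date` column.
#' @param classification Wet/dry table as in
#'   [default_year_classification()].
#' @param start_month Water-year start month (default 7).
#' @return Data.frame with `class`, `count`, `percent_exact`, `percent`
#'   (1 d.p.); attribute `total`.
#' @export
stratified_proportions <- function(lines, classification = default_year_classification(),
                                   start_month = 7) {
  if (!nrow(lines)) stop("no long-distance lines")
  classification <- validate_year_classification(classification)
  wy <- assign_water_year(lines$date, start_month)
  cls <- classification$class[match(wy, classification$water_year)]
  if (anyNA(cls))
    stop("unclassified water years: ",
         paste(sort(unique(wy[is.na(cls)])), collapse = ", "))
  total <- length(cls)
  lev <- intersect(c("wet", "dry"), unique(classification$class))
  cnt <- vapply(lev, function(k) sum(cls == k), integer(1))
  out <- data.frame(class = lev, count = as.integer(cnt),
                    percent_exact = 100 * cnt / total,
                    percent = round(100 * cnt / total, 1),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}

#' Wet/dry stratified KED50s
#'
#' Rebuilds the kernel utilization distribution and KED50 for each wet/dry
#' stratum of the long-distance lines (per-stratum ad hoc bandwidth) and
#' reports each stratum's area and overlap with the overall KED50. Strata
#' with fewer than 2 sampled points are skipped with a warning.
#'
#' @param lines Long-distance line table.
#' @param classification Wet/dry table.
#' @param spacing_km Line sampling interval (default 10 km).
#' @param margin,cell_km Passed to [kde_ud()].
#' @param start_month Water-year start month (default 7).
#' @return List with `overall` (`flyway_region`), `strata` (per class:
#'   `region`, `n_lines`, `area_km2`, `overlap_with_overall` - fraction of
#'   the stratum KED50 covered by the overall KED50 and vice versa), and
#'   `table` (summary data.frame).
#' @export
stratified_ked50 <- function(lines, classification = default_year_classification(),
                             spacing_km = 10, margin = 0.5, cell_km = NULL,
                             start_month = 7) {
  if (!nrow(lines)) stop("no long-distance lines")
  classification <- validate_year_classification(classification)
  wy <- assign_water_year(lines$date, start_month)
  cls <- classification$class[match(wy, classification$water_year)]
  if (anyNA(cls))
    stop("unclassified water years: ",
         paste(sort(unique(wy[is.na(cls)])), collapse = ", "))

  build <- function(ln) {
    pts <- sample_points_on_lines(ln, spacing_km = spacing_km)
    if (nrow(pts) < 2) return(NULL)
    ud <- kde_ud(pts, href_adhoc(pts), margin = margin, cell_km = cell_km)
    contour_region(ud_contours(ud, 50), 50)
  }
  overall <- build(lines)
  if (is.null(overall)) stop("too few sampled points for the overall KED50")

  strata <- list()
  rows <- list()
  for (k in intersect(c("wet", "dry"), unique(cls))) {
    ln <- lines[cls == k, , drop = FALSE]
    reg <- tryCatch(build(ln), error = function(e) NULL)
    if (is.null(reg)) {
      warning(sprintf("stratum '%s': too few lines for a KED50; skipped", k))
      next
    }
    ov <- ked50_overlap(reg, overall)
    strata[[k]] <- list(region = reg, n_lines = nrow(ln),
                        area_km2 = reg$area_km2, overlap_with_overall = ov)
    rows[[k]] <- data.frame(class = k, n_lines = nrow(ln),
                            area_km2 = reg$area_km2,
                            frac_stratum_in_overall = ov[["frac_a"]],
                            frac_overall_in_stratum = ov[["frac_b"]],
                            stringsAsFactors = FALSE)
  }
  list(overall = overall, strata = strata,
       table = { t <- do.call(rbind, rows); rownames(t) <- NULL; t })
}
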