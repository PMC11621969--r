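# Movement-HMM parameter container, validation and species presets.

#' Construct a movement-HMM parameter set
#'
#' An N-state hidden Markov model for daily displacement lines. Each state
#' emits a step length (km) from a gamma distribution parameterised by mean
#' and standard deviation (optionally mixed with a point mass at zero) and a
#' turning angle (radians) from a von Mises distribution.
#'
#' @param step_mean,step_sd Per-state gamma mean and SD of daily step length
#'   (km); both strictly positive.
#' @param Gamma N x N transition probability matrix (rows sum to 1). Default:
#'   sticky diagonal 0.9.
#' @param delta Initial state distribution (sums to 1). Default: stationary
#'   distribution of `Gamma`.
#' @param zero_mass Per-state probability of an exactly-zero step (default 0).
#' @param angle_mean Per-state von Mises mean turning angle, in `(-pi, pi]`
#'   (default 0: persistent heading).
#' @param angle_conc Per-state von Mises concentration `kappa >= 0`
#'   (default 1; 0 gives a uniform circular distribution).
#' @return Object of class `flyway_hmm_params`.
#' @export
hmm_params <- function(step_mean, step_sd, Gamma = NULL, delta = NULL,
                       zero_mass = NULL, angle_mean = NULL, angle_conc = NULL) {
  n <- length(step_mean)
  if (is.null(Gamma)) {
    Gamma <- matrix(if (n > 1) 0.1 / (n - 1) else 0, n, n)
    diag(Gamma) <- if (n > 1) 0.9 else 1
  }
  Gamma <- as.matrix(Gamma)
  if (is.null(delta)) delta <- stationary_distribution(Gamma)
  if (is.null(zero_mass)) zero_mass <- rep(0, n)
  if (is.null(angle_mean)) angle_mean <- rep(0, n)
  if (is.null(angle_conc)) angle_conc <- rep(1, n)
  p <- structure(list(n_states = n, delta = as.numeric(delta), Gamma = Gamma,
                      step_mean = as.numeric(step_mean),
                      step_sd = as.numeric(step_sd),
                      zero_mass = as.numeric(zero_mass),
                      angle_mean = as.numeric(angle_mean),
                      angle_conc = as.numeric(angle_conc)),
                 class = "flyway_hmm_params")
  validate_hmm_params(p)
  p
}

#' Validate a movement-HMM parameter set
#'
#' Checks stochasticity of `delta` and the rows of `Gamma` (tolerance 1e-9),
#' positivity of the gamma moments, zero-mass probabilities in `[0, 1)`, and
#' non-negative von Mises concentrations.
#'
#' @param p A `flyway_hmm_params` object.
#' @return `p`, invisibly; stops with an informative error otherwise.
#' @export
validate_hmm_params <- function(p) {
  n <- p$n_states
  lens <- vapply(p[c("step_mean", "step_sd", "zero_mass", "angle_mean", "angle_conc")],
                 length, integer(1))
  if (any(lens != n)) stop("invalid HMM parameters: state vectors must have length n_states")
  if (length(p$delta) != n || any(p$delta < 0) || abs(sum(p$delta) - 1) > 1e-9)
    stop("invalid HMM parameters: delta must be a probability vector summing to 1")
  if (!is.matrix(p$Gamma) || any(dim(p$Gamma) != n) || any(p$Gamma < 0) ||
      any(abs(rowSums(p$Gamma) - 1) > 1e-9))
    stop("invalid HMM parameters: transition matrix rows must sum to 1")
  if (any(!is.finite(p$step_mean)) || any(p$step_mean <= 0))
    stop("invalid HMM parameters: step_mean must be strictly positive")
  if (any(!is.finite(p$step_sd)) || any(p$step_sd <= 0))
    stop("invalid HMM parameters: step_sd must be strictly positive")
  if (any(p$zero_mass < 0) || any(p$zero_mass > 1))
    stop("invalid HMM parameters: zero_mass must lie in [0, 1]")
  if (any(p$angle_conc < 0))
    stop("invalid HMM parameters: angle_conc must be >= 0")
  invisible(p)
}

#' @export
print.flyway_hmm_params <- function(x, ...) {
  cat(sprintf("Movement HMM parameters: %d state(s)\n", x$n_states))
  st <- data.frame(state = seq_len(x$n_states),
                   step_mean_km = round(x$step_mean, 3),
                   step_sd_km = round(x$step_sd, 3),
                   zero_mass = round(x$zero_mass, 3),
                   angle_mean = round(x$angle_mean, 3),
                   angle_conc = round(x$angle_conc, 3))
  print(st, row.names = FALSE)
  cat("Transition matrix:\n")
  print(round(x$Gamma, 4))
  invisible(x)
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of `Gamma` for eigenvalue 1, normalised to sum to 1.
#'
#' @param Gamma Stochastic matrix.
#' @return Numeric probability vector.
#' @export
stationary_distribution <- function(Gamma) {
  Gamma <- as.matrix(Gamma)
  if (nrow(Gamma) == 1) return(1)
  e <- eigen(t(Gamma))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Index of the long-distance state
#'
#' The movement class with the largest mean step length is designated the
#' long-distance state.
#'
#' @param p A `flyway_hmm_params` object.
#' @return Integer state index.
#' @export
long_distance_state <- function(p) which.max(p$step_mean)

#' Species preset movement models
#'
#' Default generative parameter sets emulating the movement regimes of the
#' two study species: straw-necked ibis (`"SNI"`, diurnal, five states: four
#' short-distance classes with mean < 3 km and one long-distance class with
#' mean 48 km and SD 71 km) and royal spoonbill (`"RSB"`, nocturnal, six
#' states: five classes with mean < 4 km and one with mean 43 km, SD 73 km).
#' Short states are sticky; the daily probability of entering the
#' long-distance state is small, so flights punctuate multi-day residency.
#'
#' @param species `"SNI"` or `"RSB"`.
#' @return A `flyway_hmm_params` object.
#' @export
species_preset <- function(species = c("SNI", "RSB")) {
  species <- match.arg(species)
  if (species == "SNI") {
    mean_km <- c(0.3, 0.8, 1.6, 2.7, 48)
    sd_km <- c(0.3, 0.7, 1.2, 2.0, 71)
    conc <- c(0.2, 0.3, 0.5, 0.8, 5)
  } else {
    mean_km <- c(0.3, 0.7, 1.3, 2.2, 3.6, 43)
    sd_km <- c(0.3, 0.6, 1.0, 1.6, 2.6, 73)
    conc <- c(0.2, 0.3, 0.4, 0.6, 0.9, 5)
  }
  n <- length(mean_km)
  long <- n
  Gamma <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    Gamma[i, ] <- 0.11 / (n - 2)       # to the other short states
    Gamma[i, i] <- 0.85
    Gamma[i, long] <- 0.04             # daily chance of starting a flight
  }
  Gamma[long, ] <- 0.70 / (n - 1)      # flights end at a new residency locale
  Gamma[long, long] <- 0.30            # multi-day flights possible
  hmm_params(step_mean = mean_km, step_sd = sd_km, Gamma = Gamma,
             angle_mean = rep(0, n), angle_conc = conc)
}

#' Default synthetic flyway corridor
#'
#' A three-waypoint polyline running south-west to north-east across inland
#' south-eastern Australia (roughly the Murray-Darling Basin axis), about
#' 900 km long. Used as the axis along which synthetic long-distance flights
#' are oriented.
#'
#' @return Matrix of waypoints with columns `lon`, `lat`.
#' @export
default_corridor <- function() {
  cbind(lon = c(143.5, 147.0, 149.5),
        lat = c(-35.5, -32.5, -29.5))
}

#' Default wet/dry water-year classification
#'
#' The study-period classification used throughout: water years (July-June)
#' 2017-2018, 2018-2019 and 2019-2020 dry; 2016-2017, 2020-2021, 2021-2022
#' and 2022-2023 wet. Supplied as configuration - wet/dry status is an input
#' to this package, not derived from rainfall products.
#'
#' @return Data.frame with columns `water_year`, `class`.
#' @export
default_year_classification <- function() {
  data.frame(
    water_year = c("2016-2017", "2017-2018", "2018-2019", "2019-2020",
                   "2020-2021", "2021-2022", "2022-2023"),
    class = c("wet", "dry", "dry", "dry", "wet", "wet", "wet"),
    stringsAsFactors = FALSE
  )
}
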