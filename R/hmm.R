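# N-state hidden Markov model for daily displacement lines: gamma step
# lengths (mean/SD parameterisation, optional zero mass) and von Mises
# turning angles. Likelihood via the scaled forward recursion (C++),
# maximisation by quasi-Newton search on unconstrained transforms, model
# choice by AIC over a sweep of state counts, decoding by Viterbi.

#' Emission log density of one movement state
#'
#' Log density of a (step length, turning angle) observation under a single
#' state's emission model: a gamma distribution with the given mean and SD
#' (optionally mixed with a point mass at zero) times a von Mises turning
#' angle density. A missing component (`NA`) contributes 0 to the log
#' density; a zero step under zero mass `z` contributes `log(z)` (`-Inf`
#' when `z = 0`).
#'
#' @param step_km Step lengths (km, >= 0) or `NA`.
#' @param turn_rad Turning angles in `(-pi, pi]` or `NA`.
#' @param step_mean,step_sd Gamma mean and SD (km).
#' @param zero_mass Probability of a zero step (default 0).
#' @param angle_mean,angle_conc von Mises mean and concentration
#'   (defaults 0, 0: uniform angles).
#' @return Vector of log densities.
#' @export
emission_logdensity <- function(step_km, turn_rad, step_mean, step_sd,
                                zero_mass = 0, angle_mean = 0, angle_conc = 0) {
  sr <- gamma_shape_rate(step_mean, step_sd)
  n <- max(length(step_km), length(turn_rad))
  step_km <- rep_len(step_km, n); turn_rad <- rep_len(turn_rad, n)
  ld <- numeric(n)
  s_ok <- !is.na(step_km)
  zero <- s_ok & step_km == 0
  pos <- s_ok & step_km > 0
  ld[zero] <- if (zero_mass > 0) log(zero_mass) else -Inf
  ld[pos] <- log1p(-zero_mass) +
    stats::dgamma(step_km[pos], shape = sr$shape, rate = sr$rate, log = TRUE)
  a_ok <- !is.na(turn_rad)
  ld[a_ok] <- ld[a_ok] + dvonmises_log(turn_rad[a_ok], angle_mean, angle_conc)
  ld
}

# T x N matrix of per-day log emission densities; missing days give
# all-zero rows (an emission vector of ones).
.emission_matrix <- function(step, turn, params) {
  n <- params$n_states
  out <- matrix(0, length(step), n)
  for (j in seq_len(n)) {
    out[, j] <- emission_logdensity(step, turn, params$step_mean[j],
                                    params$step_sd[j], params$zero_mass[j],
                                    params$angle_mean[j], params$angle_conc[j])
  }
  out[is.na(step) & is.na(turn), ] <- 0
  out
}

.split_series <- function(series) {
  if (!"individual_id" %in% names(series))
    series$individual_id <- "bird_01"
  split(series, series$individual_id)
}

#' Forward-algorithm log likelihood
#'
#' Scaled forward recursion over each bird's contiguous daily series;
#' missing days contribute an emission vector of ones, preserving the
#' transition structure across gaps. Log likelihoods are summed over birds.
#' A series in which every day is missing contributes 0 (with a warning).
#'
#' @param series DailyStepSeries data.frame (one or more birds), or a
#'   `flyway_track` from the simulator.
#' @param params A `flyway_hmm_params` object.
#' @return Log likelihood (scalar).
#' @export
forward_loglik <- function(series, params) {
  validate_hmm_params(params)
  ll <- 0
  for (s in .split_series(series)) {
    if (all(is.na(s$step_km) & is.na(s$turn_rad))) {
      warning("series with all days missing contributes 0 to the log likelihood")
      next
    }
    ld <- .emission_matrix(s$step_km, s$turn_rad, params)
    ll <- ll + .fwd_loglik_cpp(ld, params$delta, params$Gamma)
  }
  ll
}

# ---- unconstrained working parameters --------------------------------------
# layout: log step_mean (n) | log step_sd (n) | angle pair ax, ay (2n)
#         | delta logits (n-1) | Gamma off-diagonal logits (n(n-1))
#         | zero-mass logits (n, only when estimated)

.n_free_parameters <- function(n, zero_mass_estimated) {
  (n - 1) + n * (n - 1) + 2 * n + 2 * n + if (zero_mass_estimated) n else 0
}

.pack_params <- function(p, est_zm) {
  n <- p$n_states
  ax <- p$angle_conc * cos(p$angle_mean)
  ay <- p$angle_conc * sin(p$angle_mean)
  w <- c(log(p$step_mean), log(p$step_sd), ax, ay)
  if (n > 1) {
    w <- c(w, log(p$delta[-1] / p$delta[1]))
    for (i in seq_len(n)) w <- c(w, log(p$Gamma[i, -i] / p$Gamma[i, i]))
  }
  if (est_zm) w <- c(w, stats::qlogis(pmin(pmax(p$zero_mass, 1e-8), 1 - 1e-8)))
  w
}

.unpack_params <- function(w, n, est_zm) {
  step_mean <- exp(w[1:n])
  step_sd <- exp(w[n + 1:n])
  ax <- w[2 * n + 1:n]; ay <- w[3 * n + 1:n]
  angle_mean <- atan2(ay, ax)
  angle_conc <- sqrt(ax^2 + ay^2)
  pos <- 4 * n
  if (n > 1) {
    ed <- exp(c(0, w[pos + seq_len(n - 1)]))
    delta <- ed / sum(ed)
    pos <- pos + n - 1
    Gamma <- matrix(0, n, n)
    for (i in seq_len(n)) {
      eg <- exp(w[pos + seq_len(n - 1)])
      pos <- pos + n - 1
      row <- numeric(n); row[i] <- 1; row[-i] <- eg
      Gamma[i, ] <- row / sum(row)
    }
  } else {
    delta <- 1; Gamma <- matrix(1, 1, 1)
  }
  zm <- if (est_zm) stats::plogis(w[pos + 1:n]) else rep(0, n)
  structure(list(n_states = n, delta = delta, Gamma = Gamma,
                 step_mean = step_mean, step_sd = step_sd, zero_mass = zm,
                 angle_mean = angle_mean, angle_conc = angle_conc),
            class = "flyway_hmm_params")
}

.working_bounds <- function(n, est_zm) {
  lower <- c(rep(-7, 2 * n), rep(-30, 2 * n))
  upper <- c(rep(12, 2 * n), rep(30, 2 * n))
  if (n > 1) {
    lower <- c(lower, rep(-15, (n - 1) + n * (n - 1)))
    upper <- c(upper, rep(15, (n - 1) + n * (n - 1)))
  }
  if (est_zm) { lower <- c(lower, rep(-15, n)); upper <- c(upper, rep(15, n)) }
  list(lower = lower, upper = upper)
}

# random starting parameters: step means log-uniform between the 5th and
# 95th percentiles of observed steps — stratified, one draw per equal
# log-range interval, so every restart spreads its means across the data
# range — SDs equal to means, kappa uniform in [0.5, 3], transition rows
# Dirichlet(5 on diagonal, 1 off)
.random_start <- function(obs_steps, n, est_zm, zero_frac) {
  q <- stats::quantile(obs_steps[obs_steps > 0], c(0.05, 0.95), names = FALSE)
  q[1] <- max(q[1], 1e-3)
  q[2] <- max(q[2], q[1] * 1.001)
  edges <- seq(log(q[1]), log(q[2]), length.out = n + 1)
  mean0 <- exp(stats::runif(n, edges[-(n + 1)], edges[-1]))
  rdir <- function(alpha) { g <- stats::rgamma(length(alpha), alpha); g / sum(g) }
  Gamma <- t(vapply(seq_len(n), function(i) {
    a <- rep(1, n); a[i] <- 5; rdir(a)
  }, numeric(n)))
  if (n == 1) Gamma <- matrix(1, 1, 1)
  hmm_params(step_mean = mean0, step_sd = mean0, Gamma = Gamma,
             delta = rdir(rep(2, n)),
             zero_mass = if (est_zm) rep(max(zero_frac, 1e-4), n) else rep(0, n),
             angle_mean = rep(0, n),
             angle_conc = stats::runif(n, 0.5, 3))
}

# permute states so step means are ascending
.canonical_order <- function(p) {
  perm <- order(p$step_mean)
  structure(list(n_states = p$n_states, delta = p$delta[perm],
                 Gamma = p$Gamma[perm, perm, drop = FALSE],
                 step_mean = p$step_mean[perm], step_sd = p$step_sd[perm],
                 zero_mass = p$zero_mass[perm],
                 angle_mean = p$angle_mean[perm],
                 angle_conc = p$angle_conc[perm]),
            class = "flyway_hmm_params")
}

#' Fit a movement HMM by maximum likelihood
#'
#' Maximises the forward-algorithm likelihood over all birds jointly
#' (per-bird log likelihoods summed) by quasi-Newton (L-BFGS-B) search on
#' unconstrained working parameters: log transforms for the gamma moments,
#' a `(kappa*cos(mu), kappa*sin(mu))` pair for each angle distribution, and
#' row-wise multinomial logits for the initial and transition distributions.
#' Several random restarts are run and the best retained; states are
#' relabelled in ascending step-mean order after fitting.
#'
#' @param series DailyStepSeries (one or more birds).
#' @param n_states Number of states (>= 1).
#' @param n_restarts Number of random restarts (default 6).
#' @param seed Integer seed controlling the random starts (fits are
#'   deterministic given seed and data).
#' @param estimate_zero_mass `TRUE`/`FALSE`/`NULL`; `NULL` (default)
#'   estimates per-state zero masses only if zero steps occur in the data.
#' @param maxit Iteration cap per restart (default 500).
#' @param by_bird Fit one model per bird instead of pooling; returns a named
#'   list of fits.
#' @return A `flyway_hmm_fit`: list with `params`, `log_likelihood`,
#'   `n_free_parameters`, `aic` (`= -2*loglik + 2*npar`), `convergence`,
#'   `restart` (index of the winning run), `seed`, `n_obs`.
#' @export
fit_hmm <- function(series, n_states, n_restarts = 6, seed = NULL,
                    estimate_zero_mass = NULL, maxit = 500, by_bird = FALSE) {
  if (by_bird) {
    birds <- .split_series(series)
    return(lapply(birds, fit_hmm, n_states = n_states, n_restarts = n_restarts,
                  seed = seed, estimate_zero_mass = estimate_zero_mass,
                  maxit = maxit, by_bird = FALSE))
  }
  birds <- .split_series(series)
  obs_steps <- unlist(lapply(birds, function(s) s$step_km[!is.na(s$step_km)]),
                      use.names = FALSE)
  if (length(obs_steps) < 2) stop("too few observed daily lines to fit an HMM")
  est_zm <- if (is.null(estimate_zero_mass)) any(obs_steps == 0) else estimate_zero_mass
  zero_frac <- mean(obs_steps == 0)
  npar <- .n_free_parameters(n_states, est_zm)
  if (length(obs_steps) < 10 * npar)
    warning(sprintf("only %d observed lines for %d free parameters; fit may be unstable",
                    length(obs_steps), npar))
  if (!is.null(seed)) set.seed(seed)

  # precomputed sufficient statistics for the C++ likelihood
  step <- unlist(lapply(birds, `[[`, "step_km"), use.names = FALSE)
  turn <- unlist(lapply(birds, `[[`, "turn_rad"), use.names = FALSE)
  seg_len <- vapply(birds, nrow, integer(1))
  seg_start <- as.integer(cumsum(c(0L, seg_len[-length(seg_len)])))
  step_ok <- !is.na(step); turn_ok <- !is.na(turn)
  step[!step_ok] <- 0; turn[!turn_ok] <- 0
  logstep <- ifelse(step_ok & step > 0, log(step), 0)
  costurn <- cos(turn); sinturn <- sin(turn)
  negll <- function(w) {
    p <- .unpack_params(w, n_states, est_zm)
    if (any(!is.finite(p$step_mean)) || any(p$step_sd <= 0)) return(1e10)
    v <- .negloglik_cpp(step, logstep, costurn, sinturn, step_ok, turn_ok,
                        seg_start, as.integer(seg_len), p$delta, p$Gamma,
                        p$step_mean, p$step_sd, p$zero_mass,
                        p$angle_mean, p$angle_conc)
    if (!is.finite(v)) return(1e10)
    v
  }

  b <- .working_bounds(n_states, est_zm)
  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    start <- .random_start(obs_steps, n_states, est_zm, zero_frac)
    w0 <- .pack_params(start, est_zm)
    runs[[r]] <- tryCatch(
      stats::optim(w0, negll, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(maxit = maxit,
                                  ndeps = rep(1e-6, length(w0)))),
      error = function(e) e)
  }
  ok <- !vapply(runs, inherits, logical(1), "error")
  if (!any(ok)) {
    msgs <- vapply(runs, conditionMessage, character(1))
    stop("all HMM restarts failed: ", paste(unique(msgs), collapse = "; "))
  }
  vals <- vapply(runs, function(r) if (inherits(r, "error")) Inf else r$value,
                 numeric(1))
  best <- which.min(vals)
  fit <- runs[[best]]
  params <- .canonical_order(.unpack_params(fit$par, n_states, est_zm))
  ll <- -fit$value
  structure(list(params = params, log_likelihood = ll,
                 n_free_parameters = npar, aic = -2 * ll + 2 * npar,
                 convergence = fit$convergence == 0, restart = best,
                 seed = seed, n_obs = length(obs_steps),
                 n_states = n_states),
            class = "flyway_hmm_fit")
}

#' @export
print.flyway_hmm_fit <- function(x, ...) {
  cat(sprintf("Movement HMM fit: %d states, %d observed lines\n", x$n_states, x$n_obs))
  cat(sprintf("  log-likelihood %.3f, %d free parameters, AIC %.3f%s\n",
              x$log_likelihood, x$n_free_parameters, x$aic,
              if (x$convergence) "" else " (NOT converged)"))
  print(x$params)
  invisible(x)
}

#' AIC sweep over candidate state counts
#'
#' Fits models for each state count in `n_states_range` and selects the fit
#' with the lowest AIC (ties broken towards fewer states). Fit failures for
#' individual state counts are recorded and the sweep continues; it fails
#' only if every count fails.
#'
#' @inheritParams fit_hmm
#' @param n_states_range Integer vector of candidate state counts
#'   (default `2:6`).
#' @return List with `fits` (per state count), `table` (AIC table
#'   data.frame) and `selected` (the winning `flyway_hmm_fit`).
#' @export
aic_sweep <- function(series, n_states_range = 2:6, n_restarts = 6,
                      seed = NULL, estimate_zero_mass = NULL, maxit = 500) {
  stopifnot(length(n_states_range) >= 1)
  fits <- vector("list", length(n_states_range))
  names(fits) <- as.character(n_states_range)
  for (k in seq_along(n_states_range)) {
    sk <- if (is.null(seed)) NULL else (seed + 101L * n_states_range[k]) %% .Machine$integer.max
    fits[[k]] <- tryCatch(
      fit_hmm(series, n_states_range[k], n_restarts = n_restarts, seed = sk,
              estimate_zero_mass = estimate_zero_mass, maxit = maxit),
      error = function(e) e)
  }
  failed <- vapply(fits, inherits, logical(1), "error")
  if (all(failed)) stop("all state counts failed to fit")
  tab <- data.frame(
    n_states = n_states_range,
    loglik = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$log_likelihood, numeric(1)),
    n_par = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else as.numeric(f$n_free_parameters), numeric(1)),
    aic = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$aic, numeric(1)),
    converged = vapply(fits, function(f) if (inherits(f, "error")) NA else f$convergence, logical(1)))
  sel <- which(!failed)[which.min(tab$aic[!failed])]  # min AIC; ties -> smaller N
  list(fits = fits, table = tab, selected = fits[[sel]])
}

#' Decode most-likely state sequences
#'
#' Global Viterbi decoding per bird in log space; missing days are bridged
#' by transition-only steps and carry no state in the output. Ties are
#' broken towards the lower state index.
#'
#' @param series DailyStepSeries.
#' @param params Fitted `flyway_hmm_params` (or a `flyway_hmm_fit`).
#' @return The series with a `state` column (`NA` on missing days) and
#'   attribute `long_state` (index of the largest-mean state).
#' @export
viterbi_decode <- function(series, params) {
  if (inherits(params, "flyway_hmm_fit")) params <- params$params
  validate_hmm_params(params)
  out <- series
  out$state <- NA_integer_
  for (s in .split_series(series)) {
    idx <- which(series$individual_id == s$individual_id[1])
    if (!length(idx)) idx <- seq_len(nrow(series))
    ld <- .emission_matrix(s$step_km, s$turn_rad, params)
    path <- .viterbi_cpp(ld, params$delta, params$Gamma)
    path[is.na(s$step_km) & is.na(s$turn_rad)] <- NA_integer_
    out$state[idx] <- path
  }
  attr(out, "long_state") <- long_distance_state(params)
  out
}

# long-distance line table from a decoded (or simulated) series; a line in
# a bird's final row (no following anchor record) keeps NA endpoints
.line_table <- function(series, sel) {
  n <- nrow(series)
  has_next <- c(series$individual_id[-1] == series$individual_id[-n], FALSE)
  i <- which(sel & !is.na(series$step_km))
  nxt <- ifelse(has_next[i], i + 1, NA_integer_)
  data.frame(individual_id = series$individual_id[i], date = series$date[i],
             lon1 = series$lon[i], lat1 = series$lat[i],
             lon2 = series$lon[nxt], lat2 = series$lat[nxt],
             step_km = series$step_km[i], stringsAsFactors = FALSE)
}

#' Extract long-distance movement lines
#'
#' Returns the observed daily displacement lines whose decoded state is the
#' long-distance state (the class with the largest mean step length), as
#' great-circle segments with endpoints and attributes.
#'
#' @param states A decoded series from [viterbi_decode()] (or a simulated
#'   `flyway_track` with its latent `state` column, after
#'   [track_as_series()]).
#' @param long_state Long-distance state index; defaults to the
#'   `long_state` attribute.
#' @return Data.frame with `individual_id`, `date`, `lon1`, `lat1`, `lon2`,
#'   `lat2`, `step_km`. Empty (with a warning) if no long-distance lines.
#' @export
extract_long_distance <- function(states, long_state = NULL) {
  if (is.null(long_state)) long_state <- attr(states, "long_state")
  if (is.null(long_state)) stop("long_state not supplied and not an attribute")
  out <- .line_table(states, !is.na(states$state) & states$state == long_state)
  if (!nrow(out)) warning("no long-distance lines found")
  out
}

#' Threshold classification of long-distance lines
#'
#' The comparison method to the HMM: long-distance movements are the daily
#' lines whose length strictly exceeds the pooled median step length plus
#' two sample standard deviations.
#'
#' @param series DailyStepSeries (pooled per species; >= 2 observed lines).
#' @return List with `threshold_km`, `lines` (long-distance line table) and
#'   `n_lines` (observed lines considered).
#' @export
threshold_classify <- function(series) {
  obs <- series$step_km[!is.na(series$step_km)]
  if (length(obs) < 2) stop("need >= 2 observed lines for the threshold")
  thr <- stats::median(obs) + 2 * stats::sd(obs)
  lines <- .line_table(series, !is.na(series$step_km) & series$step_km > thr)
  list(threshold_km = thr, lines = lines, n_lines = length(obs))
}

#' Convert a simulated track to a daily-step series
#'
#' Reshapes a `flyway_track` (which stores each day's start and end anchors)
#' into the DailyStepSeries layout used by the fitting and decoding
#' functions, keeping the latent `state` column for recovery tests.
#'
#' @param track A `flyway_track`.
#' @param individual_id Id to assign (default `"bird_01"`).
#' @return DailyStepSeries data.frame with a final end-anchor row.
#' @export
track_as_series <- function(track, individual_id = "bird_01") {
  n <- nrow(track)
  out <- data.frame(
    individual_id = individual_id,
    date = c(track$date, track$date[n] + 1),
    lon = c(track$lon, track$lon_end[n]),
    lat = c(track$lat, track$lat_end[n]),
    step_km = c(track$step_km, NA_real_),
    turn_rad = c(track$turn_rad, NA_real_),
    missing = FALSE,
    state = c(track$state, NA_integer_),
    stringsAsFactors = FALSE)
  class(out) <- c("flyway_steps", "data.frame")
  out
}
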