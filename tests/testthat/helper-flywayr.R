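# Shared fixtures and independent oracles for the test suite. Oracles here
# deliberately avoid the package's likelihood/decoding code paths: emission
# densities are recomputed from the closed forms and path probabilities by
# exhaustive enumeration.

# build a DailyStepSeries data.frame by hand
make_series <- function(step, turn = rep(NA_real_, length(step)),
                        id = "b01", start = as.Date("2020-01-01"),
                        lon = NULL, lat = NULL) {
  n <- length(step)
  out <- data.frame(
    individual_id = id,
    date = start + seq_len(n) - 1,
    lon = if (is.null(lon)) rep(146, n) else lon,
    lat = if (is.null(lat)) rep(-33, n) else lat,
    step_km = step, turn_rad = turn,
    missing = is.na(step) & is.na(turn),
    stringsAsFactors = FALSE)
  class(out) <- c("flyway_steps", "data.frame")
  out
}

# independent emission log density (closed forms, no package internals)
oracle_emission <- function(step, turn, mean, sd, zm, mu, kappa) {
  e <- 0
  if (!is.na(step)) {
    if (step == 0) {
      e <- e + if (zm > 0) log(zm) else -Inf
    } else {
      shape <- mean^2 / sd^2; rate <- mean / sd^2
      e <- e + log(1 - zm) + dgamma(step, shape = shape, rate = rate, log = TRUE)
    }
  }
  if (!is.na(turn)) {
    li0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
    e <- e + kappa * cos(turn - mu) - log(2 * pi) - li0
  }
  e
}

oracle_emission_matrix <- function(series, p) {
  em <- matrix(NA_real_, nrow(series), p$n_states)
  for (t in seq_len(nrow(series)))
    for (j in seq_len(p$n_states))
      em[t, j] <- oracle_emission(series$step_km[t], series$turn_rad[t],
                                  p$step_mean[j], p$step_sd[j], p$zero_mass[j],
                                  p$angle_mean[j], p$angle_conc[j])
  em
}

# exhaustive-path likelihood: logsumexp over all N^T state paths (log
# space throughout, so extreme emission densities cannot underflow)
oracle_loglik <- function(series, p) {
  em <- oracle_emission_matrix(series, p)
  T_ <- nrow(series); N <- p$n_states
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), T_)))
  lp <- numeric(nrow(paths))
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    v <- log(p$delta[s[1]]) + em[1, s[1]]
    if (T_ > 1) for (t in 2:T_) v <- v + log(p$Gamma[s[t - 1], s[t]]) + em[t, s[t]]
    lp[r] <- v
  }
  m <- max(lp)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lp - m)))
}

# exhaustive-path Viterbi: argmax joint log probability, ties to the
# lexicographically smallest path (lowest state indices first)
oracle_viterbi <- function(series, p) {
  em <- oracle_emission_matrix(series, p)
  T_ <- nrow(series); N <- p$n_states
  grid <- expand.grid(rep(list(seq_len(N)), T_))
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  paths <- as.matrix(grid)
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    lp <- log(p$delta[s[1]]) + em[1, s[1]]
    if (T_ > 1) for (t in 2:T_) lp <- lp + log(p$Gamma[s[t - 1], s[t]]) + em[t, s[t]]
    if (lp > best) { best <- lp; best_path <- s }
  }
  list(path = unname(best_path), logprob = best)
}

# joint log probability of a given state path (for Viterbi dominance checks)
oracle_path_logprob <- function(series, p, s) {
  em <- oracle_emission_matrix(series, p)
  lp <- log(p$delta[s[1]]) + em[1, s[1]]
  if (length(s) > 1)
    for (t in 2:length(s)) lp <- lp + log(p$Gamma[s[t - 1], s[t]]) + em[t, s[t]]
  lp
}

# random valid parameter set for property tests
random_params <- function(n_states, with_zero_mass = FALSE) {
  rdir <- function(a) { g <- rgamma(length(a), a); g / sum(g) }
  Gamma <- t(vapply(seq_len(n_states), function(i) rdir(rep(1, n_states)),
                    numeric(n_states)))
  if (n_states == 1) Gamma <- matrix(1, 1, 1)
  hmm_params(step_mean = runif(n_states, 0.5, 50),
             step_sd = runif(n_states, 0.5, 50),
             Gamma = Gamma, delta = rdir(rep(1, n_states)),
             zero_mass = if (with_zero_mass) runif(n_states, 0, 0.3) else rep(0, n_states),
             angle_mean = runif(n_states, -pi, pi),
             angle_conc = runif(n_states, 0, 4))
}

# random short observation series (some missing days allowed)
random_series <- function(T_, p_missing = 0.2, p_zero = 0) {
  step <- rgamma(T_, 2, 0.5)
  if (p_zero > 0) step[runif(T_) < p_zero] <- 0
  turn <- runif(T_, -pi, pi)
  turn[1] <- NA
  miss <- runif(T_) < p_missing
  step[miss] <- NA; turn[miss] <- NA
  make_series(step, turn)
}

# rectangular grid-mask region in a shared local frame, for overlap and
# membership fixtures (km coordinates; center fixes the projection)
make_rect_region <- function(xmin, xmax, ymin, ymax, cell = 0.05,
                             grid_x = c(-2, 3), grid_y = c(-2, 3),
                             center = c(146, -33)) {
  gx <- seq(grid_x[1] + cell / 2, grid_x[2], by = cell)
  gy <- seq(grid_y[1] + cell / 2, grid_y[2], by = cell)
  mask <- outer(gx > xmin & gx < xmax, gy > ymin & gy < ymax, "&")
  structure(list(x = gx, y = gy, cell = cell, mask = mask, center = center,
                 area_km2 = sum(mask) * cell^2),
            class = "flyway_region")
}
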