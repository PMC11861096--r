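# Shared fixtures and independent oracles, built in code.

const_weather <- function(n, tmax, tmin, start = as.Date("2019-01-01")) {
  tibble::tibble(date = start + seq_len(n) - 1L,
                 tmin = rep(tmin, n), tmax = rep(tmax, n))
}

random_weather <- function(n, start = as.Date("2019-01-01")) {
  tmean <- runif(n, 0, 40)
  half <- runif(n, 0.5, 8)
  tibble::tibble(date = start + seq_len(n) - 1L,
                 tmin = tmean - half, tmax = tmean + half)
}

# Brute-force day-by-day oracle: materialise every day's capped temperatures
# explicitly, independent of the package's vectorised path.
oracle_daily <- function(tmax, tmin, base, ceiling, rule) {
  if (tmax > ceiling) tmax <- ceiling
  if (rule == "cap_max_floor_min" && tmin < base) tmin <- base
  v <- (tmax + tmin) / 2 - base
  if (v < 0) v <- 0
  v
}

oracle_window <- function(weather, start, end, base, ceiling, rule) {
  days <- seq(as.Date(start), as.Date(end), by = "day")
  gdd <- 0; grow <- 0
  for (d in days) {
    i <- which(weather$date == d)
    v <- oracle_daily(weather$tmax[i], weather$tmin[i], base, ceiling, rule)
    gdd <- gdd + v
    if (v > 0) grow <- grow + 1
  }
  list(gdd = gdd, grow_days = grow)
}

# Definitional brute force for the stability coefficients.
oracle_superiority <- function(x) {
  n <- ncol(x)
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + (x[i, j] - max(x[, j]))^2
    out[i] <- acc / (2 * n)
  }
  out
}

oracle_static <- function(x) {
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    m <- mean(x[i, ])
    out[i] <- sum((x[i, ] - m)^2) / (ncol(x) - 1)
  }
  out
}

# RCBD mean squares computed from group means, independent of stats::aov.
oracle_rcbd_ms <- function(y, g, b) {
  g <- factor(g); b <- factor(b)
  ng <- nlevels(g); nb <- nlevels(b)
  gm <- mean(y)
  ms_g <- nb * sum((tapply(y, g, mean) - gm)^2) / (ng - 1)
  fit <- tapply(y, g, mean)[g] + tapply(y, b, mean)[b] - gm
  ms_e <- sum((y - fit)^2) / ((ng - 1) * (nb - 1))
  list(ms_g = ms_g, ms_e = ms_e)
}

# Small trial used by several suites: cheap but structurally complete.
small_trial <- function(seed = 1, n_g = 24, penalty = 1) {
  panel <- genotype_panel(n_genotypes = n_g, n_desi = 2,
                          origin_counts = c(Syria = n_g - 4, India = 2,
                                            Australia = 2),
                          seed = seed + 1000)
  simulate_trial(panel = panel,
                 response = response_model(yield_sdd_penalty = penalty),
                 seed = seed)
}
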