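#' Location temperature profile
#'
#' Parameterises a location's seasonal temperature regime as a sinusoidal
#' annual cycle of the daily mean plus Gaussian day-to-day noise, with a
#' fixed diurnal range: `tmax = mean + diurnal_range/2`,
#' `tmin = mean - diurnal_range/2`.
#'
#' @param name Location label.
#' @param mean_temp Annual mean of the daily mean temperature (degC).
#' @param amplitude Seasonal half-range of the daily mean (degC).
#' @param peak_doy Day of year at which the sinusoid peaks (default 15,
#'   mid-January: a southern-hemisphere summer peak).
#' @param diurnal_range tmax - tmin (degC), constant across days.
#' @param daily_noise_sd Standard deviation of daily Gaussian noise on the
#'   mean (degC).
#' @return Object of class `location_profile`.
#' @export
location_profile <- function(name, mean_temp, amplitude, peak_doy = 15,
                             diurnal_range, daily_noise_sd) {
  stopifnot(is.character(name), length(name) == 1,
            is.finite(mean_temp), is.finite(amplitude), amplitude >= 0,
            is.finite(diurnal_range), diurnal_range > 0,
            is.finite(daily_noise_sd), daily_noise_sd >= 0)
  structure(list(name = name, mean_temp = mean_temp, amplitude = amplitude,
                 peak_doy = peak_doy, diurnal_range = diurnal_range,
                 daily_noise_sd = daily_noise_sd),
            class = "location_profile")
}

#' Default pair of contrasting trial locations
#'
#' A hot, thermally stable tropical site (high mean, modest seasonality,
#' wide diurnal range) and a temperate, variable site (cool winters, strong
#' seasonality, noisier day-to-day weather). The hot site accumulates thermal
#' time several-fold faster and regularly exceeds the 30 degC growth ceiling;
#' the temperate site only does so late in its season.
#'
#' @return Named list of two [location_profile()] objects, `hot` and
#'   `temperate`.
#' @export
default_locations <- function() {
  list(
    hot = location_profile("hot", mean_temp = 27, amplitude = 6,
                           peak_doy = 15, diurnal_range = 14,
                           daily_noise_sd = 1.5),
    temperate = location_profile("temperate", mean_temp = 19, amplitude = 8,
                                 peak_doy = 15, diurnal_range = 14,
                                 daily_noise_sd = 2.5)
  )
}

#' Default sowing dates
#'
#' Two times of sowing (TOS) per location. The second sowing is delayed by
#' one month at the hot site and two months at the temperate site, pushing
#' reproduction into hotter conditions to impose heat stress.
#'
#' @return Named list of `Date` vectors of length two.
#' @export
default_tos_dates <- function() {
  list(hot = as.Date(c("2019-04-15", "2019-05-15")),
       temperate = as.Date(c("2019-06-01", "2019-08-01")))
}

#' Generate a synthetic daily weather series
#'
#' @param profile A [location_profile()].
#' @param start_date First date of the series.
#' @param n_days Number of days (>= 1).
#' @param seed Optional integer seed; if supplied the series is reproducible
#'   on its own. Leave `NULL` when the caller manages the random stream.
#' @return Tibble with columns `date`, `tmin`, `tmax`.
#' @export
generate_weather <- function(profile, start_date, n_days, seed = NULL) {
  stopifnot(inherits(profile, "location_profile"), n_days >= 1)
  if (!is.null(seed)) set.seed(seed)
  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  doy <- as.POSIXlt(dates)$yday + 1
  tmean <- profile$mean_temp +
    profile$amplitude * cos(2 * pi * (doy - profile$peak_doy) / 365) +
    stats::rnorm(n_days, 0, profile$daily_noise_sd)
  tibble::tibble(date = dates,
                 tmin = tmean - profile$diurnal_range / 2,
                 tmax = tmean + profile$diurnal_range / 2)
}

#' Generate a genotype panel
#'
#' Draws a panel of genotypes with thermal requirements (degree-days to
#' flowering and to maturity), trait potentials (plot yield and 100-seed
#' weight), and a per-genotype heat sensitivity (fractional yield loss per
#' stress degree day). Defaults mirror an elite chickpea panel: 148
#' genotypes, 10 desi / 138 kabuli, originating from Syria (129), India (10)
#' and Australia (9).
#'
#' @param n_genotypes Panel size.
#' @param n_desi Number of desi-type genotypes (the rest are kabuli).
#' @param origin_counts Named integer vector of origin counts summing to
#'   `n_genotypes`.
#' @param flowering_mean,flowering_sd Degree-day requirement to flowering.
#' @param maturity_extra_mean,maturity_extra_sd Additional degree-days from
#'   flowering to maturity.
#' @param yield_potential_mean,yield_potential_sd Unstressed plot yield (g).
#' @param hsw_potential_mean,hsw_potential_sd 100-seed weight (g).
#' @param heat_sensitivity_mean,heat_sensitivity_sd Fractional yield loss per
#'   SDD unit (truncated at 0).
#' @param seed Optional integer seed.
#' @return Tibble of class `genotype_panel` with one row per genotype.
#' @export
genotype_panel <- function(n_genotypes = 148, n_desi = 10,
                           origin_counts = c(Syria = 129, India = 10,
                                             Australia = 9),
                           flowering_mean = 400, flowering_sd = 40,
                           maturity_extra_mean = 500, maturity_extra_sd = 50,
                           yield_potential_mean = 1800,
                           yield_potential_sd = 150,
                           hsw_potential_mean = 35, hsw_potential_sd = 5,
                           heat_sensitivity_mean = 0.0012,
                           heat_sensitivity_sd = 0.0005,
                           seed = NULL) {
  stopifnot(n_genotypes >= 1, n_desi >= 0, n_desi <= n_genotypes)
  if (sum(origin_counts) != n_genotypes) {
    stop("origin_counts must sum to n_genotypes", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  flowering <- pmax(100, stats::rnorm(n_genotypes, flowering_mean,
                                      flowering_sd))
  maturity <- flowering + pmax(100, stats::rnorm(n_genotypes,
                                                 maturity_extra_mean,
                                                 maturity_extra_sd))
  out <- tibble::tibble(
    genotype_id = seq_len(n_genotypes),
    type = sample(rep(c("desi", "kabuli"), c(n_desi, n_genotypes - n_desi))),
    origin = sample(rep(names(origin_counts), origin_counts)),
    flowering_requirement = flowering,
    maturity_requirement = maturity,
    yield_potential = pmax(1, stats::rnorm(n_genotypes, yield_potential_mean,
                                           yield_potential_sd)),
    hsw_potential = pmax(1, stats::rnorm(n_genotypes, hsw_potential_mean,
                                         hsw_potential_sd)),
    heat_sensitivity = pmax(0, stats::rnorm(n_genotypes,
                                            heat_sensitivity_mean,
                                            heat_sensitivity_sd))
  )
  class(out) <- c("genotype_panel", class(out))
  out
}

#' Trait response model for the trial simulator
#'
#' Environment effects, block/residual variation, genotype-by-environment
#' (G-by-E) interaction and heat-stress penalties for the two harvest traits.
#' Genotype main effects come from the panel's trait potentials. Heat stress
#' acts multiplicatively on yield — each plot's base yield is scaled by
#' `max(0, 1 - heat_sensitivity * yield_sdd_penalty * SDD)` — and additively
#' (small) on 100-seed weight. Defaults make yield environmentally plastic
#' (large environment effects and G-by-E) and seed weight predominantly
#' genotypic.
#'
#' Environment effects are named by `"location:tos"`; unlisted environments
#' get 0.
#'
#' @param yield_env,hsw_env Named numeric vectors of environment effects
#'   (g per plot, g per 100 seeds).
#' @param yield_ge_sd,hsw_ge_sd G-by-E effect standard deviations.
#' @param yield_block_sd,hsw_block_sd Block (replicate) effect sds.
#' @param yield_resid_sd,hsw_resid_sd Plot residual sds.
#' @param yield_sdd_penalty Multiplier on each genotype's heat sensitivity
#'   (1 = sensitivities used as-is; 0 switches stress off).
#' @param hsw_sdd_penalty Grams of seed weight lost per SDD unit.
#' @return Object of class `response_model`.
#' @export
response_model <- function(yield_env = c("hot:1" = 900, "hot:2" = 750,
                                         "temperate:1" = 0,
                                         "temperate:2" = -400),
                           yield_ge_sd = 80, yield_block_sd = 40,
                           yield_resid_sd = 180, yield_sdd_penalty = 1,
                           hsw_env = c("hot:1" = 1.5, "hot:2" = 2,
                                       "temperate:1" = 0,
                                       "temperate:2" = -0.5),
                           hsw_ge_sd = 0.4, hsw_block_sd = 0.2,
                           hsw_resid_sd = 1, hsw_sdd_penalty = 0.005) {
  sds <- c(yield_ge_sd, yield_block_sd, yield_resid_sd, hsw_ge_sd,
           hsw_block_sd, hsw_resid_sd)
  stopifnot(all(is.finite(sds)), all(sds >= 0),
            yield_sdd_penalty >= 0, hsw_sdd_penalty >= 0)
  structure(list(yield_env = yield_env, yield_ge_sd = yield_ge_sd,
                 yield_block_sd = yield_block_sd,
                 yield_resid_sd = yield_resid_sd,
                 yield_sdd_penalty = yield_sdd_penalty,
                 hsw_env = hsw_env, hsw_ge_sd = hsw_ge_sd,
                 hsw_block_sd = hsw_block_sd, hsw_resid_sd = hsw_resid_sd,
                 hsw_sdd_penalty = hsw_sdd_penalty),
            class = "response_model")
}

#' Thermal-time-driven phenology
#'
#' Flowering occurs on the first date whose cumulative GDD from sowing
#' (sowing day included) reaches the genotype's flowering requirement;
#' maturity analogously. A requirement of zero flowers on the sowing date.
#'
#' @param flowering_requirement,maturity_requirement Degree-day requirements
#'   (`0 < flowering < maturity` for positive requirements).
#' @param weather Daily weather covering the season.
#' @param sowing_date Sowing date.
#' @param config A [thermal_config()].
#' @return List with `flowering_date` and `maturity_date`.
#' @export
simulate_phenology <- function(flowering_requirement, maturity_requirement,
                               weather, sowing_date,
                               config = thermal_config()) {
  stopifnot(flowering_requirement >= 0,
            maturity_requirement >= flowering_requirement)
  w <- as_weather(weather)
  sowing_date <- as.Date(sowing_date)
  eng <- thermal_engine(w, config)
  i0 <- as.integer(sowing_date - eng$origin) + 1L
  if (i0 < 1L || i0 > eng$n) {
    stop("weather series does not cover the sowing date", call. = FALSE)
  }
  base <- if (i0 > 1L) eng$cum_g[i0 - 1L] else 0
  cum <- eng$cum_g[i0:eng$n] - base
  stage_date <- function(req) {
    if (req <= 0) return(sowing_date)
    k <- findInterval(req - 1e-9, cum) + 1L
    if (k > length(cum) || cum[k] < req - 1e-9) {
      stop(sprintf("thermal requirement (%.1f degree-days) unreachable within the weather series",
                   req), call. = FALSE)
    }
    sowing_date + k - 1L
  }
  list(flowering_date = stage_date(flowering_requirement),
       maturity_date = stage_date(maturity_requirement))
}

#' Simulate a multi-environment trial
#'
#' Generates weather for each location, thermal-time-driven phenology for
#' every genotype in every environment (location x time of sowing), and
#' plot-level yield and 100-seed weight under a randomized complete block
#' design. A single random stream seeded once is consumed in a fixed,
#' documented order — weather (in location order), genotype panel (if not
#' supplied), G-by-E effects, block effects, plot residuals — so runs are
#' byte-reproducible under a fixed seed.
#'
#' Plot yield is
#' `(potential + env + gxe + block + resid) * max(0, 1 - sensitivity * penalty * SDD)`
#' floored at zero, where SDD is the plot's full-season stress degree days;
#' seed weight is the analogous additive model minus `hsw_sdd_penalty * SDD`.
#'
#' @param panel A [genotype_panel()], or `NULL` to draw the default panel
#'   from the shared stream.
#' @param locations Named list of [location_profile()]s.
#' @param tos_dates Named list (same names) of sowing-date vectors.
#' @param n_reps Replicates per environment (complete blocks).
#' @param response A [response_model()].
#' @param config A [thermal_config()].
#' @param seed Integer seed for the shared stream.
#' @param horizon_days Weather horizon generated past the first sowing.
#' @param plot_area_m2 Plot area (default 8).
#' @return Object of class `met_trial`: a list with `plots` (one row per
#'   plot), `weather` (named list of series), `panel`, and `params`.
#' @export
simulate_trial <- function(panel = NULL, locations = default_locations(),
                           tos_dates = default_tos_dates(), n_reps = 2,
                           response = response_model(),
                           config = thermal_config(), seed = 1,
                           horizon_days = 420, plot_area_m2 = 8) {
  stopifnot(inherits(response, "response_model"),
            inherits(config, "thermal_config"),
            n_reps >= 1, length(locations) >= 1,
            all(names(locations) %in% names(tos_dates)))
  set.seed(seed)
  # 1. weather, in location order
  weather <- list()
  for (loc in names(locations)) {
    tds <- as.Date(tos_dates[[loc]])
    if (!length(tds)) stop("each location needs at least one sowing date",
                           call. = FALSE)
    n_days <- horizon_days + as.integer(max(tds) - min(tds))
    weather[[loc]] <- generate_weather(locations[[loc]], min(tds), n_days)
  }
  # 2. genotype panel
  if (is.null(panel)) panel <- genotype_panel()
  stopifnot(is.data.frame(panel), nrow(panel) >= 1)
  n_g <- nrow(panel)

  envs <- do.call(rbind, lapply(names(locations), function(loc) {
    tds <- as.Date(tos_dates[[loc]])
    data.frame(location = loc, tos = seq_along(tds), sowing = tds)
  }))
  n_env <- nrow(envs)
  env_key <- paste(envs$location, envs$tos, sep = ":")

  # 3. effects, in documented order
  ge_y <- matrix(stats::rnorm(n_g * n_env, 0, response$yield_ge_sd),
                 n_g, n_env)
  ge_h <- matrix(stats::rnorm(n_g * n_env, 0, response$hsw_ge_sd),
                 n_g, n_env)
  blk_y <- matrix(stats::rnorm(n_env * n_reps, 0, response$yield_block_sd),
                  n_env, n_reps)
  blk_h <- matrix(stats::rnorm(n_env * n_reps, 0, response$hsw_block_sd),
                  n_env, n_reps)
  eps_y <- array(stats::rnorm(n_g * n_env * n_reps, 0,
                              response$yield_resid_sd),
                 c(n_g, n_env, n_reps))
  eps_h <- array(stats::rnorm(n_g * n_env * n_reps, 0,
                              response$hsw_resid_sd),
                 c(n_g, n_env, n_reps))

  env_eff <- function(tab, key) if (key %in% names(tab)) tab[[key]] else 0

  # 4. phenology and full-season SDD per genotype x environment
  flo <- mat <- matrix(as.Date(NA), n_g, n_env)
  sdd <- matrix(0, n_g, n_env)
  for (j in seq_len(n_env)) {
    loc <- envs$location[j]
    eng <- thermal_engine(as_weather(weather[[loc]]), config)
    i0 <- as.integer(envs$sowing[j] - eng$origin) + 1L
    base_g <- if (i0 > 1L) eng$cum_g[i0 - 1L] else 0
    cum <- eng$cum_g[i0:eng$n] - base_g
    kf <- findInterval(panel$flowering_requirement - 1e-9, cum) + 1L
    km <- findInterval(panel$maturity_requirement - 1e-9, cum) + 1L
    if (any(km > length(cum))) {
      stop(sprintf("maturity requirement unreachable within the %s weather horizon",
                   loc), call. = FALSE)
    }
    kf[panel$flowering_requirement <= 0] <- 1L
    flo[, j] <- envs$sowing[j] + kf - 1L
    mat[, j] <- envs$sowing[j] + km - 1L
    base_s <- if (i0 > 1L) eng$cum_s[i0 - 1L] else 0
    cum_s <- eng$cum_s[i0:eng$n] - base_s
    sdd[, j] <- (cum_s[km] - cum[km])  # SDD over [sowing, maturity]
  }

  # 5. assemble plot records
  rows <- vector("list", n_env * n_reps)
  idx <- 1L
  for (j in seq_len(n_env)) {
    ey <- env_eff(response$yield_env, env_key[j])
    eh <- env_eff(response$hsw_env, env_key[j])
    for (r in seq_len(n_reps)) {
      base_y <- panel$yield_potential + ey + ge_y[, j] + blk_y[j, r] +
        eps_y[, j, r]
      stress <- pmax(0, 1 - panel$heat_sensitivity *
                       response$yield_sdd_penalty * sdd[, j])
      base_h <- panel$hsw_potential + eh + ge_h[, j] + blk_h[j, r] +
        eps_h[, j, r] - response$hsw_sdd_penalty * sdd[, j]
      rows[[idx]] <- tibble::tibble(
        plot_id = sprintf("%s_T%d_R%d_G%03d", envs$location[j], envs$tos[j],
                          r, panel$genotype_id),
        genotype_id = panel$genotype_id,
        location = envs$location[j],
        tos = envs$tos[j],
        replicate = r,
        sowing_date = envs$sowing[j],
        flowering_date = as.Date(flo[, j], origin = "1970-01-01"),
        maturity_date = as.Date(mat[, j], origin = "1970-01-01"),
        yield_g = pmax(0, base_y * stress),
        hsw_g = pmax(0.001, base_h),
        plot_area_m2 = plot_area_m2
      )
      idx <- idx + 1L
    }
  }
  plots <- dplyr::bind_rows(rows)
  structure(list(plots = plots, weather = weather, panel = panel,
                 params = list(seed = seed, n_reps = n_reps,
                               tos_dates = tos_dates, response = response,
                               config = config,
                               horizon_days = horizon_days,
                               plot_area_m2 = plot_area_m2)),
            class = "met_trial")
}

#' @export
print.met_trial <- function(x, ...) {
  cat(sprintf(
    "<met_trial> %d plots | %d genotypes | %d environment(s) | %d rep(s) | seed %s\n",
    nrow(x$plots), nrow(x$panel),
    length(unique(paste(x$plots$location, x$plots$tos))),
    x$params$n_reps, format(x$params$seed)))
  invisible(x)
}
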