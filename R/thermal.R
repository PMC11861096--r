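#' Thermal-time configuration
#'
#' Bundles the cardinal temperatures used by the degree-day calculations:
#' the base temperature below which no growth is credited, the growth
#' ceiling above which additional heat no longer accelerates development,
#' and the stress ceiling used to isolate supra-optimal heat. Stress degree
#' days (SDD) are defined as the GDD accumulated with the stress ceiling
#' minus the GDD accumulated with the growth ceiling, so the stress ceiling
#' must sit above any temperature actually observed for SDD to capture all
#' heat above the growth ceiling.
#'
#' @param t_base Base temperature in degrees Celsius (default 10).
#' @param t_growth_ceiling Growth ceiling in degrees Celsius (default 30).
#' @param t_stress_ceiling Stress ceiling in degrees Celsius (default 50).
#' @param capping_rule How daily extremes are capped before averaging:
#'   `"cap_max_floor_min"` (default) caps tmax at the ceiling *and* floors
#'   tmin at the base; `"cap_max_only"` caps tmax only. Both clamp the
#'   resulting day at zero.
#' @return An object of class `thermal_config`.
#' @examples
#' thermal_config()
#' @export
thermal_config <- function(t_base = 10, t_growth_ceiling = 30,
                           t_stress_ceiling = 50,
                           capping_rule = c("cap_max_floor_min",
                                            "cap_max_only")) {
  capping_rule <- match.arg(capping_rule)
  if (!all(is.finite(c(t_base, t_growth_ceiling, t_stress_ceiling)))) {
    stop("thermal_config temperatures must be finite", call. = FALSE)
  }
  if (!(t_base < t_growth_ceiling && t_growth_ceiling < t_stress_ceiling)) {
    stop("thermal_config requires t_base < t_growth_ceiling < t_stress_ceiling",
         call. = FALSE)
  }
  structure(
    list(t_base = t_base,
         t_growth_ceiling = t_growth_ceiling,
         t_stress_ceiling = t_stress_ceiling,
         capping_rule = capping_rule),
    class = "thermal_config"
  )
}

#' @export
print.thermal_config <- function(x, ...) {
  cat(sprintf(
    "<thermal_config> base %g degC | growth ceiling %g degC | stress ceiling %g degC | %s\n",
    x$t_base, x$t_growth_ceiling, x$t_stress_ceiling, x$capping_rule))
  invisible(x)
}

#' Daily degree-day contribution
#'
#' One day's thermal-time credit: the capped daily mean temperature minus the
#' base, clamped at zero. Under `cap_max_floor_min` the maximum is capped at
#' the ceiling and the minimum floored at the base before averaging; under
#' `cap_max_only` only the maximum is capped.
#'
#' @param tmax,tmin Daily maximum and minimum air temperature, degrees
#'   Celsius. Vectorised.
#' @param t_base Base temperature (degrees Celsius).
#' @param t_ceiling Upper threshold applied to `tmax` (degrees Celsius).
#' @param capping_rule See [thermal_config()].
#' @return Numeric vector of degree-days (degC day), never negative.
#' @examples
#' daily_degree_days(30, 10)           # 10
#' daily_degree_days(35, 20)           # 15: tmax capped at 30
#' daily_degree_days(35, 20, t_ceiling = 50)  # 17.5
#' @export
daily_degree_days <- function(tmax, tmin, t_base = 10, t_ceiling = 30,
                              capping_rule = c("cap_max_floor_min",
                                               "cap_max_only")) {
  capping_rule <- match.arg(capping_rule)
  if (any(!is.finite(tmax)) || any(!is.finite(tmin))) {
    stop("non-finite temperature in degree-day input", call. = FALSE)
  }
  if (any(tmax < tmin)) {
    stop("tmax < tmin in degree-day input", call. = FALSE)
  }
  if (t_base >= t_ceiling) {
    stop("degree-day base must lie below the ceiling", call. = FALSE)
  }
  tmax_c <- pmin(tmax, t_ceiling)
  tmin_c <- if (capping_rule == "cap_max_floor_min") pmax(tmin, t_base) else tmin
  pmax(0, (tmax_c + tmin_c) / 2 - t_base)
}

# Validate and normalise a daily weather table: columns date/tmin/tmax,
# unique sorted dates, tmax >= tmin. Returns a tibble sorted by date.
as_weather <- function(weather) {
  if (!is.data.frame(weather)) {
    stop("weather must be a data frame with columns date, tmin, tmax",
         call. = FALSE)
  }
  need <- c("date", "tmin", "tmax")
  miss <- setdiff(need, names(weather))
  if (length(miss)) {
    stop("weather is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  w <- tibble::as_tibble(weather[need])
  w$date <- as.Date(w$date)
  if (anyNA(w$date)) stop("weather contains unparseable dates", call. = FALSE)
  if (anyDuplicated(w$date)) {
    stop("weather contains duplicate dates", call. = FALSE)
  }
  if (any(!is.finite(w$tmin)) || any(!is.finite(w$tmax))) {
    stop("weather contains non-finite temperatures", call. = FALSE)
  }
  if (any(w$tmax < w$tmin)) {
    stop("weather contains days with tmax < tmin", call. = FALSE)
  }
  w[order(w$date), ]
}

# Index a contiguous window into a weather table, erroring on the first
# missing date (gaps are never interpolated).
window_index <- function(w, start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (start_date > end_date) {
    stop("window start is after its end", call. = FALSE)
  }
  days <- seq(start_date, end_date, by = "day")
  idx <- match(days, w$date)
  if (anyNA(idx)) {
    stop(sprintf("weather series has a gap: no record for %s",
                 format(days[which(is.na(idx))[1]])), call. = FALSE)
  }
  idx
}

#' Accumulate growing degree days over a date window
#'
#' Sums [daily_degree_days()] over every calendar day in
#' `[start_date, end_date]` (both inclusive). Every day in the window must be
#' present in the weather series; gaps are an error, not interpolated.
#'
#' @param weather Data frame with columns `date`, `tmin`, `tmax`.
#' @param start_date,end_date Window bounds (inclusive); `Date` or ISO-8601
#'   strings.
#' @inheritParams daily_degree_days
#' @return Accumulated degree-days (degC day).
#' @export
accumulate_gdd <- function(weather, start_date, end_date, t_base = 10,
                           t_ceiling = 30,
                           capping_rule = c("cap_max_floor_min",
                                            "cap_max_only")) {
  capping_rule <- match.arg(capping_rule)
  w <- as_weather(weather)
  idx <- window_index(w, start_date, end_date)
  sum(daily_degree_days(w$tmax[idx], w$tmin[idx], t_base, t_ceiling,
                        capping_rule))
}

#' Accumulate stress degree days over a date window
#'
#' SDD = GDD computed with the stress ceiling minus GDD computed with the
#' growth ceiling. Day by day the stress-ceiling contribution dominates the
#' growth-ceiling one, so the result is always non-negative; it is zero
#' whenever no day in the window exceeds the growth ceiling.
#'
#' @inheritParams accumulate_gdd
#' @param config A [thermal_config()].
#' @return Accumulated stress degree-days (degC day), `>= 0`.
#' @export
compute_sdd <- function(weather, start_date, end_date,
                        config = thermal_config()) {
  stopifnot(inherits(config, "thermal_config"))
  hi <- accumulate_gdd(weather, start_date, end_date, config$t_base,
                       config$t_stress_ceiling, config$capping_rule)
  lo <- accumulate_gdd(weather, start_date, end_date, config$t_base,
                       config$t_growth_ceiling, config$capping_rule)
  hi - lo
}

#' Count days suitable for growth in a window
#'
#' A "grow day" is a day whose degree-day contribution is strictly positive,
#' i.e. whose capped mean temperature exceeds the base.
#'
#' @inheritParams accumulate_gdd
#' @return Integer count of grow days.
#' @export
count_grow_days <- function(weather, start_date, end_date, t_base = 10,
                            t_ceiling = 30,
                            capping_rule = c("cap_max_floor_min",
                                             "cap_max_only")) {
  capping_rule <- match.arg(capping_rule)
  w <- as_weather(weather)
  idx <- window_index(w, start_date, end_date)
  sum(daily_degree_days(w$tmax[idx], w$tmin[idx], t_base, t_ceiling,
                        capping_rule) > 0)
}

zero_profile <- function(stage, age_days = 0L) {
  tibble::tibble(stage = stage, age_days = as.integer(age_days),
                 grow_days = 0L, gdd = 0, sdd = 0)
}

#' Thermal profile of one plot's growth stages
#'
#' Splits a plot's season into disjoint, additive stage windows —
#' vegetative `[sowing, flowering - 1]`, reproductive `[flowering, maturity]`
#' — plus the full season `[sowing, maturity]`, and accumulates GDD, SDD and
#' grow days over each. `age_days` is the number of calendar days in the
#' window, so vegetative + reproductive = full season for every column.
#'
#' @param sowing_date,flowering_date,maturity_date Stage dates
#'   (sowing <= flowering <= maturity).
#' @param weather Daily weather covering sowing through maturity.
#' @param config A [thermal_config()].
#' @param plot_id Optional identifier used in error messages.
#' @return Tibble with one row per stage (`vegetative`, `reproductive`,
#'   `full_season`) and columns `age_days`, `grow_days`, `gdd`, `sdd`.
#' @export
stage_thermal_profile <- function(sowing_date, flowering_date, maturity_date,
                                  weather, config = thermal_config(),
                                  plot_id = NULL) {
  stopifnot(inherits(config, "thermal_config"))
  s <- as.Date(sowing_date); f <- as.Date(flowering_date)
  m <- as.Date(maturity_date)
  if (is.na(s) || is.na(f) || is.na(m) || s > f || f > m) {
    stop(sprintf("phenology dates out of order%s (need sowing <= flowering <= maturity)",
                 if (is.null(plot_id)) "" else paste0(" for plot ", plot_id)),
         call. = FALSE)
  }
  one <- function(stage, a, b, age) {
    if (a > b) return(zero_profile(stage, age))
    tibble::tibble(
      stage = stage,
      age_days = as.integer(age),
      grow_days = as.integer(count_grow_days(weather, a, b, config$t_base,
                                             config$t_growth_ceiling,
                                             config$capping_rule)),
      gdd = accumulate_gdd(weather, a, b, config$t_base,
                           config$t_growth_ceiling, config$capping_rule),
      sdd = compute_sdd(weather, a, b, config)
    )
  }
  dplyr::bind_rows(
    one("vegetative", s, f - 1, as.integer(f - s)),
    one("reproductive", f, m, as.integer(m - f) + 1L),
    one("full_season", s, m, as.integer(m - s) + 1L)
  )
}

# Precomputed per-day engine for fast window sums over a contiguous series.
thermal_engine <- function(w, config) {
  if (nrow(w) > 1 && any(diff(w$date) != 1)) {
    gap <- w$date[which(diff(w$date) != 1)[1]] + 1
    stop(sprintf("weather series has a gap: no record for %s", format(gap)),
         call. = FALSE)
  }
  dd_g <- daily_degree_days(w$tmax, w$tmin, config$t_base,
                            config$t_growth_ceiling, config$capping_rule)
  dd_s <- daily_degree_days(w$tmax, w$tmin, config$t_base,
                            config$t_stress_ceiling, config$capping_rule)
  list(origin = w$date[1], n = nrow(w),
       cum_g = cumsum(dd_g), cum_s = cumsum(dd_s), cum_n = cumsum(dd_g > 0))
}

engine_window <- function(eng, start_date, end_date) {
  i0 <- as.integer(as.Date(start_date) - eng$origin) + 1L
  i1 <- as.integer(as.Date(end_date) - eng$origin) + 1L
  if (i0 < 1L || i1 > eng$n) {
    stop(sprintf("weather series has a gap: no record for %s",
                 format(if (i0 < 1L) as.Date(start_date) else as.Date(end_date))),
         call. = FALSE)
  }
  lo_g <- if (i0 > 1L) eng$cum_g[i0 - 1L] else 0
  lo_s <- if (i0 > 1L) eng$cum_s[i0 - 1L] else 0
  lo_n <- if (i0 > 1L) eng$cum_n[i0 - 1L] else 0L
  c(gdd = eng$cum_g[i1] - lo_g,
    sdd = (eng$cum_s[i1] - lo_s) - (eng$cum_g[i1] - lo_g),
    grow_days = eng$cum_n[i1] - lo_n)
}

#' Thermal profiles for a table of plots
#'
#' Batch version of [stage_thermal_profile()]: computes the per-stage GDD,
#' SDD, grow-day and age summaries for every plot record, using the weather
#' series of the plot's location. Plots with a missing maturity date are
#' retained with `NA` reproductive and full-season profiles.
#'
#' @param plots Plot records (see [simulate_trial()] / [read_plots_csv()]).
#' @param weather A single weather data frame, or a named list of them keyed
#'   by location.
#' @param config A [thermal_config()].
#' @return Long tibble: `plot_id`, `genotype_id`, `location`, `tos`,
#'   `replicate`, `stage`, `age_days`, `grow_days`, `gdd`, `sdd`.
#' @export
thermal_profiles <- function(plots, weather, config = thermal_config()) {
  stopifnot(is.data.frame(plots), inherits(config, "thermal_config"))
  locs <- unique(plots$location)
  if (is.data.frame(weather)) {
    if (length(locs) > 1) {
      stop("plots span several locations; supply weather as a named list",
           call. = FALSE)
    }
    weather <- stats::setNames(list(weather), locs)
  }
  miss <- setdiff(locs, names(weather))
  if (length(miss)) {
    stop("no weather series for location(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- vector("list", length(locs))
  for (li in seq_along(locs)) {
    loc <- locs[li]
    eng <- thermal_engine(as_weather(weather[[loc]]), config)
    sub <- plots[plots$location == loc, ]
    n <- nrow(sub)
    s <- as.Date(sub$sowing_date); f <- as.Date(sub$flowering_date)
    m <- as.Date(sub$maturity_date)
    bad <- which(is.na(s) | is.na(f) | s > f | (!is.na(m) & f > m))
    if (length(bad)) {
      stop(sprintf("phenology dates out of order for plot %s",
                   sub$plot_id[bad[1]]), call. = FALSE)
    }
    i_s <- as.integer(s - eng$origin) + 1L
    i_f <- as.integer(f - eng$origin) + 1L
    i_m <- as.integer(m - eng$origin) + 1L
    i_end <- ifelse(is.na(i_m), i_f, i_m)
    oob <- which(i_s < 1L | i_end > eng$n)
    if (length(oob)) {
      stop(sprintf("weather series has a gap: no record for %s",
                   format(if (i_s[oob[1]] < 1L) s[oob[1]] else
                     if (is.na(m[oob[1]])) f[oob[1]] else m[oob[1]])),
           call. = FALSE)
    }
    # zero-padded cumulative sums: window [i0, i1] sums to c[i1 + 1] - c[i0]
    cg <- c(0, eng$cum_g); cs <- c(0, eng$cum_s); cn <- c(0, eng$cum_n)
    has_veg <- i_f > i_s
    gdd_v <- ifelse(has_veg, cg[i_f] - cg[i_s], 0)
    sdd_v <- ifelse(has_veg, (cs[i_f] - cs[i_s]) - gdd_v, 0)
    grw_v <- ifelse(has_veg, cn[i_f] - cn[i_s], 0)
    gdd_r <- cg[i_m + 1L] - cg[i_f]
    sdd_r <- (cs[i_m + 1L] - cs[i_f]) - gdd_r
    grw_r <- cn[i_m + 1L] - cn[i_f]
    gdd_f <- cg[i_m + 1L] - cg[i_s]
    sdd_f <- (cs[i_m + 1L] - cs[i_s]) - gdd_f
    grw_f <- cn[i_m + 1L] - cn[i_s]
    interleave <- function(a, b, c_) as.vector(rbind(a, b, c_))
    out[[li]] <- tibble::tibble(
      plot_id = rep(sub$plot_id, each = 3L),
      genotype_id = rep(sub$genotype_id, each = 3L),
      location = loc,
      tos = rep(sub$tos, each = 3L),
      replicate = rep(sub$replicate, each = 3L),
      stage = rep(c("vegetative", "reproductive", "full_season"), times = n),
      age_days = interleave(as.integer(f - s), as.integer(m - f) + 1L,
                            as.integer(m - s) + 1L),
      grow_days = interleave(grw_v, grw_r, grw_f),
      gdd = interleave(gdd_v, gdd_r, gdd_f),
      sdd = interleave(sdd_v, sdd_r, sdd_f)
    )
  }
  dplyr::bind_rows(out)
}
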