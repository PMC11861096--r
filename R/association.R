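#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranked data (ties get average ranks); the
#' p-value comes from the t approximation with `n - 2` degrees of freedom,
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. A perfect monotone pair gives
#' `rho = +/-1` and `p = 0`.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, neither constant.
#' @return List: `rho`, `p_value`, `n`, `tier` (see [significance_tier()]).
#' @export
spearman_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for a constant input vector", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = p, n = n, tier = significance_tier(p))
}

#' Significance tier of a p-value
#'
#' Tiers used in the correlation tables: `"**"`-style highly significant at
#' `p < 0.001`, significant at `p < 0.05`, otherwise not significant.
#'
#' @param p Numeric p-value(s).
#' @return Character vector with levels `"ns"`, `"p<0.05"`, `"p<0.001"`.
#' @export
significance_tier <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.001, "p<0.001", ifelse(p < 0.05, "p<0.05", "ns"))
}

#' Correlate thermal statistics with harvest traits
#'
#' For each location, growth period (vegetative, reproductive), thermal
#' statistic (GDD, SDD) and trait (yield, 100-seed weight), computes the
#' Spearman rank correlation across genotype x time-of-sowing predicted
#' means, pooling the location's sowing times. Predicted means are replicate
#' means per genotype and environment for both the thermal statistics and
#' the traits.
#'
#' @param plots Plot records.
#' @param profiles Output of [thermal_profiles()].
#' @param periods Growth periods to use.
#' @param traits Trait columns.
#' @return Tibble: location, period, thermal, trait, rho, p_value, tier, n.
#' @export
correlate_thermal_traits <- function(plots, profiles,
                                     periods = c("vegetative",
                                                 "reproductive"),
                                     traits = c("yield_g", "hsw_g")) {
  prof <- profiles[profiles$stage %in% periods, ]
  thermal_pm <- dplyr::summarise(
    dplyr::group_by(prof, .data$location, .data$tos, .data$genotype_id,
                    .data$stage),
    gdd = mean(.data$gdd), sdd = mean(.data$sdd), .groups = "drop")
  trait_pm <- dplyr::summarise(
    dplyr::group_by(plots, .data$location, .data$tos, .data$genotype_id),
    dplyr::across(dplyr::all_of(traits), mean), .groups = "drop")
  dat <- dplyr::inner_join(thermal_pm, trait_pm,
                           by = c("location", "tos", "genotype_id"))
  rows <- list()
  for (loc in unique(dat$location)) {
    for (per in periods) {
      sub <- dat[dat$location == loc & dat$stage == per, ]
      for (th in c("gdd", "sdd")) {
        for (tr in traits) {
          # a thermal statistic can be constant (e.g. SDD identically zero
          # in a mild environment); report the pair as undefined rather
          # than aborting the whole table
          if (stats::var(sub[[th]], na.rm = TRUE) == 0 ||
              stats::var(sub[[tr]], na.rm = TRUE) == 0) {
            ct <- list(rho = NA_real_, p_value = NA_real_, n = nrow(sub),
                       tier = "ns")
          } else {
            ct <- spearman_test(sub[[th]], sub[[tr]])
          }
          rows[[length(rows) + 1]] <- tibble::tibble(
            location = loc, period = per, thermal = th, trait = tr,
            rho = ct$rho, p_value = ct$p_value, tier = ct$tier, n = ct$n)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Fit an exponential trend y = a * exp(b * x)
#'
#' Ordinary least squares on the log scale: a straight line is fitted to
#' `(x, log y)`, giving `log a` and `b`; decreasing trends have `b < 0`.
#' The coefficient of determination is reported on the log scale by default
#' (where the fit is linear); `r2_scale = "original"` computes
#' `1 - SS_res / SS_tot` against the back-transformed curve instead.
#'
#' @param x Predictor (degree-days).
#' @param y Response (must be strictly positive).
#' @param r2_scale `"log"` (default) or `"original"`.
#' @return Object of class `trend_fit`: `a`, `b`, `r2`, `r2_scale`, `n`.
#' @export
fit_exponential_trend <- function(x, y, r2_scale = c("log", "original")) {
  r2_scale <- match.arg(r2_scale)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("exponential trend requires strictly positive y", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("exponential trend requires a non-constant predictor", call. = FALSE)
  }
  fit <- stats::lm(log(y) ~ x)
  a <- unname(exp(stats::coef(fit)[1]))
  b <- unname(stats::coef(fit)[2])
  r2 <- if (r2_scale == "log") {
    # computed directly (not via summary.lm) so an exact fit is quiet
    sst <- sum((log(y) - mean(log(y)))^2)
    if (sst < 1e-24) 1 else 1 - sum(stats::resid(fit)^2) / sst
  } else {
    pred <- a * exp(b * x)
    1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }
  structure(list(a = a, b = b, r2 = r2, r2_scale = r2_scale, n = length(x)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> y = %.4g * exp(%.4g x) | R^2 = %.3f (%s scale) | n = %d\n",
              x$a, x$b, x$r2, x$r2_scale, x$n))
  invisible(x)
}

#' Exponential yield trends against thermal statistics
#'
#' Fits [fit_exponential_trend()] of a trait on GDD and SDD accumulated over
#' the chosen growth window, per location, over genotype x time-of-sowing
#' predicted means (the location's sowing times pooled). The default window
#' is the full season, where cumulative stress exposure differs most between
#' sowing times.
#'
#' @inheritParams correlate_thermal_traits
#' @param trait Trait column (strictly positive).
#' @param period Growth period supplying the thermal statistic.
#' @return Tibble: location, thermal, a, b, r2, n.
#' @export
thermal_trend_fits <- function(plots, profiles, trait = "yield_g",
                               period = "full_season") {
  prof <- profiles[profiles$stage == period, ]
  thermal_pm <- dplyr::summarise(
    dplyr::group_by(prof, .data$location, .data$tos, .data$genotype_id),
    gdd = mean(.data$gdd), sdd = mean(.data$sdd), .groups = "drop")
  trait_pm <- dplyr::summarise(
    dplyr::group_by(plots, .data$location, .data$tos, .data$genotype_id),
    value = mean(.data[[trait]]), .groups = "drop")
  dat <- dplyr::inner_join(thermal_pm, trait_pm,
                           by = c("location", "tos", "genotype_id"))
  dat <- dat[dat$value > 0, ]
  rows <- list()
  for (loc in unique(dat$location)) {
    sub <- dat[dat$location == loc, ]
    for (th in c("gdd", "sdd")) {
      if (stats::var(sub[[th]]) == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          location = loc, thermal = th, trait = trait, period = period,
          a = NA_real_, b = NA_real_, r2 = NA_real_, n = nrow(sub))
        next
      }
      ft <- fit_exponential_trend(sub[[th]], sub$value)
      rows[[length(rows) + 1]] <- tibble::tibble(
        location = loc, thermal = th, trait = trait, period = period,
        a = ft$a, b = ft$b, r2 = ft$r2, n = ft$n)
    }
  }
  dplyr::bind_rows(rows)
}
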