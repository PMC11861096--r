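#' Genotype x environment table of predicted means
#'
#' Builds the genotype-by-environment matrix of predicted trait means used by
#' all downstream stability, biplot and correlation analyses. Environments
#' are location x time-of-sowing combinations present in the data (filter
#' the plots first for a single-location, TOS-as-environment run). Cells are
#' replicate means after subtracting estimated block effects (block effect =
#' block mean - environment mean); with balanced complete blocks this equals
#' the plain replicate mean.
#'
#' @param plots Plot records.
#' @param trait Column to average, `"yield_g"` or `"hsw_g"` (any numeric
#'   plot column is accepted).
#' @return Numeric matrix of class `gxe_table` (genotypes x environments)
#'   with attribute `trait`.
#' @export
predicted_means <- function(plots, trait = c("yield_g", "hsw_g")) {
  trait <- if (length(trait) > 1) trait[1] else trait
  stopifnot(is.data.frame(plots), trait %in% names(plots))
  env <- paste(plots$location, plots$tos, sep = ":")
  gid <- plots$genotype_id
  counts <- table(gid, env)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)
    msg <- paste(sprintf("genotype %s in %s", rownames(counts)[bad[, 1]],
                         colnames(counts)[bad[, 2]]), collapse = "; ")
    stop("incomplete genotype x environment table; missing cells: ", msg,
         call. = FALSE)
  }
  y <- plots[[trait]]
  env_mean <- stats::ave(y, env)
  block_mean <- stats::ave(y, env, plots$replicate)
  adj <- y - (block_mean - env_mean)
  cell <- tapply(adj, list(gid, env), mean)
  ord <- order(suppressWarnings(as.numeric(rownames(cell))), rownames(cell))
  cell <- cell[ord, , drop = FALSE]
  structure(cell, trait = trait, class = c("gxe_table", "matrix", "array"))
}

#' Coerce a matrix to a genotype x environment table
#'
#' @param x Numeric matrix, genotypes in rows, environments in columns.
#' @param trait Trait label to attach.
#' @return A `gxe_table`.
#' @export
as_gxe_table <- function(x, trait = "trait") {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("E", seq_len(ncol(x)))
  structure(x, trait = trait, class = c("gxe_table", "matrix", "array"))
}

#' Environment-level summary table
#'
#' Per location and time of sowing: mean and standard deviation of stage age,
#' grow days, GDD and SDD at the requested stage, plus yield (converted to
#' t/ha from plot grams and area) and 100-seed weight. `stage = "flowering"`
#' summarises accumulation from sowing to flowering (the vegetative window);
#' `stage = "maturity"` the full season.
#'
#' @param plots Plot records.
#' @param profiles Output of [thermal_profiles()] for the same plots.
#' @param stage `"flowering"` or `"maturity"`.
#' @return Tibble with one row per (location, tos).
#' @export
environment_summary <- function(plots, profiles,
                                stage = c("flowering", "maturity")) {
  stage <- match.arg(stage)
  window <- c(flowering = "vegetative", maturity = "full_season")[[stage]]
  prof <- profiles[profiles$stage == window,
                   c("plot_id", "age_days", "grow_days", "gdd", "sdd")]
  if (!all(plots$plot_id %in% prof$plot_id)) {
    stop("thermal profiles missing for some plots", call. = FALSE)
  }
  dat <- dplyr::inner_join(plots, prof, by = "plot_id")
  dat$yield_t_ha <- grams_per_plot_to_t_ha(dat$yield_g, dat$plot_area_m2)
  dplyr::summarise(
    dplyr::group_by(dat, .data$location, .data$tos),
    stage = stage,
    age_mean = mean(.data$age_days), age_sd = stats::sd(.data$age_days),
    grow_days_mean = mean(.data$grow_days),
    grow_days_sd = stats::sd(.data$grow_days),
    gdd_mean = mean(.data$gdd), gdd_sd = stats::sd(.data$gdd),
    sdd_mean = mean(.data$sdd), sdd_sd = stats::sd(.data$sdd),
    yield_t_ha_mean = mean(.data$yield_t_ha),
    yield_t_ha_sd = stats::sd(.data$yield_t_ha),
    hsw_mean = mean(.data$hsw_g), hsw_sd = stats::sd(.data$hsw_g),
    .groups = "drop"
  )
}

#' Relative difference between two values, in percent
#'
#' The proportional-difference convention used throughout the environment
#' comparisons: `(max(a, b) - min(a, b)) / max(a, b) * 100`. It is symmetric
#' in its arguments and bounded in `[0, 100)` for positive inputs. Note this
#' divides by the *larger* value — not the more common "percent change"
#' `(max - min) / min`.
#'
#' @param a,b Trait values (vectorised; `max(a, b) > 0` required pairwise).
#' @return Percentage difference(s).
#' @examples
#' relative_difference(783, 641)  # 18.1
#' relative_difference(85, 65)    # 23.5
#' @export
relative_difference <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  if (any(!is.finite(hi)) || any(hi <= 0)) {
    stop("relative_difference undefined: larger value must be positive",
         call. = FALSE)
  }
  (hi - lo) / hi * 100
}

#' Convert plot yield in grams to tonnes per hectare
#'
#' `1 g/m^2 = 0.01 t/ha`, so `yield_g / plot_area_m2 * 0.01`.
#'
#' @param yield_g Plot yield in grams.
#' @param plot_area_m2 Plot area in square metres (default 8).
#' @return Yield in t/ha.
#' @examples
#' grams_per_plot_to_t_ha(1784, 8)  # 2.23
#' @export
grams_per_plot_to_t_ha <- function(yield_g, plot_area_m2 = 8) {
  stopifnot(all(plot_area_m2 > 0))
  yield_g / plot_area_m2 * 0.01
}
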