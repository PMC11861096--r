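#' Read a daily weather CSV
#'
#' Expects a headered CSV with columns `date` (ISO-8601), `tmin`, `tmax`.
#' Rows are validated (parseable date, finite temperatures, `tmax >= tmin`)
#' with errors reporting the offending file line; duplicate dates are
#' rejected; the result is sorted by date.
#'
#' @param path Path to the CSV file.
#' @return Tibble with columns `date`, `tmin`, `tmax`.
#' @export
read_weather_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin", "tmax")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("weather CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop(sprintf("%s line %d: unparseable date '%s'", path,
                 line[which(is.na(dates))[1]],
                 raw$date[which(is.na(dates))[1]]), call. = FALSE)
  }
  tmin <- suppressWarnings(as.numeric(raw$tmin))
  tmax <- suppressWarnings(as.numeric(raw$tmax))
  bad <- which(!is.finite(tmin) | !is.finite(tmax))
  if (length(bad)) {
    stop(sprintf("%s line %d: non-numeric temperature", path, line[bad[1]]),
         call. = FALSE)
  }
  bad <- which(tmax < tmin)
  if (length(bad)) {
    stop(sprintf("%s line %d: tmax < tmin", path, line[bad[1]]),
         call. = FALSE)
  }
  if (anyDuplicated(dates)) {
    stop(sprintf("%s: duplicate date %s", path,
                 format(dates[duplicated(dates)][1])), call. = FALSE)
  }
  ord <- order(dates)
  tibble::tibble(date = dates[ord], tmin = tmin[ord], tmax = tmax[ord])
}

#' Write a daily weather CSV
#'
#' @param weather Weather table (`date`, `tmin`, `tmax`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(weather, path) {
  w <- as_weather(weather)
  w$date <- format(w$date, "%Y-%m-%d")
  utils::write.csv(w, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

plots_columns <- c("plot_id", "genotype_id", "location", "tos", "replicate",
                   "sowing_date", "flowering_date", "maturity_date",
                   "yield_g", "hsw_g", "plot_area_m2")

#' Read a plot-records CSV
#'
#' Columns: `plot_id`, `genotype_id`, `location`, `tos`, `replicate`,
#' `sowing_date`, `flowering_date`, `maturity_date`, `yield_g`, `hsw_g` and
#' optionally `plot_area_m2` (default 8). Dates must satisfy
#' `sowing <= flowering <= maturity`; a missing maturity date is allowed —
#' the record is retained and its reproductive-stage quantities are reported
#' as `NA` downstream.
#'
#' @param path Path to the CSV file.
#' @return Tibble of plot records.
#' @export
read_plots_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(plots_columns, "plot_area_m2")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("plots CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"plot_area_m2" %in% names(raw)) raw$plot_area_m2 <- 8
  out <- tibble::tibble(
    plot_id = as.character(raw$plot_id),
    genotype_id = raw$genotype_id,
    location = as.character(raw$location),
    tos = as.integer(raw$tos),
    replicate = as.integer(raw$replicate),
    sowing_date = as.Date(raw$sowing_date),
    flowering_date = as.Date(raw$flowering_date),
    maturity_date = as.Date(ifelse(raw$maturity_date %in% c("", "NA"),
                                   NA, as.character(raw$maturity_date))),
    yield_g = as.numeric(raw$yield_g),
    hsw_g = as.numeric(raw$hsw_g),
    plot_area_m2 = as.numeric(raw$plot_area_m2)
  )
  if (anyNA(out$sowing_date) || anyNA(out$flowering_date)) {
    stop("plots CSV: sowing and flowering dates are required for every record",
         call. = FALSE)
  }
  bad <- which(out$sowing_date > out$flowering_date |
                 (!is.na(out$maturity_date) &
                    out$flowering_date > out$maturity_date))
  if (length(bad)) {
    stop(sprintf("phenology dates out of order for plot %s",
                 out$plot_id[bad[1]]), call. = FALSE)
  }
  if (any(out$yield_g < 0, na.rm = TRUE)) {
    stop("plots CSV: negative yield", call. = FALSE)
  }
  if (any(out$hsw_g <= 0, na.rm = TRUE)) {
    stop("plots CSV: 100-seed weight must be positive", call. = FALSE)
  }
  out
}

#' Write a plot-records CSV
#'
#' @param plots Plot records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plots_csv <- function(plots, path) {
  out <- as.data.frame(plots[intersect(plots_columns, names(plots))])
  for (col in c("sowing_date", "flowering_date", "maturity_date")) {
    out[[col]] <- format(as.Date(out[[col]]), "%Y-%m-%d")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Either point `weather_csvs` (named by location) and `plots_csv` at
#' existing data, or leave them `NULL` to simulate the default synthetic
#' scenario under `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for simulation.
#' @param weather_csvs Named character vector of weather CSV paths, or NULL.
#' @param plots_csv Plots CSV path, or NULL.
#' @param t_base,t_growth_ceiling,t_stress_ceiling,capping_rule Thermal
#'   settings, see [thermal_config()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "thermet_out", seed = 1,
                            weather_csvs = NULL, plots_csv = NULL,
                            t_base = 10, t_growth_ceiling = 30,
                            t_stress_ceiling = 50,
                            capping_rule = "cap_max_floor_min") {
  structure(list(out_dir = out_dir, seed = seed,
                 weather_csvs = weather_csvs, plots_csv = plots_csv,
                 thermal = thermal_config(t_base, t_growth_ceiling,
                                          t_stress_ceiling, capping_rule)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  if (!is.null(args$weather_csvs)) args$weather_csvs <- unlist(args$weather_csvs)
  do.call(pipeline_config, args)
}

write_tbl <- function(x, path) {
  df <- as.data.frame(x)
  for (col in names(df)) {
    if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a multi-environment trial, then runs every stage —
#' thermal profiles, environment summaries, predicted means, stability
#' ranking, GGE decomposition, heritability, thermal-trait correlations and
#' exponential trend fits — and writes one CSV per output plus a JSON run
#' manifest to `config$out_dir`. Given fixed inputs and seed the outputs are
#' byte-identical across reruns.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @return Invisible list of all computed objects.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config$thermal
  simulated <- is.null(config$plots_csv)
  if (simulated) {
    trial <- simulate_trial(seed = config$seed, config = cfg)
    plots <- trial$plots
    weather <- trial$weather
    for (loc in names(weather)) {
      write_weather_csv(weather[[loc]],
                        file.path(config$out_dir,
                                  paste0("weather_", loc, ".csv")))
    }
    write_plots_csv(plots, file.path(config$out_dir, "plots.csv"))
  } else {
    plots <- read_plots_csv(config$plots_csv)
    weather <- lapply(config$weather_csvs, read_weather_csv)
  }

  message("thermet: thermal profiles")
  profiles <- thermal_profiles(plots, weather, cfg)
  write_tbl(profiles, file.path(config$out_dir, "thermal_profiles.csv"))

  message("thermet: environment summaries")
  env_sum <- dplyr::bind_rows(
    environment_summary(plots, profiles, "flowering"),
    environment_summary(plots, profiles, "maturity"))
  write_tbl(env_sum, file.path(config$out_dir, "environment_summary.csv"))

  message("thermet: predicted means, stability, GGE")
  traits <- c("yield_g", "hsw_g")
  pm <- lapply(stats::setNames(traits, traits),
               function(tr) predicted_means(plots, tr))
  stab_rows <- list(); gge_rows <- list()
  for (tr in traits) {
    write_tbl(tibble::as_tibble(unclass(pm[[tr]]), rownames = "genotype"),
              file.path(config$out_dir, paste0("predicted_means_", tr, ".csv")))
    for (loc in unique(plots$location)) {
      sub <- plots[plots$location == loc, ]
      if (length(unique(sub$tos)) < 2) next
      st <- stability_analysis(predicted_means(sub, tr))
      st$location <- loc; st$trait <- tr
      stab_rows[[length(stab_rows) + 1]] <- st
    }
    gge <- gge_decompose(pm[[tr]])
    gge_rows[[length(gge_rows) + 1]] <- tibble::tibble(
      trait = tr, component = c("PC1", "PC2"),
      variance_pct = gge$pc_variance_pct)
    write_tbl(tibble::as_tibble(gge$genotype_scores, rownames = "genotype"),
              file.path(config$out_dir, paste0("gge_scores_", tr, ".csv")))
  }
  stability <- dplyr::bind_rows(stab_rows)
  write_tbl(stability, file.path(config$out_dir, "stability.csv"))
  gge_var <- dplyr::bind_rows(gge_rows)
  write_tbl(gge_var, file.path(config$out_dir, "gge_variance.csv"))

  message("thermet: heritability")
  herit <- heritability_by_environment(plots, traits)
  write_tbl(herit, file.path(config$out_dir, "heritability.csv"))

  message("thermet: correlations and trend fits")
  correlations <- correlate_thermal_traits(plots, profiles)
  write_tbl(correlations, file.path(config$out_dir, "correlations.csv"))
  trends <- thermal_trend_fits(plots, profiles)
  write_tbl(trends, file.path(config$out_dir, "trend_fits.csv"))

  manifest <- list(
    package = "thermet",
    version = as.character(utils::packageVersion("thermet")),
    seed = config$seed,
    simulated = simulated,
    thermal = unclass(cfg),
    inputs = list(plots_csv = config$plots_csv,
                  weather_csvs = as.list(config$weather_csvs)),
    outputs = list.files(config$out_dir, pattern = "\\.csv$")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(plots = plots, weather = weather, profiles = profiles,
                 environment_summary = env_sum, predicted_means = pm,
                 stability = stability, gge_variance = gge_var,
                 heritability = herit, correlations = correlations,
                 trend_fits = trends, manifest = manifest))
}
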