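#' RCBD variance components for one environment
#'
#' Method-of-moments solution of the two-way (genotype + block) analysis of
#' variance for a balanced randomized complete block design within a single
#' environment: the residual variance is the error mean square and the
#' genetic variance is `(MS_genotype - MS_error) / r`, truncated at zero
#' (variance components are non-negative by definition).
#'
#' @param plots Plot records from exactly one environment (one location x
#'   time-of-sowing combination).
#' @param trait Trait column, e.g. `"yield_g"` or `"hsw_g"`.
#' @return List: `s_g2`, `s_e2`, `r` (replicates), `ms_genotype`,
#'   `ms_error`, `n_genotypes`.
#' @export
variance_components_rcbd <- function(plots, trait = c("yield_g", "hsw_g")) {
  trait <- if (length(trait) > 1) trait[1] else trait
  stopifnot(is.data.frame(plots), trait %in% names(plots))
  env <- unique(paste(plots$location, plots$tos, sep = ":"))
  if (length(env) != 1) {
    stop("plots span several environments; fit one model per environment",
         call. = FALSE)
  }
  g <- factor(plots$genotype_id)
  b <- factor(plots$replicate)
  counts <- table(g, b)
  if (any(counts != 1) || nlevels(b) < 2) {
    stop("unbalanced design: the RCBD estimator needs every genotype exactly once in each of >= 2 blocks",
         call. = FALSE)
  }
  r <- nlevels(b)
  fit <- stats::aov(plots[[trait]] ~ g + b)
  tab <- summary(fit)[[1]]
  ms <- tab[["Mean Sq"]]
  names(ms) <- trimws(rownames(tab))
  ms_g <- ms[["g"]]
  ms_e <- ms[["Residuals"]]
  list(s_g2 = max(0, (ms_g - ms_e) / r), s_e2 = ms_e, r = r,
       ms_genotype = ms_g, ms_error = ms_e, n_genotypes = nlevels(g))
}

#' Broad-sense heritability
#'
#' `H^2 = s_g2 / (s_g2 + s_e2 / r)`: the fraction of variance among genotype
#' means attributable to genetic variance, given `r` replicates. Lies in
#' `[0, 1]` and increases with replication for fixed variances.
#'
#' @param s_g2 Genetic variance (>= 0).
#' @param s_e2 Residual variance (>= 0).
#' @param r Number of replicates (>= 1).
#' @return Heritability in `[0, 1]`.
#' @examples
#' broad_sense_heritability(1, 1, 2)  # 2/3
#' @export
broad_sense_heritability <- function(s_g2, s_e2, r) {
  stopifnot(is.numeric(s_g2), is.numeric(s_e2), r >= 1)
  if (any(s_g2 < 0) || any(s_e2 < 0)) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  if (any(s_g2 + s_e2 == 0)) {
    stop("heritability undefined when both variance components are zero",
         call. = FALSE)
  }
  s_g2 / (s_g2 + s_e2 / r)
}

#' Heritability of each trait in each environment
#'
#' Fits the within-environment RCBD variance-component model for every
#' location x time-of-sowing combination and trait, and returns the
#' broad-sense heritabilities.
#'
#' @param plots Plot records (any number of environments).
#' @param traits Trait columns to analyse.
#' @return Tibble: location, tos, environment, trait, s_g2, s_e2, r, h2.
#' @export
heritability_by_environment <- function(plots,
                                        traits = c("yield_g", "hsw_g")) {
  envs <- unique(plots[c("location", "tos")])
  rows <- list()
  for (i in seq_len(nrow(envs))) {
    sub <- plots[plots$location == envs$location[i] &
                   plots$tos == envs$tos[i], ]
    for (tr in traits) {
      vc <- variance_components_rcbd(sub, tr)
      rows[[length(rows) + 1]] <- tibble::tibble(
        location = envs$location[i], tos = envs$tos[i],
        environment = paste(envs$location[i], envs$tos[i], sep = ":"),
        trait = tr, s_g2 = vc$s_g2, s_e2 = vc$s_e2, r = vc$r,
        h2 = broad_sense_heritability(vc$s_g2, vc$s_e2, vc$r)
      )
    }
  }
  dplyr::bind_rows(rows)
}
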