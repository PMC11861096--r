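as_table_matrix <- function(table, min_env = 2) {
  x <- unclass(as.matrix(table))
  if (anyNA(x)) stop("genotype x environment table has missing cells",
                     call. = FALSE)
  if (ncol(x) < min_env) {
    stop(sprintf("at least %d environments required", min_env),
         call. = FALSE)
  }
  x
}

#' Cultivar superiority (Lin & Binns)
#'
#' Mean squared distance of each genotype from the best genotype in each
#' environment: `P_i = sum_j (X_ij - M_j)^2 / (2 n)`, with `M_j` the column
#' maximum and `n` the number of environments. `P_i = 0` iff genotype `i` is
#' the maximum in every environment; low values mark broadly superior
#' genotypes.
#'
#' @param table A [predicted_means()] table (or plain matrix), genotypes x
#'   environments, at least 2 environments, no missing cells.
#' @return Named numeric vector of superiority coefficients (squared trait
#'   units).
#' @export
superiority <- function(table) {
  x <- as_table_matrix(table)
  m <- apply(x, 2, max)
  rowSums(sweep(x, 2, m)^2) / (2 * ncol(x))
}

#' Static stability
#'
#' Sample variance of each genotype's means across environments:
#' `S_i^2 = sum_j (X_ij - mean_i)^2 / (n - 1)`. Zero for a genotype constant
#' across environments; low values mark environment-insensitive genotypes.
#'
#' @inheritParams superiority
#' @return Named numeric vector of variances (squared trait units).
#' @export
static_stability <- function(table) {
  x <- as_table_matrix(table)
  apply(x, 1, stats::var)
}

#' Rank coefficients and select the top set
#'
#' Ascending order: the lowest coefficient gets rank 1. Ties are broken
#' deterministically by genotype id.
#'
#' @param coefficients Named numeric vector (names = genotype ids).
#' @param k Size of the selected top set.
#' @return List with `ranking` (tibble: genotype, coefficient, rank) and
#'   `top` (character vector of the k best genotype ids).
#' @export
rank_and_select <- function(coefficients, k = 10) {
  stopifnot(is.numeric(coefficients), k >= 1, k <= length(coefficients))
  ids <- names(coefficients)
  if (is.null(ids)) ids <- as.character(seq_along(coefficients))
  num <- suppressWarnings(as.numeric(ids))
  ord <- if (anyNA(num)) order(coefficients, ids) else order(coefficients, num)
  rk <- integer(length(ord))
  rk[ord] <- seq_along(ord)
  list(ranking = tibble::tibble(genotype = ids, coefficient = coefficients,
                                rank = rk),
       top = ids[ord[seq_len(k)]])
}

#' Fraction of a selected set shared with another
#'
#' @param a,b Character vectors of selected genotype ids (typically the
#'   top-k sets from two locations).
#' @return `length(intersect(a, b)) / length(a)`.
#' @export
selection_overlap <- function(a, b) {
  stopifnot(length(a) >= 1)
  length(intersect(a, b)) / length(a)
}

#' Combined stability analysis
#'
#' Superiority and static stability with their ranks, one row per genotype.
#'
#' @inheritParams superiority
#' @param k Top-set size used for the `top_superiority` / `top_static`
#'   attributes.
#' @return Tibble: genotype, superiority, static_stability,
#'   rank_superiority, rank_static.
#' @export
stability_analysis <- function(table, k = 10) {
  x <- as_table_matrix(table)
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  sup <- stats::setNames(superiority(x), rownames(x))
  sta <- stats::setNames(static_stability(x), rownames(x))
  k <- min(k, nrow(x))
  rs <- rank_and_select(sup, k)
  rt <- rank_and_select(sta, k)
  out <- tibble::tibble(
    genotype = rownames(x),
    superiority = unname(sup),
    static_stability = unname(sta),
    rank_superiority = rs$ranking$rank,
    rank_static = rt$ranking$rank
  )
  attr(out, "top_superiority") <- rs$top
  attr(out, "top_static") <- rt$top
  attr(out, "trait") <- attr(table, "trait")
  out
}

#' GGE biplot decomposition
#'
#' Centers each environment column by its mean — removing the environment
#' main effect while retaining genotype main effects and genotype-by-
#' environment interaction ("G + GE") — then takes the singular value
#' decomposition of the centered matrix. The percentage of variance on
#' component k is `100 * d_k^2 / sum(d^2)`. Axis signs are fixed by a
#' deterministic convention: the largest-magnitude environment loading on
#' each retained component is made positive.
#'
#' Score scaling: `"symmetric"` (default) gives both sides `sqrt(d)`;
#' `"genotype_focused"` gives genotypes `d` and environments unit loadings;
#' `"environment_focused"` the reverse.
#'
#' @param table Genotype x environment table, `>= 3` genotypes and `>= 2`
#'   environments.
#' @param scaling Score scaling, see Details.
#' @return Object of class `gge_biplot`: genotype and environment score
#'   matrices (2 components), `pc_variance_pct` (first two percentages),
#'   `variance_pct_all`, and a `degenerate` flag (zero-variance input gives
#'   zero scores).
#' @export
gge_decompose <- function(table, scaling = c("symmetric", "genotype_focused",
                                             "environment_focused")) {
  scaling <- match.arg(scaling)
  x <- as_table_matrix(table)
  if (nrow(x) < 3) stop("at least 3 genotypes required", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("E", seq_len(ncol(x)))
  cx <- sweep(x, 2, colMeans(x))
  tot <- sum(cx^2)
  if (tot < 1e-12) {
    g <- matrix(0, nrow(x), 2, dimnames = list(rownames(x), c("PC1", "PC2")))
    e <- matrix(0, ncol(x), 2, dimnames = list(colnames(x), c("PC1", "PC2")))
    return(structure(list(genotype_scores = g, environment_scores = e,
                          pc_variance_pct = c(0, 0),
                          variance_pct_all = rep(0, min(dim(x))),
                          scaling = scaling, trait = attr(table, "trait"),
                          degenerate = TRUE),
                     class = "gge_biplot"))
  }
  sv <- svd(cx)
  pct <- sv$d^2 / sum(sv$d^2) * 100
  u <- sv$u[, 1:2, drop = FALSE]
  v <- sv$v[, 1:2, drop = FALSE]
  d <- sv$d[1:2]
  for (k in 1:2) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) {
      v[, k] <- -v[, k]
      u[, k] <- -u[, k]
    }
  }
  scale_g <- switch(scaling, symmetric = sqrt(d), genotype_focused = d,
                    environment_focused = c(1, 1))
  scale_e <- switch(scaling, symmetric = sqrt(d), genotype_focused = c(1, 1),
                    environment_focused = d)
  g <- u %*% diag(scale_g, 2)
  e <- v %*% diag(scale_e, 2)
  dimnames(g) <- list(rownames(x), c("PC1", "PC2"))
  dimnames(e) <- list(colnames(x), c("PC1", "PC2"))
  structure(list(genotype_scores = g, environment_scores = e,
                 pc_variance_pct = pct[1:2], variance_pct_all = pct,
                 scaling = scaling, trait = attr(table, "trait"),
                 degenerate = FALSE),
            class = "gge_biplot")
}

#' @export
print.gge_biplot <- function(x, ...) {
  cat(sprintf("<gge_biplot>%s %d genotypes x %d environments | PC1 %.2f%% PC2 %.2f%% | %s scaling\n",
              if (is.null(x$trait)) "" else paste0(" [", x$trait, "]"),
              nrow(x$genotype_scores), nrow(x$environment_scores),
              x$pc_variance_pct[1], x$pc_variance_pct[2], x$scaling))
  if (x$degenerate) cat("  (degenerate: zero-variance input)\n")
  invisible(x)
}

#' Plot a GGE biplot
#'
#' Genotypes as points, environments as labelled vectors from the origin.
#'
#' @param object A [gge_decompose()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.gge_biplot <- function(object, ...) {
  gs <- tibble::as_tibble(object$genotype_scores, rownames = "genotype")
  es <- tibble::as_tibble(object$environment_scores, rownames = "environment")
  ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_point(data = gs,
                        ggplot2::aes(x = .data$PC1, y = .data$PC2),
                        colour = "grey30", size = 1) +
    ggplot2::geom_segment(data = es,
                          ggplot2::aes(x = 0, y = 0, xend = .data$PC1,
                                       yend = .data$PC2),
                          colour = "firebrick",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(data = es,
                       ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                    label = .data$environment),
                       colour = "firebrick", vjust = -0.6, size = 3) +
    ggplot2::labs(
      title = if (is.null(object$trait)) "GGE biplot" else
        paste("GGE biplot:", object$trait),
      x = sprintf("PC1 (%.1f%%)", object$pc_variance_pct[1]),
      y = sprintf("PC2 (%.1f%%)", object$pc_variance_pct[2])
    ) +
    ggplot2::theme_minimal()
}
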