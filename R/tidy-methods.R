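#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a production-loss model fit
#'
#' @param x A `carbon_fit`.
#' @param ... Unused.
#' @return A tibble with one row per producer: `producer`, `rate`.
#' @export
tidy.carbon_fit <- function(x, ...) x$rates

#' One-row summary of a production-loss model fit
#'
#' @param x A `carbon_fit`.
#' @param ... Unused.
#' @return A tibble with `d`, `r2`, `n`.
#' @export
glance.carbon_fit <- function(x, ...) {
  tibble::tibble(d = x$d, r2 = x$r2, n = nrow(x$observed))
}

#' Tidy a joint multi-bag production-loss fit
#'
#' @param x A `carbon_fit_set`.
#' @param ... Unused.
#' @return A tibble with one row per (bag, producer).
#' @export
tidy.carbon_fit_set <- function(x, ...) x$rates

#' One-row summary of a joint multi-bag fit
#'
#' @param x A `carbon_fit_set`.
#' @param ... Unused.
#' @return A tibble with `variable`, `d`, `r2`, `n_bags`.
#' @export
glance.carbon_fit_set <- function(x, ...) {
  tibble::tibble(variable = x$variable, d = x$d, r2 = x$r2,
                 n_bags = length(x$bags))
}

#' Tidy the infected-cell multiplier scan
#'
#' @param x An `infection_fit`.
#' @param ... Unused.
#' @return The deviation per candidate multiplier.
#' @export
tidy.infection_fit <- function(x, ...) x$i_scan

#' One-row summary of the infected-cell multiplier fit
#'
#' @param x An `infection_fit`.
#' @param ... Unused.
#' @return A tibble with `I`, `T`, `deviation`.
#' @export
glance.infection_fit <- function(x, ...) {
  tibble::tibble(I = x$I, T = x$T, deviation = x$deviation)
}

#' Tidy a succession clustering
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return Per-taxon cluster labels.
#' @export
tidy.cluster_result <- function(x, ...) x$labels

#' One-row summary of a succession clustering
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return A tibble with `n_clusters`, best silhouette `score`,
#'   `degenerate`.
#' @export
glance.cluster_result <- function(x, ...) {
  best <- x$silhouette$score[match(x$n_clusters, x$silhouette$k)]
  tibble::tibble(n_clusters = x$n_clusters,
                 score = if (length(best) == 0) NA_real_ else best,
                 degenerate = x$degenerate)
}

#' Tidy a dilution-experiment result
#'
#' @param x A `dilution_result`.
#' @param ... Unused.
#' @return A one-row tibble of rates and pooling decisions.
#' @export
tidy.dilution_result <- function(x, ...) {
  tibble::tibble(mu = x$mu, g = x$g, v = x$v,
                 k1_nut = x$k1_nut, k1 = x$k1, kd = x$kd,
                 kd_tff = x$kd_tff,
                 pooled_nutrients = x$pooled_nutrients,
                 p_nutrients = x$p_nutrients, p_grazing = x$p_grazing,
                 p_lysis = x$p_lysis)
}
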