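#' Integrated abundance per bag over common sampling days
#'
#' Restricts to days on which every bag has a non-missing value of the
#' variable, then sums per bag. Used to compare whole-experiment totals
#' (e.g. host cells vs viral load) across enclosures.
#'
#' @param table A measurement tibble.
#' @param variable Variable to integrate.
#' @return A tibble with columns `bag` and `total`.
#' @export
integrate_abundance <- function(table, variable) {
  x <- table |> dplyr::filter(.data$variable == !!variable)
  if (nrow(x) == 0) stop("no observations of ", variable, call. = FALSE)
  bags <- unique(x$bag)
  common <- x |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::distinct(.data$bag, .data$day) |>
    dplyr::count(.data$day) |>
    dplyr::filter(.data$n == length(bags)) |>
    dplyr::pull(.data$day)
  if (length(common) == 0) {
    stop("no day on which every bag has a value", call. = FALSE)
  }
  x |>
    dplyr::filter(.data$day %in% common) |>
    dplyr::group_by(.data$bag) |>
    dplyr::summarise(total = sum(.data$value), .groups = "drop")
}

#' Exponential growth rate from log-linear fits with shifted windows
#'
#' Ordinary least-squares slope of log abundance against day over a window,
#' repeated with the window start shifted by each element of `shifts`
#' (selecting the twice-daily sample nearest each shifted start). The mean
#' and standard deviation over the shifted fits quantify sensitivity to the
#' exact window start. Non-positive abundances are dropped before the log
#' transform; it is an error if fewer than 3 points remain.
#'
#' @param table A measurement tibble with twice-daily samples.
#' @param variable Variable to fit.
#' @param bag Bag to fit.
#' @param window `c(start_day, end_day)`.
#' @param shifts Start-day shifts in days (default -0.5, 0, +0.5).
#' @return A one-row tibble: `bag`, `variable`, `window_start`,
#'   `window_end`, `rate`, `rate_sd`, `n_fits`.
#' @export
fit_growth_rate <- function(table, variable, bag, window,
                            shifts = c(-0.5, 0, 0.5)) {
  x <- table |>
    dplyr::filter(.data$variable == !!variable, .data$bag == !!bag,
                  !is.na(.data$value))
  if (nrow(x) == 0) stop("no observations", call. = FALSE)
  lo <- min(vapply(shifts, function(s) {
    x$day[which.min(abs(x$day - (window[1] + s)))]
  }, numeric(1)))
  in_window <- x$day >= lo - 1e-9 & x$day <= window[2] + 1e-9
  dropped <- sum(x$value[in_window] <= 0)
  if (dropped > 0) {
    warning(dropped,
            " non-positive value(s) in window dropped before log transform")
  }
  x <- dplyr::filter(x, .data$value > 0)
  slopes <- vapply(shifts, function(s) {
    target <- window[1] + s
    start_actual <- x$day[which.min(abs(x$day - target))]
    w <- dplyr::filter(x, .data$day >= start_actual - 1e-9,
                       .data$day <= window[2] + 1e-9)
    if (nrow(w) < 3) {
      stop("fewer than 3 positive observations in window", call. = FALSE)
    }
    unname(stats::coef(stats::lm(log(value) ~ day, data = w))[2])
  }, numeric(1))
  tibble::tibble(bag = bag, variable = variable,
                 window_start = window[1], window_end = window[2],
                 rate = mean(slopes), rate_sd = stats::sd(slopes),
                 n_fits = length(slopes))
}

#' Growth-rate window presets per population
#'
#' Named default fitting windows: thraustochytrids until their abundance
#' maximum; free-living bacteria after day 15 until the final day except the
#' two most infected bags (bag 4 until day 22, bag 7 until day 18); 2-20 um
#' bacteria after day 10 until the final day except bags 4 and 7 (until day
#' 22). All overridable.
#'
#' @param n_days Experiment length in days (default 24).
#' @return A nested list `preset[[population]][[bag]] = c(start, end)` with
#'   a `default` entry per population.
#' @export
growth_window_presets <- function(n_days = 24) {
  final <- n_days - 1
  list(
    thraustochytrids = list(default = c(NA, NA)),  # until per-bag maximum
    bacteria_fl = list(default = c(15, final), `4` = c(15, 22),
                       `7` = c(15, 18)),
    bacteria_2_20 = list(default = c(10, final), `4` = c(10, 22),
                         `7` = c(10, 22))
  )
}

#' Convert cell counts to carbon biomass
#'
#' Multiplies abundances (cells/mL) by a per-cell carbon factor:
#' thraustochytrids 1.65e-10 g C/cell, bacteria 1e-14 g C/cell, E. huxleyi
#' from the spherical-cell estimate (see [cell_carbon()]). Unknown groups
#' require an explicit factor.
#'
#' @param counts A measurement tibble (or data frame with `bag`, `day`,
#'   `value` in cells/mL).
#' @param group One of `"thraustochytrid"`, `"bacteria"`, `"ehux"`, or any
#'   label if `factor` is supplied.
#' @param factor Optional per-cell carbon in g C/cell, overriding the
#'   built-in factors.
#' @return A tibble with columns `bag`, `day`, `group`, `biomass_g_c_ml`
#'   and `factor_g_c_cell`.
#' @export
biomass_from_counts <- function(counts, group, factor = NULL) {
  builtin <- c(thraustochytrid = 1.65e-10,
               bacteria = 1e-14,
               ehux = cell_carbon(2.5)$carbon_fg * 1e-15)
  if (is.null(factor)) {
    if (!group %in% names(builtin)) {
      stop("unknown group '", group, "': supply an explicit factor",
           call. = FALSE)
    }
    factor <- unname(builtin[group])
  }
  tibble::tibble(bag = counts$bag, day = counts$day, group = group,
                 biomass_g_c_ml = counts$value * factor,
                 factor_g_c_cell = factor)
}

#' Exponential rate of change of the thraustochytrid:bacteria biomass ratio
#'
#' OLS slope k of log biomass ratio against day over a window:
#' log BR(t) = k t + log BR(0). The window defaults to day 10 up to the day
#' on which the ratio is maximal. For exact exponential series k equals the
#' difference of the two groups' growth rates.
#'
#' @param thrausto,bacteria Biomass tibbles (see [biomass_from_counts()])
#'   for one bag, sharing days.
#' @param window Optional `c(start, end)`; default `c(10, day of max
#'   ratio)`.
#' @return A one-row tibble with `rate`, `window_start`, `window_end`, `n`.
#' @export
fit_biomass_ratio_rate <- function(thrausto, bacteria, window = NULL) {
  joined <- dplyr::inner_join(
    dplyr::select(thrausto, "day", thr = "biomass_g_c_ml"),
    dplyr::select(bacteria, "day", bac = "biomass_g_c_ml"),
    by = "day") |>
    dplyr::arrange(.data$day)
  if (any(joined$bac <= 0 & joined$thr > 0)) {
    stop("zero bacterial biomass on a day with thraustochytrid biomass",
         call. = FALSE)
  }
  joined <- dplyr::filter(joined, .data$thr > 0, .data$bac > 0)
  joined$ratio <- joined$thr / joined$bac
  if (is.null(window)) {
    # last day attaining the maximum, so a flat ratio keeps its full window
    at_max <- joined$ratio >= max(joined$ratio) * (1 - 1e-12)
    window <- c(10, max(joined$day[at_max]))
  }
  w <- dplyr::filter(joined, .data$day >= window[1], .data$day <= window[2])
  if (nrow(w) < 2) stop("fewer than 2 ratio points in window", call. = FALSE)
  k <- unname(stats::coef(stats::lm(log(ratio) ~ day, data = w))[2])
  tibble::tibble(rate = k, window_start = window[1], window_end = window[2],
                 n = nrow(w))
}

#' Linear correlation of a per-bag metric with total viral load
#'
#' Two modes: `"stratified"` fits a simple linear regression separately for
#' covered and uncovered enclosures; `"pooled"` fits a single regression
#' with an additive cover-class term (the metric corrected for bag cover).
#' When the two cover classes share an intercept the pooled slope equals
#' the stratified slopes.
#'
#' @param data A data frame with one row per bag: columns `metric`,
#'   `viral_total`, and logical `covered`.
#' @param mode `"stratified"` or `"pooled"`.
#' @return A tibble with one row per stratum (or one pooled row): `stratum`,
#'   `slope`, `r2`, `p` (two-sided p of the slope).
#' @export
correlate_with_viral_load <- function(data, mode = c("stratified", "pooled")) {
  mode <- match.arg(mode)
  if (stats::var(data$viral_total) == 0) {
    stop("zero variance in viral load", call. = FALSE)
  }
  fit_one <- function(df, stratum, formula) {
    fit <- stats::lm(formula, data = df)
    sm <- summary(fit)
    tibble::tibble(stratum = stratum,
                   slope = unname(stats::coef(fit)["viral_total"]),
                   r2 = sm$r.squared,
                   p = sm$coefficients["viral_total", 4])
  }
  if (mode == "stratified") {
    data |>
      dplyr::group_by(.data$covered) |>
      dplyr::group_map(function(df, key) {
        if (nrow(df) < 3) {
          stop("need at least 3 bags per cover stratum", call. = FALSE)
        }
        fit_one(df, if (key$covered) "covered" else "uncovered",
                metric ~ viral_total)
      }) |>
      dplyr::bind_rows()
  } else {
    formula <- if (length(unique(data$covered)) > 1) {
      metric ~ viral_total + covered
    } else {
      metric ~ viral_total
    }
    fit_one(data, "pooled", formula)
  }
}
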