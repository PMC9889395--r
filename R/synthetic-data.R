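#' Define a synthetic mesocosm scenario
#'
#' Collects every parameter of the in-silico experiment: seven enclosures
#' monitored for 24 days, two bloom peaks (a mixed pico/nanophytoplankton
#' bloom followed by an E. huxleyi bloom), a viral-load gradient spanning
#' three orders of magnitude across bags, infected fractions peaking at a
#' few to 25+ percent, and the recursive production-loss parameters that
#' drive the bulk chemistry forward models. Defaults emulate the study
#' conditions; all are overridable.
#'
#' Per-cell production rates are expressed in measurement units per
#' (cell/mL) per day: for TEP, 1e-3 ug XG eq L^-1 per cell mL^-1 equals
#' 1 pg XG per cell per day; for PIC, 1e-3 umol L^-1 per cell mL^-1 equals
#' 1 pmol per cell per day.
#'
#' @param n_bags Number of enclosures (default 7).
#' @param n_days Experiment length in days (default 24; must be >= 3).
#' @param covered Logical per bag; bags 5-7 are covered by default.
#' @param viral_load_scale Per-bag multiplier of the peak viral load,
#'   spanning >= 3 orders of magnitude by default.
#' @param viral_load_max Peak biomass-associated viral load (copies/L) in
#'   the most infected bag.
#' @param bloom1_peak_day,bloom2_peak_day Peak days of the mixed bloom and
#'   the E. huxleyi bloom.
#' @param infection_fraction_max Per-bag maximum infected fraction; the
#'   moderately and strongly infected uncovered bags default to 10% and
#'   25%.
#' @param tep_params List `(a_E, a_N, a_P, d)`: per-cell TEP production and
#'   daily loss fraction.
#' @param pic_params List `(a_E, d)` for the coccolith model.
#' @param poc_params,csp_params Same shape as `tep_params`; POC defaults
#'   put ~5 pg C per host cell per day; neither responds to infection.
#' @param infection_multiplier Fold-increase of per-cell TEP and PIC
#'   production in infected cells (default 4).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise (default 0.1).
#' @param seed Integer seed; one substream is derived per variable and bag.
#' @return An object of class `mesocosm_scenario`.
#' @export
mesocosm_scenario <- function(
    n_bags = 7,
    n_days = 24,
    covered = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    viral_load_scale = c(0.05, 0.3, 0.001, 0.92, 0.001, 0.01, 1),
    viral_load_max = 1.54e10,
    bloom1_peak_day = 5,
    bloom2_peak_day = 17,
    infection_fraction_max = c(0, 0.10, 0, 0.25, 0, 0, 0.27),
    tep_params = list(a_E = 4.75e-3, a_N = 1.2e-3, a_P = 2e-4, d = 0.12),
    pic_params = list(a_E = 1.5e-3, d = 0.0075),
    poc_params = list(a_E = 5e-3, a_N = 2.5e-3, a_P = 4e-4, d = 0.1),
    csp_params = list(a_E = 3e-3, a_N = 1.5e-3, a_P = 3e-4, d = 0.15),
    infection_multiplier = 4,
    noise_cv = 0.1,
    seed = 1L) {
  covered <- rep_len(covered, n_bags)
  viral_load_scale <- rep_len(viral_load_scale, n_bags)
  infection_fraction_max <- rep_len(infection_fraction_max, n_bags)
  if (n_days < 3) stop("n_days must be >= 3", call. = FALSE)
  if (any(viral_load_scale < 0)) stop("negative viral load scale",
                                      call. = FALSE)
  if (any(infection_fraction_max < 0 | infection_fraction_max > 1)) {
    stop("infection fractions must lie in [0, 1]", call. = FALSE)
  }
  for (p in list(tep_params, pic_params, poc_params, csp_params)) {
    rates <- unlist(p[setdiff(names(p), "d")])
    if (any(rates < 0)) stop("per-cell rates must be >= 0", call. = FALSE)
    if (p$d < 0 || p$d >= 1) stop("loss fractions must lie in [0, 1)",
                                  call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  structure(list(
    n_bags = as.integer(n_bags), n_days = as.integer(n_days),
    covered = covered, viral_load_scale = viral_load_scale,
    viral_load_max = viral_load_max,
    bloom1_peak_day = bloom1_peak_day, bloom2_peak_day = bloom2_peak_day,
    infection_fraction_max = infection_fraction_max,
    tep_params = tep_params, pic_params = pic_params,
    poc_params = poc_params, csp_params = csp_params,
    infection_multiplier = infection_multiplier,
    noise_cv = noise_cv, seed = as.integer(seed)
  ), class = "mesocosm_scenario")
}

logistic <- function(z) 1 / (1 + exp(-z))

# deterministic substream seed per (seed, variable index), kept below 2^31
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %%
               2147483629)
}

apply_lognormal_noise <- function(value, cv, seed) {
  if (cv == 0) return(value)
  sdlog <- sqrt(log(1 + cv^2))
  set.seed(seed)
  value * stats::rlnorm(length(value), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# deterministic mean trajectories; bag enters only through its viral-load
# scale so that equal scales give identical series
abundance_shape <- function(variable, t, scenario, scale_norm) {
  b1 <- scenario$bloom1_peak_day
  b2 <- scenario$bloom2_peak_day
  final <- scenario$n_days - 1
  switch(variable,
    pico = 2e3 + 1.8e5 * exp(-0.5 * ((t - b1) / 2.2)^2),
    nano = 5e2 + 2.5e4 * exp(-0.5 * ((t - b1 - 1.5) / 2.8)^2),
    ehux = {
      base <- 30 + 5.7e4 * logistic((t - (b2 - 3.5)) * 0.9)
      loss <- 0.3 + 0.6 * scale_norm
      lambda <- -log(1 - loss) / max(final - b2, 1)
      decline <- ifelse(t > b2, exp(-lambda * (t - b2)), 1)
      base * decline
    },
    bacteria_fl = 5e5 * (1 + 9 * logistic((t - 9) / 1.2)) *
      (1 + (0.5 + 1.5 * scale_norm) * logistic((t - 20.5) / 0.8)),
    bacteria_2_20 = 4e4 * (1 + 7 * logistic((t - 10) / 1.5)) *
      (1 + (0.5 + 2.5 * scale_norm) * logistic((t - 20) / 0.8)),
    thraustochytrids = ifelse(
      t <= b2, 0,
      pmin(4 * exp((0.35 + 0.45 * scale_norm) * (t - b2)), 450)),
    ciliates = 1.5 * (1 + 5 * (1 - scale_norm) * logistic((t - 20) / 1.2)),
    viral_load = 1e7 + scenario$viral_load_max * scale_norm *
      logistic((t - (b2 + 1.5)) / 1.2),
    stop("unknown variable ", variable, call. = FALSE))
}

abundance_units <- c(
  pico = "cells/mL", nano = "cells/mL", ehux = "cells/mL",
  bacteria_fl = "cells/mL", bacteria_2_20 = "cells/mL",
  thraustochytrids = "cells/mL", ciliates = "cells/mL",
  viral_load = "copies/L")

# flow cytometry twice daily (morning + evening), other assays daily
twice_daily <- c("pico", "nano", "ehux", "bacteria_fl", "bacteria_2_20")

#' Generate per-bag abundance time series
#'
#' Deterministic bloom trajectories plus multiplicative lognormal noise:
#' picophytoplankton and nanophytoplankton peak in the mixed bloom, the
#' host rises logistically to its second-bloom peak and declines with a
#' demise depth that grows with the bag's viral load (up to ~90% of peak in
#' the most infected bags), bacteria expand during the first-bloom demise,
#' thraustochytrids appear only after the host peak with growth rates
#' increasing with viral load, ciliates increase late in low-virus bags,
#' and the biomass-associated viral load rises sigmoidal during demise.
#' Flow-cytometry variables are sampled twice daily (half-day offsets),
#' other assays daily.
#'
#' @param scenario A `mesocosm_scenario`.
#' @return A measurement tibble (bag, day, variable, value, unit).
#' @export
generate_abundances <- function(scenario) {
  stopifnot(inherits(scenario, "mesocosm_scenario"))
  scale_norm <- scenario$viral_load_scale /
    max(scenario$viral_load_scale, 1e-300)
  vars <- names(abundance_units)
  rows <- purrr::map_dfr(seq_len(scenario$n_bags), function(b) {
    purrr::map_dfr(seq_along(vars), function(vi) {
      v <- vars[vi]
      t <- if (v %in% twice_daily) {
        seq(0, scenario$n_days - 1, by = 0.5)
      } else {
        seq(0, scenario$n_days - 1, by = 1)
      }
      mean_val <- abundance_shape(v, t, scenario, scale_norm[b])
      value <- apply_lognormal_noise(
        mean_val, scenario$noise_cv,
        sub_seed(scenario$seed, b * 100 + vi))
      tibble::tibble(bag = b, day = t, variable = v, value = value,
                     unit = unname(abundance_units[v]))
    })
  })
  measurement_table(rows)
}

#' Generate the infected-fraction time course
#'
#' A logistic profile rising through the demise phase, rescaled so that the
#' maximum over sampled days equals each bag's `infection_fraction_max`
#' exactly. Fractions are reported noise-free (they are used as a model
#' input, not refit).
#'
#' @param scenario A `mesocosm_scenario`.
#' @return A measurement tibble with variable `infection_fraction`.
#' @export
generate_infection <- function(scenario) {
  stopifnot(inherits(scenario, "mesocosm_scenario"))
  t <- seq(0, scenario$n_days - 1, by = 1)
  raw <- logistic((t - (scenario$bloom2_peak_day + 2)) / 1.5)
  raw <- raw / max(raw)
  rows <- purrr::map_dfr(seq_len(scenario$n_bags), function(b) {
    tibble::tibble(bag = b, day = t, variable = "infection_fraction",
                   value = scenario$infection_fraction_max[b] * raw,
                   unit = "fraction")
  })
  measurement_table(rows)
}

#' Generate bulk chemistry by forward application of the carbon models
#'
#' TEP (and POC, CSP) follow the recursive production-loss model driven by
#' the three producer groups; PIC follows the positive-increment coccolith
#' model. Infected host cells produce `infection_multiplier` times the
#' per-cell TEP and PIC of bystanders, so the population-level rates of the
#' more infected bags are elevated. Multiplicative lognormal noise with the
#' scenario's CV is added on top; with `noise_cv = 0` the series are exact
#' model output and refitting recovers the generating parameters on the
#' grid.
#'
#' @param abundances Measurement tibble from [generate_abundances()].
#' @param scenario A `mesocosm_scenario`.
#' @param infection Optional measurement tibble of infected fractions;
#'   generated from the scenario when NULL.
#' @return A measurement tibble with variables TEP, PIC, POC, CSP, DOC.
#' @export
generate_bulk_chemistry <- function(abundances, scenario, infection = NULL) {
  stopifnot(inherits(scenario, "mesocosm_scenario"))
  need <- c("ehux", "nano", "pico")
  have <- unique(abundances$variable)
  if (!all(need %in% have)) {
    stop("missing producer series: ", paste(setdiff(need, have),
                                            collapse = ", "), call. = FALSE)
  }
  if (is.null(infection)) infection <- generate_infection(scenario)
  I <- scenario$infection_multiplier
  rows <- purrr::map_dfr(seq_len(scenario$n_bags), function(b) {
    prod <- abundances |>
      dplyr::filter(.data$bag == b, .data$variable %in% need,
                    .data$day %% 1 == 0) |>
      dplyr::select("day", "variable", "value") |>
      tidyr::pivot_wider(names_from = "variable", values_from = "value") |>
      dplyr::arrange(.data$day)
    f <- infection |>
      dplyr::filter(.data$bag == b) |>
      dplyr::arrange(.data$day)
    f_t <- stats::approx(f$day, f$value, xout = prod$day, rule = 2)$y
    infected_weight <- (1 - f_t) + I * f_t
    tp <- scenario$tep_params
    prod_tep <- dplyr::mutate(prod, ehux = .data$ehux * infected_weight)
    tep <- forward_tep(prod_tep,
                       c(ehux = tp$a_E, nano = tp$a_N, pico = tp$a_P),
                       tp$d)$value
    pp <- scenario$pic_params
    pic_inc <- pic_increments(prod$ehux) * infected_weight
    pic <- accumulate_pool(pp$a_E * pic_inc, pp$d, "recursion")
    oc <- scenario$poc_params
    poc <- forward_tep(prod,
                       c(ehux = oc$a_E, nano = oc$a_N, pico = oc$a_P),
                       oc$d)$value
    cs <- scenario$csp_params
    csp <- forward_tep(prod,
                       c(ehux = cs$a_E, nano = cs$a_N, pico = cs$a_P),
                       cs$d)$value
    doc <- 80 + 10 * logistic((prod$day - 8) / 1) +
      15 * logistic((prod$day - 19) / 1)
    series <- list(TEP = tep, PIC = pic, POC = poc, CSP = csp, DOC = doc)
    units <- c(TEP = "ug XG eq/L", PIC = "umol/L", POC = "ug C/L",
               CSP = "ug BSA eq/L", DOC = "umol/L")
    purrr::map_dfr(seq_along(series), function(vi) {
      v <- names(series)[vi]
      value <- apply_lognormal_noise(
        series[[v]], scenario$noise_cv,
        sub_seed(scenario$seed, 10000 + b * 100 + vi))
      tibble::tibble(bag = b, day = prod$day, variable = v, value = value,
                     unit = unname(units[v]))
    })
  })
  measurement_table(rows)
}

#' Generate a composition matrix with planted succession clusters
#'
#' Taxa are organized into Gaussian-bump relative-abundance profiles at
#' staggered center days (the planted clusters), identical across bags up
#' to multiplicative noise; the most virally loaded bag receives planted
#' over- and under-represented taxa during the demise days. Columns are
#' renormalized to sum to 1. Taxa carry taxonomy strings and trophic
#' annotations that shift from autotrophy in early clusters toward
#' (osmotrophic) heterotrophy in late clusters; a fraction of taxa is left
#' unannotated. For the 18S marker a dominant host taxon tracking the
#' per-bag E. huxleyi trajectory can be included; for 16S one
#' chloroplast-flagged taxon is planted.
#'
#' @param scenario A `mesocosm_scenario`.
#' @param marker `"18S"` or `"16S"`.
#' @param n_taxa Number of background taxa (>= 2).
#' @param n_clusters Number of planted succession clusters (default 6).
#' @param centers Optional cluster center days (default staggered across
#'   the experiment).
#' @param sd_range Range of Gaussian bump standard deviations in days.
#' @param include_host Include the host taxon (18S only).
#' @param n_differential Number of taxa planted as over-represented (x3)
#'   in the most infected bag during demise; one additional taxon is
#'   planted under-represented (x0.3).
#' @param differential_factor Fold-change of the planted taxa.
#' @return A long composition tibble with `taxon`, `taxonomy`,
#'   `trophic_mode`, `sub_mode`, `bag`, `day`, `rel_abund`, `marker`.
#' @export
generate_composition <- function(scenario, marker = c("18S", "16S"),
                                 n_taxa = 60, n_clusters = 6,
                                 centers = NULL, sd_range = c(1.4, 2.2),
                                 include_host = TRUE, n_differential = 2,
                                 differential_factor = 3) {
  marker <- match.arg(marker)
  stopifnot(inherits(scenario, "mesocosm_scenario"))
  if (n_taxa < 2) stop("need at least 2 taxa", call. = FALSE)
  final <- scenario$n_days - 1
  if (is.null(centers)) {
    centers <- seq(2, final - 1, length.out = n_clusters)
  }
  set.seed(sub_seed(scenario$seed, if (marker == "18S") 31 else 37))
  cluster_of <- sort(rep_len(seq_len(n_clusters), n_taxa))
  center_j <- centers[cluster_of] + stats::runif(n_taxa, -0.6, 0.6)
  sd_j <- stats::runif(n_taxa, sd_range[1], sd_range[2])
  amp_j <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = 0.8)
  days <- seq(0, final, by = 1)
  base <- vapply(seq_len(n_taxa), function(j) {
    amp_j[j] * exp(-0.5 * ((days - center_j[j]) / sd_j[j])^2)
  }, numeric(length(days)))           # days x taxa
  taxa <- sprintf("%s_taxon_%02d", marker, seq_len(n_taxa))
  trophic_pool <- c("autotroph", "autotroph", "mixotroph",
                    "heterotroph", "heterotroph", "heterotroph")
  sub_pool <- c(NA, NA, NA, "other", "saprotroph", "osmotroph")
  trophic <- trophic_pool[pmin(cluster_of, 6)]
  sub_mode <- sub_pool[pmin(cluster_of, 6)]
  trophic[seq(7, n_taxa, by = 7)] <- NA  # unannotated taxa exist in real data
  taxonomy <- paste0(if (marker == "18S") "Eukaryota;" else "Bacteria;",
                     "cluster", cluster_of, ";", taxa)
  scale_norm <- scenario$viral_load_scale /
    max(scenario$viral_load_scale, 1e-300)
  focal_bag <- which.max(scenario$viral_load_scale)
  demise_days <- days[days >= min(final, scenario$bloom2_peak_day + 1)]
  # planted differential taxa: the strongest late-blooming taxa
  late <- which(center_j >= scenario$bloom2_peak_day)
  late <- late[order(amp_j[late], decreasing = TRUE)]
  over_taxa <- utils::head(late, n_differential)
  under_taxon <- if (n_differential > 0 && length(late) > n_differential) {
    late[n_differential + 1]
  } else {
    integer(0)
  }
  rows <- purrr::map_dfr(seq_len(scenario$n_bags), function(b) {
    m <- base
    if (b == focal_bag) {
      # demise-associated taxa bloom in the focal bag: a sustained plateau
      # at differential_factor times their amplitude, against the ordinary
      # decaying bump elsewhere
      sel <- days %in% demise_days
      m[sel, over_taxa] <- rep(amp_j[over_taxa] * differential_factor,
                               each = sum(sel))
      if (length(under_taxon) > 0) {
        m[sel, under_taxon] <- m[sel, under_taxon] / differential_factor
      }
    }
    if (scenario$noise_cv > 0) {
      m <- apply_lognormal_noise(
        m, scenario$noise_cv,
        sub_seed(scenario$seed, 20000 + b * 50 +
                   (if (marker == "18S") 0 else 25)))
      m <- matrix(m, nrow = length(days))
    }
    out <- tibble::tibble(
      taxon = rep(taxa, each = length(days)),
      taxonomy = rep(taxonomy, each = length(days)),
      trophic_mode = rep(trophic, each = length(days)),
      sub_mode = rep(sub_mode, each = length(days)),
      bag = b, day = rep(days, n_taxa),
      rel_abund = as.numeric(m), marker = marker)
    if (marker == "18S" && include_host) {
      host <- abundance_shape("ehux", days, scenario, scale_norm[b])
      host <- host / max(host) * max(amp_j) * 3  # dominant in bloom 2
      out <- dplyr::bind_rows(out, tibble::tibble(
        taxon = "Emiliania_huxleyi",
        taxonomy = "Eukaryota;Haptophyta;Emiliania_huxleyi",
        trophic_mode = "autotroph", sub_mode = NA_character_,
        bag = b, day = days, rel_abund = host, marker = marker))
    }
    out
  })
  if (marker == "16S") {
    # organelle reads that mapping-based filters must be able to drop
    chl <- purrr::map_dfr(seq_len(scenario$n_bags), function(b) {
      prof <- 0.3 * exp(-0.5 * ((days - scenario$bloom2_peak_day) / 3)^2)
      tibble::tibble(taxon = "Chloroplast_Ehux",
                     taxonomy = "Bacteria;Cyanobacteria;Chloroplast",
                     trophic_mode = NA_character_,
                     sub_mode = NA_character_,
                     bag = b, day = days, rel_abund = prof, marker = marker)
    })
    rows <- dplyr::bind_rows(rows, chl)
  }
  normalize_composition(rows)
}

#' Generate a paired dilution experiment with known rates
#'
#' Constructs triplicate T0 and T24 bottle counts for the four treatments
#' (100% whole seawater with and without nutrients, 20% dilution in
#' filtered seawater, 20% dilution in virus-free TFF filtrate) such that
#' noise-free application of the apparent-growth, grazing and viral-lysis
#' equations returns the planted (mu, g, v) exactly: apparent rates are
#' k(wsw_nut) = mu + b - g - v, k(wsw) = mu - g - v, k(fsw) = mu + b - xg -
#' v, k(tff) = mu + b - xg - xv, with b the nutrient boost (default 0).
#'
#' @param mu Intrinsic growth rate (per day).
#' @param g Grazing rate (per day).
#' @param v Viral lysis rate (per day, default 0).
#' @param x Fraction of whole seawater in the dilutions (0 < x <= 1).
#' @param t Incubation time in days (default 1).
#' @param C0 Initial concentration (cells/mL).
#' @param nutrient_boost Extra growth under added nutrients (per day).
#' @param noise_cv Multiplicative lognormal noise CV on counts.
#' @param n_rep Replicates per treatment (default 3).
#' @param seed Integer seed.
#' @return A tibble with columns `treatment`, `replicate`, `time`, `count`.
#' @export
generate_dilution_experiment <- function(mu, g, v = 0, x = 0.2, t = 1,
                                         C0 = 1e4, nutrient_boost = 0,
                                         noise_cv = 0, n_rep = 3,
                                         seed = 1L) {
  if (x <= 0 || x > 1) stop("x must lie in (0, 1]", call. = FALSE)
  if (t <= 0) stop("incubation time must be positive", call. = FALSE)
  k <- c(wsw_nut = mu + nutrient_boost - g - v,
         wsw = mu - g - v,
         fsw = mu + nutrient_boost - x * g - v,
         tff = mu + nutrient_boost - x * g - x * v)
  grid <- tidyr::expand_grid(treatment = names(k),
                             replicate = seq_len(n_rep))
  out <- dplyr::bind_rows(
    dplyr::mutate(grid, time = 0, count = C0),
    dplyr::mutate(grid, time = t,
                  count = C0 * exp(k[.data$treatment] * t)))
  out$count <- apply_lognormal_noise(out$count, noise_cv,
                                     sub_seed(seed, 777))
  dplyr::arrange(out, .data$treatment, .data$replicate, .data$time)
}

#' Apparent growth rates per bottle from a dilution count table
#'
#' Pairs each bottle's T0 and final counts and applies
#' [apparent_growth()].
#'
#' @param counts Tibble from [generate_dilution_experiment()] (columns
#'   `treatment`, `replicate`, `time`, `count`).
#' @return A tibble with `treatment`, `replicate`, `k`.
#' @export
dilution_apparent_rates <- function(counts) {
  counts |>
    dplyr::group_by(.data$treatment, .data$replicate) |>
    dplyr::summarise(
      k = apparent_growth(.data$count[which.min(.data$time)],
                          .data$count[which.max(.data$time)],
                          t = max(.data$time) - min(.data$time)),
      .groups = "drop")
}

#' Generate a complete synthetic mesocosm experiment
#'
#' Bundles abundances, infected fractions, bulk chemistry and the 16S/18S
#' composition matrices generated from one scenario, together with a truth
#' record holding every generating parameter needed for recovery tests.
#'
#' @param scenario A `mesocosm_scenario`.
#' @return An object of class `synthetic_experiment`: list with elements
#'   `abundances`, `chemistry`, `infection`, `composition_16s`,
#'   `composition_18s`, `truth`.
#' @export
generate_experiment <- function(scenario = mesocosm_scenario()) {
  abund <- generate_abundances(scenario)
  infection <- generate_infection(scenario)
  chem <- generate_bulk_chemistry(abund, scenario, infection)
  comp18 <- generate_composition(scenario, marker = "18S")
  comp16 <- generate_composition(scenario, marker = "16S",
                                 include_host = FALSE)
  truth <- list(
    n_bags = scenario$n_bags, n_days = scenario$n_days,
    covered = scenario$covered,
    viral_load_scale = scenario$viral_load_scale,
    viral_load_max = scenario$viral_load_max,
    bloom1_peak_day = scenario$bloom1_peak_day,
    bloom2_peak_day = scenario$bloom2_peak_day,
    infection_fraction_max = scenario$infection_fraction_max,
    tep_params = scenario$tep_params,
    pic_params = scenario$pic_params,
    poc_params = scenario$poc_params,
    csp_params = scenario$csp_params,
    infection_multiplier = scenario$infection_multiplier,
    noise_cv = scenario$noise_cv, seed = scenario$seed)
  structure(list(abundances = abund, chemistry = chem,
                 infection = infection,
                 composition_16s = comp16, composition_18s = comp18,
                 truth = truth),
            class = "synthetic_experiment")
}

#' Write a synthetic experiment to a directory of tidy CSV tables
#'
#' One CSV per measurement family plus a JSON truth record.
#'
#' @param experiment A `synthetic_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_measurements(experiment$abundances, file.path(dir, "abundances.csv"))
  write_measurements(experiment$chemistry, file.path(dir, "chemistry.csv"))
  write_measurements(experiment$infection, file.path(dir, "infection.csv"))
  write_composition(experiment$composition_16s,
                    file.path(dir, "composition_16s.csv"))
  write_composition(experiment$composition_18s,
                    file.path(dir, "composition_18s.csv"))
  jsonlite::write_json(experiment$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic experiment back from a directory
#'
#' @param dir Directory written by [write_experiment()].
#' @return A `synthetic_experiment` (truth present when `truth.json`
#'   exists).
#' @export
read_experiment <- function(dir) {
  truth_path <- file.path(dir, "truth.json")
  structure(list(
    abundances = read_measurements(file.path(dir, "abundances.csv")),
    chemistry = read_measurements(file.path(dir, "chemistry.csv")),
    infection = read_measurements(file.path(dir, "infection.csv")),
    composition_16s = read_composition(file.path(dir, "composition_16s.csv")),
    composition_18s = read_composition(file.path(dir, "composition_18s.csv")),
    truth = if (file.exists(truth_path)) {
      jsonlite::read_json(truth_path, simplifyVector = TRUE)
    }
  ), class = "synthetic_experiment")
}
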