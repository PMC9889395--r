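#' Run the full analysis pipeline on a mesocosm dataset
#'
#' Orchestrates the stages in dependency order on either a
#' `synthetic_experiment` object or a directory of tables written by
#' [write_experiment()]: integrated abundances and viral-load correlations;
#' community turnover, clustering, divergence and the differential
#' screen; growth and biomass-ratio kinetics; the TEP/PIC/POC/CSP
#' production-loss fits with a shared loss fraction; the infected-cell
#' production multiplier (baseline = the least infected uncovered bags);
#' and the correlation of fitted per-cell TEP rates with viral load. A
#' failed stage for one bag is recorded as a status row and does not abort
#' the others.
#'
#' @param data_dir Directory containing the canonical tables (ignored when
#'   `experiment` is given).
#' @param experiment Optional `synthetic_experiment` object.
#' @param config An [analysis_config()].
#' @param out_dir Optional output directory; when given, one CSV per result
#'   family plus a JSON summary is written.
#' @return An object of class `pipeline_report` (a named list of result
#'   tibbles and fit objects).
#' @export
run_pipeline <- function(data_dir = NULL, experiment = NULL,
                         config = analysis_config(), out_dir = NULL) {
  if (is.null(experiment)) {
    if (is.null(data_dir)) stop("supply data_dir or experiment",
                                call. = FALSE)
    experiment <- read_experiment(data_dir)
  }
  abund <- experiment$abundances
  chem <- experiment$chemistry
  infection <- experiment$infection
  comp18 <- experiment$composition_18s
  comp16 <- experiment$composition_16s
  bags <- sort(unique(abund$bag))
  covered <- experiment$truth$covered
  if (is.null(covered)) covered <- rep(FALSE, length(bags))

  viral_total <- integrate_abundance(abund, "viral_load")
  ehux_total <- integrate_abundance(abund, "ehux")
  corr_input <- dplyr::inner_join(
    dplyr::rename(ehux_total, metric = "total"),
    dplyr::rename(viral_total, viral_total = "total"), by = "bag") |>
    dplyr::mutate(covered = covered[match(.data$bag, bags)])
  correlations <- try_stage(function() {
    dplyr::bind_rows(
      correlate_with_viral_load(corr_input, mode = "stratified"),
      correlate_with_viral_load(corr_input, mode = "pooled"))
  }, "viral-load correlation")

  turnover <- purrr::map_dfr(bags, function(b) {
    tryCatch(fit_turnover(comp18, bag = b, start_day = 0,
                          floor = config$bc_floor),
             error = function(e) tibble::tibble(bag = b, k = NA_real_))
  })
  clusters <- try_stage(function() {
    cluster_succession(filter_taxa(comp18, 0.02, 5, criterion = "max"),
                       seed = config$seed)
  }, "succession clustering")
  diverg <- try_stage(function() divergence(
    comp18, start_days = config$start_days,
    remove_taxa = "Emiliania_huxleyi"), "divergence")
  focal <- viral_total$bag[which.max(viral_total$total)]
  differential <- try_stage(function() {
    differential_abundance(
      filter_taxa(comp16, 0.10, 1, criterion = "max"), focal,
      demise_days = seq(config$phases$demise[1], config$phases$demise[2]),
      p_adjust_method = config$p_adjust_method)
  }, "differential abundance")
  traits <- try_stage(function() aggregate_traits(comp18, config$phases),
                      "trait aggregation")

  growth <- purrr::map_dfr(bags, function(b) {
    tryCatch(
      fit_growth_rate(abund, "thraustochytrids", b,
                      window = thrausto_window(abund, b)),
      error = function(e) tibble::tibble(bag = b, rate = NA_real_))
  })

  producer_vars <- c(ehux = "ehux", nano = "nano", pico = "pico")
  carbon <- lapply(c(TEP = "TEP", POC = "POC", CSP = "CSP"), function(v) {
    try_stage(function() fit_carbon_model_set(
      chem, abund, v, producer_vars, d_grid = config$d_grid), v)
  })
  carbon$PIC <- try_stage(function() fit_carbon_model_set(
    chem, abund, "PIC", producer_vars["ehux"], d_grid = config$d_grid,
    kernel = "increment"), "PIC")

  infection_fit <- try_stage(function() {
    fit_pipeline_infection(chem, abund, infection, covered, bags,
                           config)
  }, "infection multiplier")

  tep_rate_corr <- try_stage(function() {
    rates <- carbon$TEP$rates |>
      dplyr::filter(.data$producer == "ehux") |>
      dplyr::select("bag", metric = "rate")
    correlate_with_viral_load(
      dplyr::inner_join(rates,
                        dplyr::rename(viral_total, viral_total = "total"),
                        by = "bag") |>
        dplyr::mutate(covered = covered[match(.data$bag, bags)]),
      mode = "pooled")
  }, "TEP rate vs viral load")

  report <- structure(list(
    integrated = dplyr::bind_rows(
      dplyr::mutate(ehux_total, variable = "ehux"),
      dplyr::mutate(viral_total, variable = "viral_load")),
    correlations = correlations,
    turnover = turnover,
    clusters = clusters,
    divergence = diverg,
    differential = differential,
    traits = traits,
    growth = growth,
    carbon = carbon,
    infection = infection_fit,
    tep_rate_correlation = tep_rate_corr,
    config = config
  ), class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

try_stage <- function(fn, label) {
  tryCatch(fn(), error = function(e) {
    structure(list(stage = label, error = conditionMessage(e)),
              class = "stage_failure")
  })
}

thrausto_window <- function(abund, bag) {
  x <- abund |>
    dplyr::filter(.data$variable == "thraustochytrids", .data$bag == !!bag,
                  .data$value > 0)
  c(min(x$day), x$day[which.max(x$value)])
}

fit_pipeline_infection <- function(chem, abund, infection, covered, bags,
                                   config) {
  f_max <- infection |>
    dplyr::group_by(.data$bag) |>
    dplyr::summarise(f = max(.data$value), .groups = "drop")
  uncovered <- bags[!covered]
  baseline_bags <- f_max |>
    dplyr::filter(.data$bag %in% uncovered) |>
    dplyr::arrange(.data$f) |>
    dplyr::slice_head(n = 2) |>
    dplyr::pull(.data$bag)
  infected_bag <- f_max$bag[which.max(f_max$f)]
  producer_vars <- c(ehux = "ehux", nano = "nano", pico = "pico")
  base_set <- fit_carbon_model_set(
    dplyr::filter(chem, .data$bag %in% baseline_bags),
    dplyr::filter(abund, .data$bag %in% baseline_bags),
    "TEP", producer_vars, d_grid = config$d_grid)
  base_rates <- base_set$rates |>
    dplyr::group_by(.data$producer) |>
    dplyr::summarise(rate = mean(.data$rate), .groups = "drop")
  baseline_fit <- structure(list(
    kind = "production",
    rates = base_rates[match(names(producer_vars), base_rates$producer), ],
    d = base_set$d, r2 = base_set$r2, d_scan = base_set$d_scan
  ), class = "carbon_fit")
  al <- align_pool_producers(chem, abund, "TEP", producer_vars,
                             infected_bag)
  f_series <- infection |>
    dplyr::filter(.data$bag == infected_bag) |>
    dplyr::select("day", "value")
  fit_infection_multiplier(
    al[c("day", "value")], al[c("day", names(producer_vars))], f_series,
    baseline_fit, i_grid = config$i_grid)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  put <- function(x, name) {
    if (inherits(x, "stage_failure") || is.null(x)) return(invisible())
    readr::write_csv(x, file.path(out_dir, paste0(name, ".csv")))
  }
  put(report$integrated, "integrated_abundance")
  put(report$correlations, "viral_correlations")
  put(report$turnover, "turnover")
  put(report$divergence, "divergence")
  put(report$differential, "differential_abundance")
  put(report$traits, "trait_shares")
  put(report$growth, "growth_rates")
  if (!inherits(report$clusters, "stage_failure")) {
    put(report$clusters$labels, "cluster_labels")
  }
  for (v in names(report$carbon)) {
    fit <- report$carbon[[v]]
    if (!inherits(fit, "stage_failure")) {
      put(dplyr::mutate(fit$rates, d = fit$d), paste0("carbon_", tolower(v)))
    }
  }
  summary <- list(
    d = purrr::map(report$carbon, function(f) {
      if (inherits(f, "stage_failure")) NULL else f$d
    }),
    infection_multiplier = if (!inherits(report$infection,
                                         "stage_failure")) {
      report$infection$I
    },
    n_clusters = if (!inherits(report$clusters, "stage_failure")) {
      report$clusters$n_clusters
    },
    seed = report$config$seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Mesocosm analysis pipeline report\n")
  for (v in names(x$carbon)) {
    f <- x$carbon[[v]]
    if (!inherits(f, "stage_failure")) {
      cat(sprintf("  %s: shared d = %.4f, pooled R^2 = %.4f\n", v, f$d,
                  f$r2))
    }
  }
  if (!inherits(x$infection, "stage_failure")) {
    cat(sprintf("  infected-cell production multiplier I = %.2f\n",
                x$infection$I))
  }
  if (!inherits(x$clusters, "stage_failure")) {
    cat(sprintf("  succession clusters: %d\n", x$clusters$n_clusters))
  }
  invisible(x)
}
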