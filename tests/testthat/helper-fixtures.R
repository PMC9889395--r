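# Shared fixtures: tiny scenarios and hand-built tables used across tests.

quiet_scenario <- function(...) {
  mesocosm_scenario(noise_cv = 0, seed = 1, ...)
}

# three-bag design used for the infected-subpopulation analyses: two
# uninfected baseline bags plus one bag whose infected fraction rises to
# f_max during demise
infection_scenario <- function(f_max = 0.25, I = 4, noise_cv = 0,
                               seed = 1) {
  mesocosm_scenario(
    n_bags = 3, covered = c(FALSE, FALSE, FALSE),
    viral_load_scale = c(0.001, 0.001, 1),
    infection_fraction_max = c(0, 0, f_max),
    infection_multiplier = I, noise_cv = noise_cv, seed = seed)
}

producer_vars <- c(ehux = "ehux", nano = "nano", pico = "pico")

# pull a bag's daily producer table from an abundance table
daily_producers <- function(abund, bag) {
  abund |>
    dplyr::filter(.data$bag == !!bag, .data$variable %in% producer_vars,
                  .data$day %% 1 == 0) |>
    dplyr::select("day", "variable", "value") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value") |>
    dplyr::arrange(.data$day) |>
    dplyr::rename(E = "ehux", N = "nano", P = "pico")
}

# a two-taxon composition whose Bray-Curtis similarity to its day-0 sample
# follows the exponential decay model exactly
exact_turnover_composition <- function(k, floor = 0.05, days = 0:15,
                                       bag = 1) {
  p0 <- 0.96
  bc <- (1 - floor) * exp(-k * days) + floor
  p <- p0 - (1 - bc)
  tibble::tibble(
    taxon = rep(c("A", "B"), each = length(days)),
    bag = bag, day = rep(days, 2),
    rel_abund = c(p, 1 - p))
}

# community in which a fraction `rate` of the standing mass moves onto a
# fresh day-specific taxon every day; higher replacement must fit a higher
# turnover rate
replacement_composition <- function(rate, n_days = 12, n_taxa = 20,
                                    seed = 42, bag = 1) {
  set.seed(seed)
  taxa <- c(paste0("t", seq_len(n_taxa)), paste0("new", seq_len(n_days)))
  state <- c(stats::runif(n_taxa), rep(0, n_days))
  state <- state / sum(state)
  rows <- vector("list", n_days + 1)
  rows[[1]] <- tibble::tibble(taxon = taxa, bag = bag, day = 0,
                              rel_abund = state)
  for (d in seq_len(n_days)) {
    state <- state * (1 - rate)
    state[n_taxa + d] <- rate
    rows[[d + 1]] <- tibble::tibble(taxon = taxa, bag = bag, day = d,
                                    rel_abund = state)
  }
  dplyr::bind_rows(rows)
}
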