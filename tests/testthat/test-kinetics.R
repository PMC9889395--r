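test_that("integrated abundance uses only days common to all bags", {
  single <- measurement_table(tibble::tibble(
    bag = 1, day = 0:2, variable = "x", value = c(1, 2, 3)))
  expect_equal(integrate_abundance(single, "x")$total, 6)

  two <- measurement_table(tibble::tibble(
    bag = c(1, 1, 1, 2, 2), day = c(0, 1, 5, 0, 1), variable = "x",
    value = c(1, 2, 100, 3, 4)))
  out <- integrate_abundance(two, "x")
  expect_equal(out$total, c(3, 7))  # day 5 excluded for both

  # brute-force oracle on a random sparse table
  set.seed(21)
  tab <- tidyr::expand_grid(bag = 1:4, day = 0:9) |>
    dplyr::slice_sample(prop = 0.8) |>
    dplyr::mutate(variable = "y", value = stats::runif(dplyr::n()))
  mt <- measurement_table(tab)
  got <- integrate_abundance(mt, "y")
  common <- Reduce(intersect, split(tab$day, tab$bag))
  brute <- tab |>
    dplyr::filter(day %in% common) |>
    dplyr::group_by(bag) |>
    dplyr::summarise(total = sum(value))
  expect_equal(got$total, brute$total, tolerance = 1e-12)
})

test_that("growth rates equal the OLS slope of log abundance", {
  days <- seq(0, 10, by = 0.5)
  exact <- measurement_table(tibble::tibble(
    bag = 1, day = days, variable = "x", value = exp(0.5 * days)))
  gr <- fit_growth_rate(exact, "x", 1, window = c(2, 8))
  expect_equal(gr$rate, 0.5, tolerance = 1e-12)
  expect_equal(gr$rate_sd, 0, tolerance = 1e-12)
  expect_equal(gr$n_fits, 3)

  flat <- measurement_table(tibble::tibble(
    bag = 1, day = days, variable = "x", value = 3))
  expect_equal(fit_growth_rate(flat, "x", 1, c(2, 8))$rate, 0)

  set.seed(5)
  noisy_vals <- exp(0.3 * days + stats::rnorm(length(days), 0, 0.2))
  noisy <- measurement_table(tibble::tibble(
    bag = 1, day = days, variable = "x", value = noisy_vals))
  got <- fit_growth_rate(noisy, "x", 1, c(0, 10), shifts = 0)$rate
  ols <- unname(stats::coef(stats::lm(log(noisy_vals) ~ days))[2])
  expect_equal(got, ols, tolerance = 1e-12)
})

test_that("biomass conversion applies the per-group carbon factors linearly", {
  counts <- tibble::tibble(bag = 1, day = 1:3, value = c(0, 400, 800))
  thr <- biomass_from_counts(counts, "thraustochytrid")
  expect_equal(thr$biomass_g_c_ml, c(0, 6.6e-8, 1.32e-7), tolerance = 1e-12)
  bac <- biomass_from_counts(dplyr::mutate(counts, value = 1e6), "bacteria")
  expect_equal(bac$biomass_g_c_ml, rep(1e-8, 3), tolerance = 1e-12)
  scaled <- biomass_from_counts(dplyr::mutate(counts, value = value * 7),
                                "thraustochytrid")
  expect_equal(scaled$biomass_g_c_ml, 7 * thr$biomass_g_c_ml)
  expect_error(biomass_from_counts(counts, "archaea"), "explicit factor")
})

test_that("biomass ratio rate equals the growth-rate difference for exact exponentials", {
  days <- 10:20
  thr <- tibble::tibble(day = days, biomass_g_c_ml = exp(0.3 * days))
  bac <- tibble::tibble(day = days, biomass_g_c_ml = exp(0.1 * days))
  k <- fit_biomass_ratio_rate(thr, bac)
  expect_equal(k$rate, 0.2, tolerance = 1e-12)
  # invariant to common rescaling
  k2 <- fit_biomass_ratio_rate(
    dplyr::mutate(thr, biomass_g_c_ml = biomass_g_c_ml * 1e6),
    dplyr::mutate(bac, biomass_g_c_ml = biomass_g_c_ml * 1e6))
  expect_equal(k2$rate, k$rate, tolerance = 1e-12)
  # equal growth: flat ratio
  k0 <- fit_biomass_ratio_rate(thr, thr)
  expect_equal(k0$rate, 0, tolerance = 1e-12)
})

test_that("viral-load correlations behave in stratified and pooled modes", {
  df <- tibble::tibble(
    viral_total = c(1, 2, 3, 4, 5, 6, 7),
    covered = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    metric = 2 * viral_total + 1)
  strat <- suppressWarnings(correlate_with_viral_load(df,
                                                      mode = "stratified"))
  expect_equal(strat$r2, c(1, 1), tolerance = 1e-12)
  pooled <- suppressWarnings(correlate_with_viral_load(df, mode = "pooled"))
  expect_equal(pooled$slope, strat$slope[1], tolerance = 1e-9)

  # independence null: p roughly uniform over permutations
  set.seed(9)
  ps <- replicate(200, {
    d <- tibble::tibble(viral_total = 1:8, covered = FALSE,
                        metric = sample(stats::rnorm(8)))
    correlate_with_viral_load(d, mode = "pooled")$p
  })
  expect_gt(mean(ps < 0.1), 0.02)
  expect_lt(mean(ps < 0.1), 0.25)
  expect_error(
    correlate_with_viral_load(tibble::tibble(viral_total = rep(1, 4),
                                             covered = FALSE,
                                             metric = 1:4)),
    "variance")
})
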