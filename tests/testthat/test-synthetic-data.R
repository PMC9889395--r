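test_that("scenario validation enforces the documented invariants", {
  expect_error(mesocosm_scenario(n_days = 2), "n_days")
  expect_error(mesocosm_scenario(viral_load_scale = c(-1, rep(1, 6))),
               "negative")
  expect_error(mesocosm_scenario(infection_fraction_max = rep(2, 7)),
               "0, 1")
  expect_error(mesocosm_scenario(tep_params = list(a_E = 1e-3, a_N = 0,
                                                   a_P = 0, d = 1)),
               "0, 1")
})

test_that("equal viral loads give identical noise-free series across bags", {
  sc <- mesocosm_scenario(noise_cv = 0, seed = 1,
                          viral_load_scale = rep(0.5, 7))
  ab <- generate_abundances(sc)
  wide <- ab |>
    tidyr::pivot_wider(names_from = "bag", values_from = "value")
  for (b in 2:7) {
    expect_equal(wide[[as.character(b)]], wide[["1"]], tolerance = 1e-12)
  }
})

test_that("generated dynamics carry the study's qualitative structure", {
  sc <- quiet_scenario()
  ab <- generate_abundances(sc)
  # two blooms: pico peaks near the first peak day, host near the second
  pico1 <- ab |> dplyr::filter(variable == "pico", bag == 1)
  expect_lt(abs(pico1$day[which.max(pico1$value)] - sc$bloom1_peak_day), 1.1)
  ehux1 <- ab |> dplyr::filter(variable == "ehux", bag == 1)
  expect_lt(abs(ehux1$day[which.max(ehux1$value)] - sc$bloom2_peak_day), 1.1)

  # demise depth grows with viral load, reaching ~90% in the hottest bag
  depth <- vapply(c(3, 7), function(b) {
    e <- ab |> dplyr::filter(variable == "ehux", bag == b)
    1 - min(e$value[e$day > sc$bloom2_peak_day]) / max(e$value)
  }, numeric(1))
  expect_gt(depth[2], depth[1])
  expect_gt(depth[2], 0.85)

  # thraustochytrids appear only after the host peak
  thr <- ab |> dplyr::filter(variable == "thraustochytrids", bag == 7)
  expect_true(all(thr$value[thr$day <= sc$bloom2_peak_day] == 0))
  expect_gt(max(thr$value), 100)

  # integrated viral load anticorrelates with integrated host abundance
  vtot <- integrate_abundance(ab, "viral_load")$total
  etot <- integrate_abundance(ab, "ehux")$total
  expect_lt(stats::cor(vtot, etot, method = "spearman"), 0)

  # deterministic given the seed, also with noise
  scn <- mesocosm_scenario(noise_cv = 0.1, seed = 33)
  expect_identical(generate_abundances(scn), generate_abundances(scn))
})

test_that("infected fractions peak exactly at the configured maxima", {
  sc <- quiet_scenario()
  inf <- generate_infection(sc)
  peaks <- inf |>
    dplyr::group_by(bag) |>
    dplyr::summarise(peak = max(value))
  expect_equal(peaks$peak[peaks$bag == 2], 0.10)
  expect_equal(peaks$peak[peaks$bag == 4], 0.25)
  expect_true(all(inf$value >= 0 & inf$value <= 1))
})

test_that("bulk chemistry is the exact forward model when noise is off", {
  sc <- quiet_scenario(n_bags = 2, infection_multiplier = 1)
  ab <- generate_abundances(sc)
  ch <- generate_bulk_chemistry(ab, sc)
  prod <- daily_producers(ab, 1)
  tp <- sc$tep_params
  expected <- forward_tep(prod, c(E = tp$a_E, N = tp$a_N, P = tp$a_P),
                          tp$d)$value
  got <- ch |> dplyr::filter(bag == 1, variable == "TEP") |>
    dplyr::arrange(day) |> dplyr::pull(value)
  expect_equal(got, expected, tolerance = 1e-12)

  # single constant producer, no loss: linear accumulation
  flat <- tibble::tibble(day = 0:5, E = 100, N = 0, P = 0)
  lin <- forward_tep(flat, c(E = 1, N = 0, P = 0), 0)$value
  expect_equal(lin, 100 * (1:6))

  # PIC never decreases when d = 0
  sc0 <- quiet_scenario(n_bags = 1,
                        pic_params = list(a_E = 1.5e-3, d = 0))
  ch0 <- generate_bulk_chemistry(generate_abundances(sc0), sc0)
  pic <- ch0 |> dplyr::filter(variable == "PIC") |> dplyr::arrange(day)
  expect_true(all(diff(pic$value) >= -1e-12))

  expect_error(
    generate_bulk_chemistry(dplyr::filter(ab, variable != "pico"), sc),
    "missing producer")
})

test_that("composition columns are simplexes with planted, recoverable structure", {
  sc <- quiet_scenario()
  comp <- generate_composition(sc, marker = "18S")
  sums <- comp |>
    dplyr::group_by(bag, day) |>
    dplyr::summarise(s = sum(rel_abund), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_true(all(comp$rel_abund >= 0))
  expect_true("Emiliania_huxleyi" %in% comp$taxon)
  expect_error(generate_composition(sc, n_taxa = 1), "2 taxa")

  # the 16S table carries a chloroplast-flagged row
  comp16 <- generate_composition(sc, marker = "16S", include_host = FALSE)
  expect_true(any(grepl("Chloroplast", comp16$taxonomy)))
})

test_that("dilution generator inverts exactly for random rate draws", {
  set.seed(17)
  for (i in 1:8) {
    mu <- stats::runif(1, 0.1, 1)
    g <- stats::runif(1, 0.05, 0.6)
    v <- stats::runif(1, 0.05, 0.4)
    x <- stats::runif(1, 0.1, 0.5)
    counts <- generate_dilution_experiment(mu, g, v, x, seed = i)
    dr <- dilution_rates(dilution_apparent_rates(counts), x = x)
    expect_equal(dr$g, g, tolerance = 1e-10)
    expect_equal(dr$v, v, tolerance = 1e-10)
    expect_equal(dr$mu, mu, tolerance = 1e-10)
  }
  # no mortality: all treatments share the intrinsic rate
  c0 <- generate_dilution_experiment(mu = 0.5, g = 0, v = 0, x = 0.2)
  r0 <- dilution_apparent_rates(c0)
  expect_true(all(abs(r0$k - 0.5) < 1e-12))
})

test_that("experiments round-trip through a directory of text tables", {
  sc <- quiet_scenario(n_bags = 3)
  ex <- generate_experiment(sc)
  dir <- withr::local_tempdir()
  write_experiment(ex, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_experiment(dir)
  expect_equal(back$abundances$value, ex$abundances$value,
               tolerance = 1e-10)
  expect_equal(back$truth$tep_params$d, ex$truth$tep_params$d)
  comp_sums <- back$composition_18s |>
    dplyr::group_by(bag, day) |>
    dplyr::summarise(s = sum(rel_abund), .groups = "drop")
  expect_true(all(abs(comp_sums$s - 1) < 1e-9))
})
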