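test_that("TEP recursion reproduces hand-evaluated geometric series", {
  prod <- tibble::tibble(day = 0:3, E = 10, N = 0, P = 0)
  rates <- c(E = 1, N = 0, P = 0)
  expect_equal(forward_tep(prod, rates, d = 0)$value, c(10, 20, 30, 40))
  expect_equal(forward_tep(prod, rates, d = 0.5)$value,
               c(10, 15, 17.5, 18.75))
  expect_error(forward_tep(prod, rates, d = 1), "0, 1")
  expect_error(forward_tep(prod, c(E = -1, N = 0, P = 0), d = 0), ">= 0")
})

test_that("recursion and closed form agree to 1e-10 relative for both kernels", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(5:30, 1)
    prod <- tibble::tibble(day = seq_len(n) - 1,
                           E = stats::runif(n, 0, 1e5),
                           N = stats::runif(n, 0, 1e4),
                           P = stats::runif(n, 0, 1e5))
    rates <- c(E = stats::runif(1, 0, 0.01), N = stats::runif(1, 0, 0.01),
               P = stats::runif(1, 0, 0.01))
    d <- stats::runif(1, 0, 0.99)
    rec <- forward_tep(prod, rates, d, method = "recursion")$value
    clo <- forward_tep(prod, rates, d, method = "closed")$value
    expect_lt(max(abs(rec - clo) / pmax(abs(clo), 1e-12)), 1e-10)

    e <- stats::runif(n, 0, 1e5)
    a_E <- stats::runif(1, 0, 0.01)
    prec <- forward_pic(e, a_E = a_E, d = d, method = "recursion")$value
    pclo <- forward_pic(e, a_E = a_E, d = d, method = "closed")$value
    expect_lt(max(abs(prec - pclo) / pmax(abs(pclo), 1e-12)), 1e-10)
  }
})

test_that("PIC kernel only responds to net host increases", {
  dec <- forward_pic(c(100, 80, 60, 40), a_E = 1, d = 0)$value
  expect_equal(dec, rep(100, 4))
  inc <- forward_pic(c(100, 200, 300, 400), a_E = 1, d = 0)$value
  expect_equal(diff(inc), rep(100, 3))
  # non-decreasing whenever d = 0
  set.seed(4)
  e <- stats::runif(20, 0, 1e4)
  expect_true(all(diff(forward_pic(e, 0.3, 0)$value) >= 0))
})

test_that("constrained fit exactly recovers on-grid generating parameters", {
  sc <- quiet_scenario(n_bags = 2)
  ab <- generate_abundances(sc)
  prod <- daily_producers(ab, 1)
  truth <- c(E = 4.75e-3, N = 1.2e-3, P = 2e-4)
  obs <- forward_tep(prod, truth, d = 0.12)
  fit <- fit_production_model(obs, prod)
  expect_equal(fit$d, 0.12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(stats::setNames(fit$rates$rate, fit$rates$producer),
               truth[fit$rates$producer], tolerance = 1e-9)

  pobs <- forward_pic(dplyr::rename(prod, E = "E")[c("day", "E")],
                      a_E = 1.5e-3, d = 0.0075)
  pfit <- fit_pic_model(pobs, prod[c("day", "E")])
  expect_equal(pfit$d, 0.0075)
  expect_equal(pfit$rates$rate, 1.5e-3, tolerance = 1e-9)
})

test_that("fitted rates are never negative and zero observations flag R2", {
  sc <- quiet_scenario(n_bags = 1)
  prod <- daily_producers(generate_abundances(sc), 1)
  fit0 <- fit_production_model(rep(0, nrow(prod)), prod)
  expect_true(all(fit0$rates$rate == 0))
  expect_true(is.na(fit0$r2))

  set.seed(8)
  noisy <- forward_tep(prod, c(E = 1e-3, N = 1e-3, P = 1e-4), 0.2)$value *
    exp(stats::rnorm(nrow(prod), 0, 0.5))
  fitn <- fit_production_model(noisy, prod)
  expect_true(all(fitn$rates$rate >= 0))
  expect_true(all(fitn$fitted >= 0))
})

test_that("contribution shares are conserved and respect symmetry", {
  # equal rates and equal abundances split the pool evenly
  prod <- tibble::tibble(day = 0:9, E = 50, N = 50)
  fit <- structure(list(
    kind = "production",
    rates = tibble::tibble(producer = c("E", "N"), rate = c(1, 1)),
    d = 0.1, producers = prod), class = "carbon_fit")
  sh <- contribution_shares(fit)
  expect_equal(sum(sh$share), 1, tolerance = 1e-12)
  expect_equal(sh$share, c(0.5, 0.5), tolerance = 1e-12)

  # a single active producer owns the whole pool
  prod2 <- tibble::tibble(day = 0:9, E = 30 + (0:9), N = 5, P = 0)
  single <- fit_production_model(
    forward_tep(prod2, c(E = 1, N = 0, P = 0), d = 0.1),
    prod2, d_grid = c(0.1))
  sh1 <- contribution_shares(single)
  expect_equal(sh1$share[sh1$producer == "E"], 1, tolerance = 1e-9)

  # conservation on random fitted models
  set.seed(3)
  for (i in 1:10) {
    pr <- tibble::tibble(day = 0:14, E = stats::runif(15, 0, 1e4),
                         N = stats::runif(15, 0, 1e4),
                         P = stats::runif(15, 0, 1e4))
    obs <- forward_tep(pr, c(E = 0.3, N = 0.2, P = 0.1),
                       d = 0.2)$value * exp(stats::rnorm(15, 0, 0.1))
    f <- fit_production_model(obs, pr, d_grid = seq(0.1, 0.3, 0.05))
    expect_equal(sum(contribution_shares(f)$share), 1, tolerance = 1e-12)
  }

  expect_error(contribution_shares(fit, day_range = c(100, 200)), "zero")
})

test_that("the joint multi-bag scan recovers a shared loss fraction", {
  sc <- quiet_scenario(infection_multiplier = 1)
  ab <- generate_abundances(sc)
  ch <- generate_bulk_chemistry(ab, sc)
  fit <- fit_carbon_model_set(ch, ab, "TEP", producer_vars)
  expect_equal(fit$d, sc$tep_params$d)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_true(all(abs(fit$rates$rate[fit$rates$producer == "ehux"] -
                        sc$tep_params$a_E) < 1e-9))
})

test_that("infected-subpopulation model reduces to baseline at I = 1 and recovers a planted multiplier", {
  sc <- infection_scenario(f_max = 0.25, I = 2)
  ab <- generate_abundances(sc)
  inf <- generate_infection(sc)
  ch <- generate_bulk_chemistry(ab, sc, inf)
  bl <- fit_carbon_model_set(
    dplyr::filter(ch, bag %in% 1:2), dplyr::filter(ab, bag %in% 1:2),
    "TEP", producer_vars)
  base_fit <- structure(list(
    kind = "production",
    rates = tibble::tibble(
      producer = names(producer_vars),
      rate = vapply(names(producer_vars), function(p) {
        mean(bl$rates$rate[bl$rates$producer == p])
      }, numeric(1))),
    d = bl$d, r2 = bl$r2), class = "carbon_fit")
  al <- bloomcarbon:::align_pool_producers(ch, ab, "TEP", producer_vars, 3)
  f3 <- dplyr::filter(inf, bag == 3)[c("day", "value")]
  im <- fit_infection_multiplier(al[c("day", "value")],
                                 al[c("day", names(producer_vars))],
                                 f3, base_fit)
  expect_equal(im$I, 2)
  expect_equal(im$deviation, 0, tolerance = 1e-12)

  # with I = 1 the two-subpopulation prediction is the baseline prediction
  pred_base <- forward_tep(
    al[c("day", names(producer_vars))],
    stats::setNames(base_fit$rates$rate, base_fit$rates$producer),
    base_fit$d)$value
  im1 <- fit_infection_multiplier(pred_base,
                                  al[c("day", names(producer_vars))],
                                  f3, base_fit, i_grid = seq(0, 3, 0.5))
  expect_equal(im1$I, 1)

  expect_error(
    fit_infection_multiplier(al[c("day", "value")],
                             al[c("day", names(producer_vars))],
                             rep(0, nrow(al)), base_fit),
    "unidentifiable")
})
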