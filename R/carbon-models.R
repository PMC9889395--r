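#' Forward-simulate the recursive TEP production-loss model
#'
#' The exopolymer pool grows by per-cell secretion from its phytoplankton
#' producers and loses a fixed fraction d per day to degradation and sinking:
#' TEP(t) = (1-d) TEP(t-1) + sum_i a_i X_i(t), with the pool at the first
#' time point given by that day's production alone. The recursion has the
#' closed form TEP(t) = sum_{t' <= t} (1-d)^(t-t') sum_i a_i X_i(t'); both
#' routes are implemented and agree to floating-point accuracy, which the
#' test suite uses as its primary correctness oracle.
#'
#' @param producers A data frame with a `day` column and one abundance column
#'   (cells/mL) per producer group (e.g. `E`, `N`, `P`).
#' @param rates Named non-negative per-cell production rates, one per
#'   producer column (measurement units per cell per day).
#' @param d Daily loss fraction in [0, 1).
#' @param method `"recursion"` or `"closed"`; both give the same series.
#' @return A tibble with columns `day` and `value`.
#' @export
forward_tep <- function(producers, rates, d, method = c("recursion", "closed")) {
  method <- match.arg(method)
  check_loss(d)
  if (any(rates < 0)) stop("production rates must be >= 0", call. = FALSE)
  groups <- names(rates)
  missing_gr <- setdiff(groups, names(producers))
  if (length(missing_gr) > 0) {
    stop("producer series missing: ", paste(missing_gr, collapse = ", "),
         call. = FALSE)
  }
  prod_in <- as.matrix(producers[groups]) %*% rates
  tibble::tibble(day = producers$day,
                 value = accumulate_pool(as.numeric(prod_in), d, method))
}

#' Forward-simulate the recursive PIC coccolith model
#'
#' Measured particulate inorganic carbon only increases when new E. huxleyi
#' cells (each carrying fresh coccoliths) appear: PIC(t) = (1-d) PIC(t-1) +
#' a_E max(E(t) - E(t-1), 0). Net declines in host abundance add nothing;
#' the positive part is the only reading consistent with production via new
#' coccoliths. The first time point contributes a_E max(E(0), 0).
#'
#' @param E E. huxleyi abundance series: a data frame with `day` and `E`
#'   columns, or a numeric vector.
#' @param a_E PIC produced per newly appeared cell (>= 0).
#' @param d Daily loss fraction in [0, 1).
#' @param method `"recursion"` or `"closed"`.
#' @return A tibble with columns `day` and `value`.
#' @export
forward_pic <- function(E, a_E, d, method = c("recursion", "closed")) {
  method <- match.arg(method)
  check_loss(d)
  if (a_E < 0) stop("production rates must be >= 0", call. = FALSE)
  if (is.data.frame(E)) {
    day <- E$day
    e <- E$E
  } else {
    e <- as.numeric(E)
    day <- seq_along(e) - 1
  }
  inc <- a_E * pic_increments(e)
  tibble::tibble(day = day, value = accumulate_pool(inc, d, method))
}

pic_increments <- function(e) {
  c(max(e[1], 0), pmax(diff(e), 0))
}

accumulate_pool <- function(inc, d, method) {
  n <- length(inc)
  if (method == "recursion") {
    out <- numeric(n)
    prev <- 0
    for (t in seq_len(n)) {
      out[t] <- (1 - d) * prev + inc[t]
      prev <- out[t]
    }
    out
  } else {
    vapply(seq_len(n), function(t) {
      sum((1 - d)^(t - seq_len(t)) * inc[seq_len(t)])
    }, numeric(1))
  }
}

check_loss <- function(d) {
  if (!is.numeric(d) || length(d) != 1 || d < 0 || d >= 1) {
    stop("loss fraction d must lie in [0, 1)", call. = FALSE)
  }
}

# Discounted production kernel for one producer: K(t) = sum_{t'<=t}
# (1-d)^(t-t') x(t'). Evaluated by the O(n) recursion.
discount_kernel <- function(x, d) {
  accumulate_pool(x, d, "recursion")
}

#' Fit the constrained production-loss model by a loss-rate scan
#'
#' For each candidate loss fraction d the observed series is regressed,
#' without intercept, on the d-discounted producer kernels under the
#' constraint that every per-cell rate a_i is non-negative (Lawson-Hanson
#' active-set non-negative least squares). The d maximizing R-squared (about
#' the observed mean) is selected; ties break toward smaller d. With the PIC
#' kernel the single producer column is the positive-increment series of the
#' host.
#'
#' @param observed Observed pool series: data frame with `day` and `value`,
#'   or numeric vector aligned with `producers`.
#' @param producers Data frame with `day` plus one abundance column per
#'   producer.
#' @param d_grid Increasing vector of candidate loss fractions in [0, 1).
#' @param kernel `"production"` (same-day abundances drive production, as
#'   for TEP/POC/CSP) or `"increment"` (only positive host increments
#'   produce, as for PIC; uses the first producer column).
#' @return An object of class `carbon_fit`: per-producer rates, selected
#'   `d`, `r2`, the full `d_scan`, fitted values and residuals.
#' @export
fit_production_model <- function(observed, producers,
                                 d_grid = seq(0, 0.5, by = 0.0025),
                                 kernel = c("production", "increment")) {
  kernel <- match.arg(kernel)
  if (length(d_grid) == 0) stop("empty d grid", call. = FALSE)
  y <- if (is.data.frame(observed)) observed$value else as.numeric(observed)
  groups <- setdiff(names(producers), "day")
  if (kernel == "increment") groups <- groups[1]
  X <- as.matrix(producers[groups])
  if (kernel == "increment") {
    X <- matrix(pic_increments(X[, 1]), ncol = 1,
                dimnames = list(NULL, groups))
  }
  if (all(X == 0)) stop("all producer series are zero", call. = FALSE)
  if (length(y) < length(groups) + 1) {
    stop("need at least one more observation day than producers",
         call. = FALSE)
  }
  scan <- scan_loss_grid(list(list(y = y, X = X)), d_grid)
  best <- scan$best
  a <- unname(best$coef[[1]])
  fitted <- as.numeric(kernel_matrix(X, best$d) %*% a)
  structure(list(
    kind = kernel,
    rates = tibble::tibble(producer = groups, rate = a),
    d = best$d,
    r2 = best$r2,
    d_grid = d_grid,
    d_scan = scan$table,
    observed = tibble::tibble(day = producers$day, value = y),
    fitted = fitted,
    residuals = y - fitted,
    producers = producers[c("day", groups)]
  ), class = "carbon_fit")
}

kernel_matrix <- function(X, d) {
  apply(X, 2, discount_kernel, d = d)
}

# non-negative least squares with all-zero regressor columns pinned to 0
# (a producer absent from an enclosure must not break the active-set solve)
nnls_coef <- function(K, y) {
  nonzero <- apply(abs(K), 2, max) > 0
  a <- numeric(ncol(K))
  if (any(nonzero)) {
    a[nonzero] <- pracma::lsqnonneg(K[, nonzero, drop = FALSE], y)$x
  }
  a
}

# Shared d-scan over one or more (y, X) blocks. Each block gets its own
# non-negative coefficients; R^2 pools residual and total sums of squares
# across blocks, each centered on its own observed mean.
scan_loss_grid <- function(blocks, d_grid) {
  ss_tot <- sum(vapply(blocks, function(b) sum((b$y - mean(b$y))^2),
                       numeric(1)))
  rows <- lapply(d_grid, function(d) {
    coefs <- vector("list", length(blocks))
    ss_res <- 0
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      K <- kernel_matrix(b$X, d)
      a <- nnls_coef(K, b$y)
      names(a) <- colnames(b$X)
      coefs[[i]] <- a
      ss_res <- ss_res + sum((b$y - as.numeric(K %*% a))^2)
    }
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
    list(d = d, r2 = r2, ss_res = ss_res, coef = coefs)
  })
  tab <- tibble::tibble(d = vapply(rows, `[[`, numeric(1), "d"),
                        r2 = vapply(rows, `[[`, numeric(1), "r2"),
                        ss_res = vapply(rows, `[[`, numeric(1), "ss_res"))
  # maximize r2 == minimize ss_res; which.min takes the first (smallest d)
  # among exact ties, the stated tie-break
  best <- rows[[which.min(tab$ss_res)]]
  best$r2 <- if (all(is.na(tab$r2))) NA_real_ else best$r2
  list(table = tab, best = best)
}

#' Fit the PIC coccolith model
#'
#' Convenience wrapper around [fit_production_model()] with the
#' positive-increment kernel and the host as single producer.
#'
#' @param observed Observed PIC series (data frame with `day`, `value`, or
#'   numeric vector).
#' @param E Host abundance: data frame with `day` and `E`, or numeric vector.
#' @param d_grid Candidate loss fractions.
#' @return A `carbon_fit` object.
#' @export
fit_pic_model <- function(observed, E, d_grid = seq(0, 0.5, by = 0.0025)) {
  if (!is.data.frame(E)) {
    E <- tibble::tibble(day = seq_along(E) - 1, E = as.numeric(E))
  }
  fit_production_model(observed, E, d_grid, kernel = "increment")
}

#' Fit the production-loss model across bags with a shared loss fraction
#'
#' Per-cell rates are free per bag (the population-level rate differs across
#' enclosures) while a single loss fraction d is scanned jointly: for each
#' candidate d every bag gets its own non-negative fit, and the pooled
#' R-squared selects d.
#'
#' @param chem Measurement tibble of the observed pool (one `variable`).
#' @param abund Measurement tibble holding the producer variables.
#' @param pool_variable Name of the pool variable in `chem`.
#' @param producer_vars Named character vector mapping producer short names
#'   to `abund` variable names, e.g.
#'   `c(E = "ehux", N = "nano", P = "pico")`.
#' @param d_grid Candidate loss fractions.
#' @param kernel As in [fit_production_model()].
#' @return An object of class `carbon_fit_set`: tibble of per-bag rates and
#'   R-squared, the shared `d`, and the joint `d_scan`.
#' @export
fit_carbon_model_set <- function(chem, abund, pool_variable, producer_vars,
                                 d_grid = seq(0, 0.5, by = 0.0025),
                                 kernel = c("production", "increment")) {
  kernel <- match.arg(kernel)
  bags <- sort(unique(chem$bag[chem$variable == pool_variable]))
  if (length(bags) == 0) stop("no observations of ", pool_variable,
                              call. = FALSE)
  blocks <- lapply(bags, function(b) {
    al <- align_pool_producers(chem, abund, pool_variable, producer_vars, b)
    X <- as.matrix(al[names(producer_vars)])
    if (kernel == "increment") {
      X <- matrix(pic_increments(X[, 1]), ncol = 1,
                  dimnames = list(NULL, names(producer_vars)[1]))
    }
    list(y = al$value, X = X, day = al$day)
  })
  scan <- scan_loss_grid(blocks, d_grid)
  best <- scan$best
  groups <- colnames(blocks[[1]]$X)
  per_bag <- purrr::map2_dfr(seq_along(bags), blocks, function(i, b) {
    a <- best$coef[[i]]
    fitted <- as.numeric(kernel_matrix(b$X, best$d) %*% a)
    ss_tot <- sum((b$y - mean(b$y))^2)
    r2 <- if (ss_tot > 0) 1 - sum((b$y - fitted)^2) / ss_tot else NA_real_
    tibble::tibble(bag = bags[i],
                   producer = groups,
                   rate = as.numeric(a),
                   r2 = r2)
  })
  structure(list(kind = kernel, variable = pool_variable,
                 rates = per_bag, d = best$d, r2 = best$r2,
                 d_scan = scan$table, bags = bags, blocks = blocks),
            class = "carbon_fit_set")
}

align_pool_producers <- function(chem, abund, pool_variable, producer_vars,
                                 bag) {
  pool <- chem |>
    dplyr::filter(.data$variable == pool_variable, .data$bag == !!bag) |>
    dplyr::select("day", "value")
  prod <- abund |>
    dplyr::filter(.data$variable %in% producer_vars, .data$bag == !!bag,
                  .data$day %% 1 == 0) |>
    dplyr::select("day", "variable", "value") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value")
  ren <- stats::setNames(producer_vars, names(producer_vars))
  names(prod)[match(ren, names(prod))] <- names(ren)
  out <- dplyr::inner_join(pool, prod, by = "day") |> dplyr::arrange(.data$day)
  if (nrow(out) < length(producer_vars) + 1) {
    stop("too few aligned days for bag ", bag, call. = FALSE)
  }
  out
}

#' Per-producer contribution shares of the modeled pool
#'
#' Each producer's summed discounted-kernel contribution over a day range,
#' divided by the total modeled pool over the same range. Shares sum to 1 by
#' construction.
#'
#' @param fit A `carbon_fit` object.
#' @param day_range Optional `c(min, max)` day window (inclusive); default
#'   all fitted days.
#' @return A tibble with columns `producer` and `share`.
#' @export
contribution_shares <- function(fit, day_range = NULL) {
  stopifnot(inherits(fit, "carbon_fit"))
  groups <- fit$rates$producer
  X <- as.matrix(fit$producers[groups])
  if (fit$kind == "increment") {
    X <- matrix(pic_increments(X[, 1]), ncol = 1,
                dimnames = list(NULL, groups))
  }
  K <- kernel_matrix(X, fit$d)
  contrib <- sweep(K, 2, fit$rates$rate, `*`)
  keep <- rep(TRUE, nrow(K))
  if (!is.null(day_range)) {
    keep <- fit$producers$day >= day_range[1] &
      fit$producers$day <= day_range[2]
  }
  totals <- colSums(contrib[keep, , drop = FALSE])
  if (sum(totals) <= 0) stop("modeled pool is zero over the day range",
                             call. = FALSE)
  tibble::tibble(producer = groups, share = as.numeric(totals / sum(totals)))
}

#' Estimate the infected-cell production multiplier
#'
#' The host population is split into a bystander subpopulation producing T
#' per cell (T and the loss fraction taken from a baseline fit on the least
#' infected uncovered bags) and an infected subpopulation producing I x T
#' per cell, with the infected fraction f(t) measured by smFISH and linearly
#' interpolated between measurement days. I is scanned over a grid and the
#' value minimizing the squared deviation between the two-subpopulation
#' prediction and the observed pool is returned. At I = 1 the model reduces
#' exactly to the baseline single-population model.
#'
#' @param observed Observed pool series in the infected bag (data frame with
#'   `day`, `value`).
#' @param producers Producer abundances for the infected bag (data frame
#'   with `day` plus producer columns; the host column must be named as in
#'   the baseline fit's first producer).
#' @param f Infected-fraction series: data frame with `day` and `value` in
#'   [0, 1] (interpolated to the producer days), or a numeric vector aligned
#'   with `producers`.
#' @param baseline_fit `carbon_fit` from the least-infected uncovered bags.
#' @param i_grid Candidate multipliers (default 0 to 10 in steps of 0.05).
#' @return An object of class `infection_fit` with the selected multiplier
#'   `I`, baseline per-cell rate `T`, achieved deviation, and the full scan.
#' @export
fit_infection_multiplier <- function(observed, producers, f, baseline_fit,
                                     i_grid = seq(0, 10, by = 0.05)) {
  stopifnot(inherits(baseline_fit, "carbon_fit"))
  y <- if (is.data.frame(observed)) observed$value else as.numeric(observed)
  days <- producers$day
  if (is.data.frame(f)) {
    f_t <- stats::approx(f$day, f$value, xout = days, rule = 2)$y
  } else {
    f_t <- as.numeric(f)
  }
  if (any(f_t < 0 | f_t > 1)) stop("infected fractions must lie in [0, 1]",
                                   call. = FALSE)
  if (all(f_t == 0)) {
    stop("infected fraction is identically zero: multiplier unidentifiable",
         call. = FALSE)
  }
  host <- baseline_fit$rates$producer[1]
  rates <- stats::setNames(baseline_fit$rates$rate,
                           baseline_fit$rates$producer)
  d <- baseline_fit$d
  predict_with <- function(I) {
    pr <- producers
    if (baseline_fit$kind == "increment") {
      # infected multiplier applies to per-new-cell coccolith production
      inc <- pic_increments(pr[[host]]) * ((1 - f_t) + I * f_t)
      acc <- accumulate_pool(rates[host] * inc, d, "recursion")
      return(acc)
    }
    pr[[host]] <- pr[[host]] * ((1 - f_t) + I * f_t)
    forward_tep(pr, rates, d)$value
  }
  dev <- vapply(i_grid, function(I) sum((y - predict_with(I))^2), numeric(1))
  best <- which.min(dev)
  structure(list(
    I = i_grid[best],
    T = unname(rates[host]),
    deviation = dev[best],
    i_scan = tibble::tibble(I = i_grid, deviation = dev),
    f = tibble::tibble(day = days, value = f_t),
    baseline = baseline_fit
  ), class = "infection_fit")
}

#' @export
print.carbon_fit <- function(x, ...) {
  cat("Recursive production-loss model fit (", x$kind, " kernel)\n", sep = "")
  cat("  loss fraction d =", format(x$d), "/day, R^2 =",
      format(x$r2, digits = 4), "\n")
  cat("  per-cell rates:\n")
  print(x$rates)
  invisible(x)
}

#' @export
print.carbon_fit_set <- function(x, ...) {
  cat("Joint production-loss fit for", x$variable, "across",
      length(x$bags), "bags\n")
  cat("  shared loss fraction d =", format(x$d), "/day, pooled R^2 =",
      format(x$r2, digits = 4), "\n")
  print(x$rates)
  invisible(x)
}

#' @export
print.infection_fit <- function(x, ...) {
  cat("Infected-subpopulation production multiplier\n")
  cat("  I =", format(x$I), " (baseline per-cell rate T =",
      format(x$T, digits = 4), ")\n")
  cat("  squared deviation at optimum:", format(x$deviation, digits = 4),
      "\n")
  invisible(x)
}
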