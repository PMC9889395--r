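test_that("Bray-Curtis similarity matches its definition and properties", {
  expect_equal(bray_curtis_similarity(c(0.2, 0.8), c(0.2, 0.8)), 1)
  expect_equal(bray_curtis_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(bray_curtis_similarity(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)),
               0.5)
  set.seed(2)
  for (i in 1:25) {
    x <- stats::runif(6)
    y <- stats::runif(6)
    s <- bray_curtis_similarity(x, y)
    expect_gte(s, 0)
    expect_lte(s, 1)
    expect_equal(s, bray_curtis_similarity(y, x))
  }
  expect_error(bray_curtis_similarity(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis_similarity(1, c(1, 2)), "length")
})

test_that("center of mass orders profiles by when they peak", {
  expect_equal(center_of_mass(c(0, 0, 5, 0), 0:3), 2)
  expect_equal(center_of_mass(c(1, 0, 0, 1), 0:3), 1.5)
  expect_equal(center_of_mass(c(1, 2, 1), c(1, 2, 3)), 2)
  expect_error(center_of_mass(c(0, 0), 0:1), "all-zero")
})

test_that("taxon filters apply inclusive thresholds per criterion", {
  comp <- dplyr::bind_rows(
    tibble::tibble(taxon = "low", bag = 1, day = 0:9, rel_abund = 0.01),
    tibble::tibble(taxon = "edge", bag = 1, day = 0:9,
                   rel_abund = c(rep(0.03, 4), rep(0.001, 6))),
    tibble::tibble(taxon = "big", bag = 1, day = 0:9, rel_abund = 0.96))
  kept <- filter_taxa(comp, 0.02, 4, criterion = "per_sample")
  expect_setequal(unique(kept$taxon), c("edge", "big"))
  kept_max <- filter_taxa(comp, 0.10, 5, criterion = "max")
  expect_setequal(unique(kept_max$taxon), "big")

  # planted pass/fail counts on a random matrix vs brute force
  set.seed(13)
  rnd <- tidyr::expand_grid(taxon = paste0("t", 1:30), bag = 1:2,
                            day = 0:5) |>
    dplyr::mutate(rel_abund = stats::runif(dplyr::n(), 0, 0.08))
  kept_r <- unique(filter_taxa(rnd, 0.05, 3, "per_sample")$taxon)
  brute <- names(which(tapply(rnd$rel_abund >= 0.05, rnd$taxon, sum) >= 3))
  expect_setequal(kept_r, brute)
})

test_that("turnover fitting inverts the exponential decay model", {
  comp <- exact_turnover_composition(k = 0.2, floor = 0.05)
  fit <- fit_turnover(comp, bag = 1, start_day = 0, floor = 0.05)
  expect_equal(fit$k, 0.2, tolerance = 1e-6)
  expect_equal(fit$half_life, log(2) / fit$k)

  for (k_true in c(0.05, 0.5, 1.2)) {
    f <- fit_turnover(exact_turnover_composition(k = k_true), 1, 0)
    expect_equal(f$k, k_true, tolerance = 1e-6)
  }

  const <- tibble::tibble(taxon = rep(c("A", "B"), each = 5), bag = 1,
                          day = rep(0:4, 2),
                          rel_abund = rep(c(0.3, 0.7), each = 5))
  f0 <- fit_turnover(const, 1, 0)
  expect_equal(f0$k, 0)
  expect_true(f0$degenerate)
})

test_that("fitted turnover increases with the planted replacement rate", {
  k_fast <- fit_turnover(replacement_composition(0.2), 1, 0)$k
  k_slow <- fit_turnover(replacement_composition(0.1), 1, 0)$k
  expect_gt(k_fast, k_slow)
  expect_gt(k_slow, 0)
})

test_that("succession clustering recovers planted structure deterministically", {
  sc <- quiet_scenario()
  comp <- generate_composition(sc, marker = "18S", include_host = FALSE)
  filtered <- filter_taxa(comp, 0.02, 5, criterion = "max")
  cl <- cluster_succession(filtered, seed = 0)
  expect_equal(cl$n_clusters, 6)
  best <- cl$silhouette$score[cl$silhouette$k == cl$n_clusters]
  expect_true(all(best >= cl$silhouette$score, na.rm = TRUE))

  # deterministic given seed
  cl2 <- cluster_succession(filtered, seed = 0)
  expect_identical(cl$labels, cl2$labels)

  # invariant to taxon order as a partition
  perm <- filtered |> dplyr::arrange(dplyr::desc(taxon))
  cl3 <- cluster_succession(perm, seed = 0)
  lab1 <- cl$labels$cluster[order(cl$labels$taxon)]
  lab3 <- cl3$labels$cluster[order(cl3$labels$taxon)]
  expect_equal(length(unique(paste(lab1, lab3))), cl$n_clusters)

  # identical profiles degenerate to one flagged cluster
  same <- generate_composition(sc, marker = "18S", include_host = FALSE,
                               centers = rep(12, 6), sd_range = c(2, 2))
  same <- dplyr::bind_rows(lapply(unique(same$taxon)[1:8], function(tx) {
    tibble::tibble(taxon = tx, bag = 1, day = 0:23,
                   rel_abund = exp(-0.5 * ((0:23 - 12) / 2)^2))
  })) |> normalize_composition()
  cl_deg <- cluster_succession(same)
  expect_equal(cl_deg$n_clusters, 1L)
  expect_true(cl_deg$degenerate)

  expect_error(cluster_succession(filtered, k_range = 500:600), "k_range")
})

test_that("divergence is 1 under exchangeable bags and flags a perturbed bag", {
  sc <- quiet_scenario()
  comp <- generate_composition(sc, marker = "18S", include_host = FALSE,
                               n_differential = 0)
  # remove the planted under-represented taxon as well: bags identical
  comp_same <- dplyr::bind_rows(lapply(1:4, function(b) {
    dplyr::mutate(dplyr::filter(comp, bag == 1), bag = b)
  }))
  div0 <- divergence(comp_same, start_days = c(11, 12, 13), end_day = 23)
  expect_equal(div0$divergence, rep(1, 4))

  # perturb one bag after day 13 only
  pert <- comp_same |>
    dplyr::mutate(rel_abund = ifelse(
      bag == 2 & day > 13 & taxon == "18S_taxon_55",
      rel_abund + 0.5, rel_abund)) |>
    normalize_composition()
  divp <- divergence(pert, start_days = c(5, 6, 7), end_day = 23)
  expect_gt(divp$divergence[divp$bag == 2], 1)

  # invariant to bag relabeling
  relab <- dplyr::mutate(pert, bag = c(4, 3, 2, 1)[bag])
  divr <- divergence(relab, start_days = c(5, 6, 7), end_day = 23)
  expect_equal(sort(divr$divergence), sort(divp$divergence),
               tolerance = 1e-12)

  expect_error(divergence(comp_same, end_day = 99), "99")
})

test_that("differential screen finds planted taxa and respects rank invariance", {
  sc <- mesocosm_scenario(noise_cv = 0.1, seed = 3)
  comp <- generate_composition(sc, marker = "16S", include_host = FALSE)
  hits <- differential_abundance(filter_taxa(comp, 0.10, 1, "max"),
                                 focal_bag = which.max(sc$viral_load_scale))
  expect_gt(nrow(hits), 0)
  expect_true(any(hits$direction > 0))

  # identical distributions: nothing significant
  same <- dplyr::bind_rows(lapply(1:4, function(b) {
    dplyr::mutate(dplyr::filter(comp, bag == 1), bag = b)
  }))
  expect_equal(nrow(differential_abundance(same, 2)), 0)

  # p-values invariant under monotone transformation of abundances
  f <- filter_taxa(comp, 0.10, 1, "max")
  p1 <- differential_abundance(f, 7, all = TRUE)
  p2 <- differential_abundance(
    dplyr::mutate(f, rel_abund = rel_abund^3), 7, all = TRUE)
  expect_equal(p1$p, p2$p, tolerance = 1e-12)
})

test_that("trait aggregation conserves annotated shares per phase", {
  comp <- tibble::tibble(
    taxon = rep(c("A", "B"), each = 2), bag = 1,
    day = rep(c(1, 20), 2),
    rel_abund = c(0.4, 0.4, 0.6, 0.6),
    trophic_mode = rep(c("autotroph", "heterotroph"), each = 2),
    sub_mode = rep(c(NA, "osmotroph"), each = 2))
  tr <- aggregate_traits(comp)
  troph <- dplyr::filter(tr, level == "trophic")
  expect_equal(troph$share[troph$phase == "mixed" &
                             troph$trait == "autotroph"], 0.4)
  expect_equal(troph$share[troph$phase == "demise" &
                             troph$trait == "heterotroph"], 0.6)

  # all-autotroph community
  all_auto <- dplyr::mutate(comp, trophic_mode = "autotroph")
  ta <- aggregate_traits(all_auto)
  expect_true(all(abs(ta$share[ta$trait == "autotroph"] - 1) < 1e-12))

  # conservation on random annotated matrices
  set.seed(7)
  rnd <- tidyr::expand_grid(taxon = paste0("t", 1:12), bag = 1:2,
                            day = 0:23) |>
    dplyr::mutate(rel_abund = stats::runif(dplyr::n()),
                  trophic_mode = rep_len(c("autotroph", "mixotroph",
                                           "heterotroph", NA), 12)[
                    as.integer(factor(taxon))]) |>
    normalize_composition()
  sums <- aggregate_traits(rnd) |>
    dplyr::filter(level == "trophic") |>
    dplyr::group_by(phase) |>
    dplyr::summarise(s = sum(share))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_error(aggregate_traits(dplyr::select(rnd, -trophic_mode)),
               "annotations")
})
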