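#' Bray-Curtis similarity between two composition vectors
#'
#' 1 - sum|x_i - y_i| / sum(x_i + y_i). Lies in [0, 1], is symmetric, and
#' equals 1 exactly when the vectors coincide.
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @return Similarity in [0, 1].
#' @export
bray_curtis_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("negative entries", call. = FALSE)
  denom <- sum(x + y)
  if (denom == 0) stop("both vectors are all-zero", call. = FALSE)
  1 - sum(abs(x - y)) / denom
}

#' Bray-Curtis distance (1 - similarity)
#' @inheritParams bray_curtis_similarity
#' @return Distance in [0, 1].
#' @export
bray_curtis_distance <- function(x, y) 1 - bray_curtis_similarity(x, y)

#' Temporal center of mass of an abundance profile
#'
#' sum(t_i f(t_i)) / sum(f(t_i)); used to sort heatmap rows by when a taxon
#' peaks (after per-row max-normalization).
#'
#' @param value Non-negative abundances.
#' @param day Matching day coordinates.
#' @return The center-of-mass day.
#' @export
center_of_mass <- function(value, day) {
  if (sum(value) <= 0) stop("all-zero profile", call. = FALSE)
  sum(day * value) / sum(value)
}

#' Filter taxa of a composition table by prevalence or peak abundance
#'
#' Two criteria, matching the presets used across the analyses:
#' `"per_sample"` keeps taxa reaching at least `min_abund` in at least
#' `min_samples` samples (heatmap presets: 2% in 4 samples for 16S, 2% in 8
#' for 18S); `"max"` keeps taxa whose maximum relative abundance reaches
#' `min_abund` and that are observed (> 0) in at least `min_samples` samples
#' (clustering preset: 2% max in 5 samples; differential screen: 10% max).
#' Thresholds are inclusive.
#'
#' @param comp A long composition tibble.
#' @param min_abund Relative-abundance threshold.
#' @param min_samples Minimum number of qualifying samples.
#' @param criterion `"per_sample"` or `"max"`.
#' @return The filtered composition tibble (not renormalized; may be empty).
#' @export
filter_taxa <- function(comp, min_abund = 0.02, min_samples = 4,
                        criterion = c("per_sample", "max")) {
  criterion <- match.arg(criterion)
  keep <- comp |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      n_above = sum(.data$rel_abund >= min_abund),
      n_present = sum(.data$rel_abund > 0),
      peak = max(.data$rel_abund), .groups = "drop") |>
    dplyr::filter(if (criterion == "per_sample") {
      .data$n_above >= min_samples
    } else {
      .data$peak >= min_abund & .data$n_present >= min_samples
    }) |>
    dplyr::pull(.data$taxon)
  dplyr::filter(comp, .data$taxon %in% keep)
}

# taxa x day matrix of a bag's samples (or bag-averaged profiles)
comp_matrix <- function(comp, bag = NULL) {
  x <- comp
  if (!is.null(bag)) x <- dplyr::filter(x, .data$bag == !!bag)
  x |>
    dplyr::group_by(.data$taxon, .data$day) |>
    dplyr::summarise(rel_abund = mean(.data$rel_abund), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "day", values_from = "rel_abund",
                       values_fill = 0) |>
    tibble::column_to_rownames("taxon") |>
    as.matrix()
}

#' Exponential community turnover rate from Bray-Curtis decay
#'
#' For a bag, the Bray-Curtis similarity between the composition at a start
#' day t' and every later day declines roughly exponentially toward a floor
#' (taxa constantly present in all samples keep similarity from reaching 0).
#' The decay rate k >= 0 of BC(t) = (1 - BC_inf) exp(-k (t - t')) + BC_inf
#' is fitted by least squares with the floor held fixed. The derived
#' timescales 1/k and the similarity half-life ln(2)/k are both reported.
#'
#' @param comp A long composition tibble.
#' @param bag Bag to fit.
#' @param start_day Reference day t'.
#' @param floor Asymptotic similarity floor BC_inf (default 0.05).
#' @return A one-row tibble: `bag`, `start_day`, `k`, `bc_floor`, `sse`,
#'   `n`, `timescale` (1/k), `half_life` (ln 2 / k), `degenerate` flag.
#' @export
fit_turnover <- function(comp, bag, start_day, floor = 0.05) {
  curve <- turnover_curve(comp, bag, start_day)
  if (nrow(curve) < 3) {
    stop("need at least 3 time points after the start day", call. = FALSE)
  }
  if (all(curve$similarity >= 1 - 1e-6)) {
    return(tibble::tibble(bag = bag, start_day = start_day, k = 0,
                          bc_floor = floor, sse = 0, n = nrow(curve),
                          timescale = Inf, half_life = Inf,
                          degenerate = TRUE))
  }
  dt <- curve$day - start_day
  obj <- function(k) {
    sum((curve$similarity - ((1 - floor) * exp(-k * dt) + floor))^2)
  }
  opt <- stats::optimize(obj, interval = c(0, 20), tol = 1e-12)
  tibble::tibble(bag = bag, start_day = start_day, k = opt$minimum,
                 bc_floor = floor, sse = opt$objective, n = nrow(curve),
                 timescale = 1 / opt$minimum,
                 half_life = log(2) / opt$minimum,
                 degenerate = FALSE)
}

#' Bray-Curtis similarity of a bag's community to its start-day composition
#'
#' @inheritParams fit_turnover
#' @return A tibble with `day` and `similarity` for every day >= start_day.
#' @export
turnover_curve <- function(comp, bag, start_day) {
  m <- comp_matrix(comp, bag = bag)
  days <- as.numeric(colnames(m))
  if (!start_day %in% days) {
    stop("no sample at start day ", start_day, " for bag ", bag,
         call. = FALSE)
  }
  ref <- m[, as.character(start_day)]
  later <- days[days > start_day]
  tibble::tibble(
    day = later,
    similarity = vapply(later, function(d) {
      bray_curtis_similarity(ref, m[, as.character(d)])
    }, numeric(1)))
}

# silhouette variant used for choosing the cluster count: mean over taxa of
# (distance to the nearest other cluster) minus (mean distance within the
# own cluster); unnormalized, on the cosine distance.
cosine_silhouette <- function(dist_mat, labels) {
  ks <- sort(unique(labels))
  if (length(ks) < 2) return(NA_real_)
  scores <- vapply(seq_along(labels), function(i) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    a <- if (length(own) == 0) 0 else mean(dist_mat[i, own])
    b <- min(vapply(setdiff(ks, labels[i]), function(k) {
      mean(dist_mat[i, labels == k])
    }, numeric(1)))
    b - a
  }, numeric(1))
  mean(scores)
}

#' Cluster taxon succession profiles and select the count by silhouette
#'
#' Profiles are averaged across bags, smoothed with a width-2 moving
#' average, and scaled to unit length so that k-means in Euclidean space
#' orders partitions exactly as cosine distance does. For each candidate
#' count in `k_range` a k-means partition (fixed seed, multiple restarts)
#' is scored by the mean over taxa of the between-cluster minus
#' within-cluster cosine distance; the count with the highest positive
#' score wins. When all profiles coincide every candidate is degenerate and
#' a single cluster is returned with a flag.
#'
#' @param comp A long composition tibble (pre-filter with [filter_taxa()]).
#' @param k_range Candidate cluster counts (default 2 to 12).
#' @param seed Random seed for the k-means restarts.
#' @param nstart Number of k-means restarts (default 10).
#' @param smooth_width Moving-average width applied per profile (default 2).
#' @return An object of class `cluster_result`: per-taxon labels,
#'   `n_clusters`, the silhouette score per candidate count, and
#'   per-cluster mean/sd profiles.
#' @export
cluster_succession <- function(comp, k_range = 2:12, seed = 0, nstart = 10,
                               smooth_width = 2) {
  m <- comp_matrix(comp)
  if (nrow(m) < 2) stop("need at least 2 taxa", call. = FALSE)
  k_range <- k_range[k_range < nrow(m)]
  if (length(k_range) == 0) {
    stop("k_range exceeds the number of taxa", call. = FALSE)
  }
  sm <- t(apply(m, 1, moving_average, width = smooth_width))
  norms <- sqrt(rowSums(sm^2))
  norms[norms == 0] <- 1
  u <- sm / norms
  dist_mat <- 1 - tcrossprod(u)  # cosine distance
  dist_mat[dist_mat < 0] <- 0
  all_same <- max(dist_mat) < 1e-12
  scores <- rep(NA_real_, length(k_range))
  partitions <- vector("list", length(k_range))
  if (!all_same) {
    for (i in seq_along(k_range)) {
      set.seed(seed)
      km <- stats::kmeans(u, centers = k_range[i], nstart = nstart,
                          iter.max = 100)
      partitions[[i]] <- km$cluster
      scores[i] <- cosine_silhouette(dist_mat, km$cluster)
    }
  }
  sil <- tibble::tibble(k = k_range, score = scores)
  positive <- which(!is.na(scores) & scores > 0)
  if (length(positive) == 0) {
    labels <- stats::setNames(rep(1L, nrow(m)), rownames(m))
    n_clusters <- 1L
    degenerate <- TRUE
  } else {
    best <- positive[which.max(scores[positive])]
    labels <- partitions[[best]]
    names(labels) <- rownames(m)
    n_clusters <- k_range[best]
    degenerate <- FALSE
  }
  day <- as.numeric(colnames(m))
  norm_profiles <- m / apply(m, 1, max)
  profiles <- tibble::tibble(taxon = rep(rownames(m), each = length(day)),
                             day = rep(day, nrow(m)),
                             value = as.numeric(t(norm_profiles))) |>
    dplyr::mutate(cluster = labels[.data$taxon]) |>
    dplyr::group_by(.data$cluster, .data$day) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), 0),
                     .groups = "drop")
  structure(list(
    labels = tibble::tibble(taxon = names(labels),
                            cluster = as.integer(labels)),
    n_clusters = as.integer(n_clusters),
    silhouette = sil,
    profiles = profiles,
    degenerate = degenerate
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Succession clustering:", x$n_clusters, "cluster(s) over",
      nrow(x$labels), "taxa\n")
  if (x$degenerate) cat("  (degenerate: no candidate count scored > 0)\n")
  print(x$silhouette)
  invisible(x)
}

#' Compositional divergence of each bag from the rest
#'
#' For each focal bag the mean Bray-Curtis distance to all other bags at the
#' end day, normalized by the same quantity at each candidate bloom start
#' day; the mean and standard deviation over start days are returned. Under
#' a bag-exchangeable null the divergence is 1. Host reads can be removed
#' first (the 18S convention) to avoid host-abundance bias.
#'
#' @param comp A long composition tibble covering several bags.
#' @param start_days Candidate bloom start days (default 11, 12, 13).
#' @param end_day Day at which divergence is measured (default the last day
#'   present in all bags).
#' @param remove_taxa Optional regular expression; matching taxa are removed
#'   and samples renormalized before computing distances.
#' @return A tibble with `bag`, `divergence`, `divergence_sd`.
#' @export
divergence <- function(comp, start_days = c(11, 12, 13), end_day = NULL,
                       remove_taxa = NULL) {
  if (!is.null(remove_taxa)) {
    comp <- comp |>
      dplyr::filter(!grepl(remove_taxa, .data$taxon)) |>
      normalize_composition()
  }
  bags <- sort(unique(comp$bag))
  if (length(bags) < 2) stop("need at least 2 bags", call. = FALSE)
  mats <- lapply(bags, function(b) comp_matrix(comp, bag = b))
  names(mats) <- as.character(bags)
  common_days <- Reduce(intersect, lapply(mats, colnames))
  if (is.null(end_day)) end_day <- max(as.numeric(common_days))
  need <- as.character(c(start_days, end_day))
  if (!all(need %in% common_days)) {
    stop("missing sample(s) at day(s): ",
         paste(setdiff(need, common_days), collapse = ", "), call. = FALSE)
  }
  mean_dist <- function(focal, day) {
    mean(vapply(setdiff(bags, focal), function(b) {
      bray_curtis_distance(mats[[as.character(focal)]][, as.character(day)],
                           mats[[as.character(b)]][, as.character(day)])
    }, numeric(1)))
  }
  purrr::map_dfr(bags, function(focal) {
    end <- mean_dist(focal, end_day)
    ratios <- vapply(start_days, function(s) {
      start <- mean_dist(focal, s)
      if (start == 0 && end == 0) 1 else end / start
    }, numeric(1))
    tibble::tibble(bag = focal, divergence = mean(ratios),
                   divergence_sd = stats::sd(ratios))
  })
}

#' Differential-abundance screen for one bag during bloom demise
#'
#' Two-sided Mann-Whitney U test of each taxon's relative abundance in the
#' focal bag against the pooled values of all other bags over the demise
#' time points (normal approximation with tie correction), with
#' multiple-testing correction over the tested taxa. Pre-filter the input to
#' taxa with a maximum abundance of at least 10% (see [filter_taxa()]).
#'
#' @param comp A long composition tibble.
#' @param focal_bag Bag screened for over/under-represented taxa.
#' @param demise_days Days of the demise phase (default 18 to 23).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param p_adjust_method Correction method (default `"bonferroni"`).
#' @param all Return all tested taxa rather than only significant ones.
#' @return A tibble with `taxon`, `direction` (+1 over-, -1
#'   under-represented), `p`, `p_adj`, sorted by `p_adj`.
#' @export
differential_abundance <- function(comp, focal_bag, demise_days = 18:23,
                                   alpha = 0.05,
                                   p_adjust_method = "bonferroni",
                                   all = FALSE) {
  x <- dplyr::filter(comp, .data$day %in% demise_days)
  res <- x |>
    dplyr::group_by(.data$taxon) |>
    dplyr::group_map(function(df, key) {
      focal <- df$rel_abund[df$bag == focal_bag]
      other <- df$rel_abund[df$bag != focal_bag]
      if (length(focal) < 2 || length(other) < 2) {
        stop("fewer than 2 observations in a group for taxon ", key$taxon,
             call. = FALSE)
      }
      p <- stats::wilcox.test(focal, other, exact = FALSE,
                              correct = TRUE)$p.value
      tibble::tibble(taxon = key$taxon,
                     direction = sign(stats::median(focal) -
                                        stats::median(other)),
                     p = p)
    }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p,
                                          method = p_adjust_method)) |>
    dplyr::arrange(.data$p_adj)
  if (all) res else dplyr::filter(res, .data$p_adj < alpha)
}

#' Aggregate relative abundance by trophic trait and bloom phase
#'
#' Sums the relative abundance of all annotated taxa sharing a trait, then
#' averages over the days (and bags) of each phase; shares are renormalized
#' over annotated taxa. Heterotrophy sub-modes (osmotroph, saprotroph,
#' other) are tabulated the same way within heterotrophs.
#'
#' @param comp A long composition tibble with a `trophic_mode` column
#'   (`autotroph`, `mixotroph`, `heterotroph`; NA = unannotated, excluded)
#'   and optionally `sub_mode`.
#' @param phases Named list of inclusive day ranges (default the three
#'   bloom phases).
#' @return A tibble with `phase`, `level` (`"trophic"` or `"submode"`),
#'   `trait`, `share`; trophic shares sum to 1 within each phase.
#' @export
aggregate_traits <- function(comp,
                             phases = list(mixed = c(0, 9),
                                           growth = c(10, 17),
                                           demise = c(18, 23))) {
  if (!"trophic_mode" %in% names(comp)) {
    stop("composition table has no trophic_mode annotations", call. = FALSE)
  }
  anno <- dplyr::filter(comp, !is.na(.data$trophic_mode))
  if (nrow(anno) == 0) stop("no annotated taxa", call. = FALSE)
  per_sample <- anno |>
    dplyr::group_by(.data$bag, .data$day) |>
    dplyr::mutate(rel_abund = .data$rel_abund / sum(.data$rel_abund)) |>
    dplyr::ungroup()
  phase_of <- function(day) {
    hit <- names(phases)[vapply(phases, function(r) {
      day >= r[1] & day <= r[2]
    }, logical(1))]
    if (length(hit) == 0) NA_character_ else hit[1]
  }
  per_sample$phase <- vapply(per_sample$day, phase_of, character(1))
  per_sample <- dplyr::filter(per_sample, !is.na(.data$phase))
  trophic <- per_sample |>
    dplyr::group_by(.data$phase, .data$bag, .data$day,
                    trait = .data$trophic_mode) |>
    dplyr::summarise(s = sum(.data$rel_abund), .groups = "drop") |>
    tidyr::complete(tidyr::nesting(phase, bag, day), trait,
                    fill = list(s = 0)) |>
    dplyr::group_by(.data$phase, .data$trait) |>
    dplyr::summarise(share = mean(.data$s), .groups = "drop") |>
    dplyr::mutate(level = "trophic")
  out <- trophic
  if ("sub_mode" %in% names(comp)) {
    het <- per_sample |>
      dplyr::filter(.data$trophic_mode == "heterotroph",
                    !is.na(.data$sub_mode))
    if (nrow(het) > 0) {
      sub <- het |>
        dplyr::group_by(.data$bag, .data$day) |>
        dplyr::mutate(rel_abund = .data$rel_abund / sum(.data$rel_abund)) |>
        dplyr::group_by(.data$phase, .data$bag, .data$day,
                        trait = .data$sub_mode) |>
        dplyr::summarise(s = sum(.data$rel_abund), .groups = "drop") |>
        tidyr::complete(tidyr::nesting(phase, bag, day), trait,
                        fill = list(s = 0)) |>
        dplyr::group_by(.data$phase, .data$trait) |>
        dplyr::summarise(share = mean(.data$s), .groups = "drop") |>
        dplyr::mutate(level = "submode")
      out <- dplyr::bind_rows(trophic, sub)
    }
  }
  dplyr::select(out, "phase", "level", "trait", "share")
}
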