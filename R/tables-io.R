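#' Build a validated long-format measurement table
#'
#' The canonical exchange format between all analysis stages: one row per
#' (bag, day, variable) observation. Days are real-valued so that evening
#' flow-cytometry samples can sit at half-day offsets (e.g. 17.5). Replicate
#' rows sharing the same key are averaged; conflicting units for the same
#' variable are an error.
#'
#' @param x A data frame with columns `bag`, `day`, `variable`, `value` and
#'   optionally `unit`.
#' @param unit Optional single unit applied to all rows lacking a `unit`
#'   column.
#' @return A tibble with columns `bag`, `day`, `variable`, `value`, `unit`,
#'   one row per key, replicates averaged.
#' @export
measurement_table <- function(x, unit = NA_character_) {
  required <- c("bag", "day", "variable", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("measurement table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!"unit" %in% names(x)) x$unit <- unit
  if (nrow(x) == 0) {
    return(tibble::tibble(bag = x$bag, day = numeric(0),
                          variable = character(0), value = numeric(0),
                          unit = character(0)))
  }
  if (!is.numeric(x$day) || (!is.numeric(x$value) && nrow(x) > 0)) {
    stop("'day' and 'value' must be numeric", call. = FALSE)
  }
  if (nrow(x) > 0 && any(x$day < 0, na.rm = TRUE)) {
    stop("'day' must be >= 0 (day 0 is the first sampling)", call. = FALSE)
  }
  conflicts <- x |>
    dplyr::distinct(.data$variable, .data$unit) |>
    dplyr::count(.data$variable) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    stop("conflicting units for variable(s): ",
         paste(conflicts$variable, collapse = ", "), call. = FALSE)
  }
  x |>
    dplyr::group_by(.data$bag, .data$day, .data$variable, .data$unit) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$bag, .data$variable, .data$day)
}

#' Read a measurement table from delimited text
#'
#' Delimiter (comma or tab) is sniffed from the header line. Parse failures
#' are reported with their line numbers. Replicate rows are averaged.
#'
#' @param path Path to a CSV/TSV file with header columns
#'   `bag,day,variable,value[,unit]`.
#' @param unit Optional per-file unit when the file has no `unit` column.
#' @return A validated measurement tibble (see [measurement_table()]).
#' @export
read_measurements <- function(path, unit = NA_character_) {
  delim <- sniff_delim(path)
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    stop("parse failures in ", path, " at line(s): ",
         paste(utils::head(probs$row, 10), collapse = ", "), call. = FALSE)
  }
  measurement_table(x, unit = unit)
}

#' Write a measurement table to CSV
#'
#' @param x A measurement tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_measurements <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a taxa-by-sample composition matrix
#'
#' Expects a wide delimited matrix: a `taxon` column (optionally `taxonomy`,
#' `trophic_mode`, `sub_mode` annotation columns) followed by one column per
#' sample, named `bag<k>_day<d>`. Counts are converted to proportions per
#' sample. Rows flagged as organelle sequence (taxonomy containing
#' "Chloroplast") can be dropped before renormalization.
#'
#' @param path Path to the delimited file.
#' @param remove_chloroplast Drop chloroplast-flagged rows, then renormalize.
#' @return A long composition tibble with columns `taxon`, `bag`, `day`,
#'   `rel_abund` plus any annotation columns, each (bag, day) sample summing
#'   to 1.
#' @export
read_composition <- function(path, remove_chloroplast = FALSE) {
  delim <- sniff_delim(path)
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  anno_cols <- intersect(names(x),
                         c("taxon", "taxonomy", "trophic_mode", "sub_mode"))
  sample_cols <- setdiff(names(x), anno_cols)
  if (!"taxon" %in% names(x)) stop("missing 'taxon' column", call. = FALSE)
  long <- x |>
    tidyr::pivot_longer(dplyr::all_of(sample_cols),
                        names_to = "sample", values_to = "rel_abund") |>
    tidyr::extract("sample", into = c("bag", "day"),
                   regex = "bag([0-9]+)_day([0-9.]+)", convert = TRUE)
  if (anyNA(long$bag) || anyNA(long$day)) {
    stop("sample columns must be named bag<k>_day<d>", call. = FALSE)
  }
  comp <- composition_table(long)
  if (remove_chloroplast && "taxonomy" %in% names(comp)) {
    comp <- comp |>
      dplyr::filter(!grepl("chloroplast", .data$taxonomy,
                           ignore.case = TRUE)) |>
      normalize_composition()
  }
  comp
}

#' Validate and normalize a long composition table
#'
#' @param x A data frame with columns `taxon`, `bag`, `day`, `rel_abund`.
#' @return A tibble in which every (bag, day) sample sums to 1.
#' @export
composition_table <- function(x) {
  required <- c("taxon", "bag", "day", "rel_abund")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("composition table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(x$rel_abund < 0, na.rm = TRUE)) {
    stop("negative entries in composition table", call. = FALSE)
  }
  if (length(unique(x$taxon)) < 2) {
    stop("composition table needs at least 2 taxa", call. = FALSE)
  }
  normalize_composition(tibble::as_tibble(x))
}

#' Renormalize each sample of a composition table to sum to 1
#'
#' Idempotent. Errors on any zero-sum sample, naming it.
#'
#' @param x A long composition tibble.
#' @return `x` with `rel_abund` scaled per (bag, day) sample.
#' @export
normalize_composition <- function(x) {
  totals <- x |>
    dplyr::group_by(.data$bag, .data$day) |>
    dplyr::summarise(total = sum(.data$rel_abund), .groups = "drop")
  zero <- totals |> dplyr::filter(.data$total <= 0)
  if (nrow(zero) > 0) {
    stop("zero-sum sample(s): ",
         paste0("bag", zero$bag, "_day", zero$day, collapse = ", "),
         call. = FALSE)
  }
  x |>
    dplyr::group_by(.data$bag, .data$day) |>
    dplyr::mutate(rel_abund = .data$rel_abund / sum(.data$rel_abund)) |>
    dplyr::ungroup()
}

#' Write a composition table as a wide taxa-by-sample CSV
#'
#' @param x A long composition tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_composition <- function(x, path) {
  anno <- intersect(names(x), c("taxon", "taxonomy", "trophic_mode", "sub_mode"))
  wide <- x |>
    dplyr::mutate(sample = paste0("bag", .data$bag, "_day", .data$day)) |>
    dplyr::select(dplyr::all_of(anno), "sample", "rel_abund") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "rel_abund",
                       values_fill = 0)
  readr::write_csv(wide, path)
  invisible(x)
}

#' Centered moving average with shrinking windows at the boundaries
#'
#' At interior points the mean is taken over a centered window of `width`
#' points (for even widths the extra point falls after the center, matching a
#' forward-leaning width-2 smoother). At the series ends the window shrinks
#' to the available points, so the output has the same length as the input.
#'
#' @param x Numeric vector.
#' @param width Window width in points (>= 1).
#' @return Numeric vector of the same length.
#' @export
moving_average <- function(x, width) {
  if (width < 1) stop("width must be >= 1", call. = FALSE)
  n <- length(x)
  lo <- floor((width - 1) / 2)
  hi <- floor(width / 2)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - lo):min(n, i + hi)])
  }, numeric(1))
}

#' Default analysis configuration
#'
#' Central defaults shared across stages: the loss-fraction grid scanned by
#' the carbon models, the Bray-Curtis similarity floor, the dilution-assay
#' significance level, the multiple-testing method, bloom phase boundaries,
#' and the normalization start days for divergence.
#'
#' @param d_grid Loss-fraction grid (per day) for the carbon-model scan.
#' @param bc_floor Asymptotic Bray-Curtis similarity floor.
#' @param dilution_alpha Significance level for dilution-assay t-tests.
#' @param p_adjust_method Multiple-testing correction for the differential
#'   abundance screen.
#' @param phases Named list of day ranges: mixed bloom, host growth, demise.
#' @param start_days Candidate bloom start days used to normalize divergence.
#' @param i_grid Grid over which the infected-cell production multiplier is
#'   scanned.
#' @param seed Default random seed.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(d_grid = seq(0, 0.5, by = 0.0025),
                            bc_floor = 0.05,
                            dilution_alpha = 0.1,
                            p_adjust_method = "bonferroni",
                            phases = list(mixed = c(0, 9),
                                          growth = c(10, 17),
                                          demise = c(18, 23)),
                            start_days = c(11, 12, 13),
                            i_grid = seq(0, 10, by = 0.05),
                            seed = 0L) {
  stopifnot(length(d_grid) > 0, all(diff(d_grid) > 0),
            bc_floor >= 0, bc_floor < 1)
  structure(list(d_grid = d_grid, bc_floor = bc_floor,
                 dilution_alpha = dilution_alpha,
                 p_adjust_method = p_adjust_method,
                 phases = phases, start_days = start_days,
                 i_grid = i_grid, seed = as.integer(seed)),
            class = "analysis_config")
}
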