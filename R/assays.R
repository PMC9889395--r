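#' Apparent growth rate from paired concentrations
#'
#' Standard dilution-method form k = ln(Ct/C0)/t. The dimensionally
#' inconsistent difference form ln(Ct - C0)/t that sometimes appears in
#' print is available behind `ratio = FALSE` for auditing only.
#'
#' @param C0,Ct Initial and final concentration (cells/mL or chlorophyll);
#'   both must be positive.
#' @param t Incubation time in days.
#' @param ratio Use the ratio form (default). Set `FALSE` to reproduce the
#'   difference form.
#' @return Growth rate per day.
#' @export
apparent_growth <- function(C0, Ct, t = 1, ratio = TRUE) {
  if (any(C0 <= 0) || any(Ct <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (any(t <= 0)) stop("incubation time must be positive", call. = FALSE)
  if (ratio) log(Ct / C0) / t else log(Ct - C0) / t
}

# Paired t-test p-value that stays defined for (near-)constant differences:
# identical replicates pool (p = 1), a constant nonzero offset separates
# (p = 0).
paired_p <- function(a, b, tol = 1e-12) {
  diffs <- a - b
  if (stats::sd(diffs) < tol * max(1, max(abs(c(a, b))))) {
    return(if (abs(mean(diffs)) < tol * max(1, max(abs(c(a, b))))) 1 else 0)
  }
  stats::t.test(a, b, paired = TRUE)$p.value
}

#' Growth, grazing and viral-lysis rates from a paired dilution experiment
#'
#' Implements the two-level design: apparent rates from triplicate 100%
#' whole seawater bottles with (`wsw_nut`) and without (`wsw`) added
#' nutrients, 20% dilutions in 0.45-um filtered seawater (`fsw`) and,
#' optionally, in 100-kDa tangential-flow filtrate (`tff`) which removes
#' viruses. Grazing is g = (kd - k1)/(1 - x) with kd the diluted and k1 the
#' nutrient-amended undiluted rate; intrinsic growth is mu = g + k1 with k1
#' the rate without added nutrients. Nutrient-amended and unamended rates
#' are pooled when a paired t-test finds no difference at `alpha`. Viral
#' lysis v = (kd_tff - kd_fsw)/(1 - x) is retained only when the TFF and FSW
#' dilutions differ at `alpha`; when retained, mu = g + v + k1.
#'
#' @param rates A data frame with columns `treatment` (one of `wsw_nut`,
#'   `wsw`, `fsw`, `tff`), `replicate`, and `k` (apparent rate per day, see
#'   [apparent_growth()]); the `tff` treatment is optional.
#' @param x Fraction of whole seawater in the diluted bottles (0 < x <= 1).
#' @param alpha Significance level for the paired t-tests (default 0.1).
#' @return An object of class `dilution_result` holding mean treatment
#'   rates, `g`, `mu`, `v` (NA when not detected), pooling decision and
#'   p-values.
#' @export
dilution_rates <- function(rates, x, alpha = 0.1) {
  if (x <= 0 || x > 1) stop("x must lie in (0, 1]", call. = FALSE)
  need <- c("wsw_nut", "wsw", "fsw")
  tr <- split(rates$k, rates$treatment)
  missing_tr <- setdiff(need, names(tr))
  if (length(missing_tr) > 0) {
    stop("missing treatment(s): ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  if (any(vapply(tr, length, integer(1)) < 2)) {
    stop("need at least 2 replicates per treatment", call. = FALSE)
  }
  p_nut <- paired_p(tr$wsw_nut, tr$wsw)
  pooled <- p_nut >= alpha
  k1_nut <- if (pooled) mean(c(tr$wsw_nut, tr$wsw)) else mean(tr$wsw_nut)
  k1_nonut <- if (pooled) mean(c(tr$wsw_nut, tr$wsw)) else mean(tr$wsw)
  kd <- mean(tr$fsw)
  g <- (kd - k1_nut) / (1 - x)
  p_grazing <- paired_p(tr$fsw, tr$wsw_nut)
  v <- NA_real_
  p_lysis <- NA_real_
  if ("tff" %in% names(tr)) {
    kd_tff <- mean(tr$tff)
    p_lysis <- paired_p(tr$tff, tr$fsw)
    if (p_lysis < alpha) v <- (kd_tff - kd) / (1 - x)
  }
  mu <- g + k1_nonut + if (is.na(v)) 0 else v
  structure(list(
    k1_nut = k1_nut, k1 = k1_nonut, kd = kd,
    kd_tff = if ("tff" %in% names(tr)) mean(tr$tff) else NA_real_,
    g = g, v = v, mu = mu, x = x,
    pooled_nutrients = pooled, p_nutrients = p_nut,
    p_grazing = p_grazing, p_lysis = p_lysis, alpha = alpha
  ), class = "dilution_result")
}

#' @export
print.dilution_result <- function(x, ...) {
  cat("Paired dilution experiment rates (per day)\n")
  cat(sprintf("  mu = %.4f, g = %.4f, v = %s\n", x$mu, x$g,
              if (is.na(x$v)) "not detected" else sprintf("%.4f", x$v)))
  cat(sprintf("  nutrient treatments %s (p = %.3g)\n",
              if (x$pooled_nutrients) "pooled" else "kept separate",
              x$p_nutrients))
  invisible(x)
}

#' Marker-gene copies per cell from genome size
#'
#' Empirical log-log regression of rDNA copy number on genome size:
#' log10(copies) = 0.6607 log10(G) + 0.7508, rounded to the nearest whole
#' copy. A 40-Mb thraustochytrid genome gives a log value of 1.809, i.e. 64
#' copies per cell.
#'
#' @param genome_size_mb Genome size in megabases (> 0).
#' @return Integer copy number per cell.
#' @export
copies_per_cell <- function(genome_size_mb) {
  if (any(genome_size_mb <= 0)) {
    stop("genome size must be positive", call. = FALSE)
  }
  round(10^(0.6607 * log10(genome_size_mb) + 0.7508))
}

#' Convert a ddPCR concentration to cells per mL of seawater
#'
#' Chains the droplet-reader output (copies per uL of reaction) through the
#' reaction volume, template dilution and filtered seawater volume, then
#' divides by the per-cell marker copy number.
#'
#' @param concentration Copies per uL of ddPCR reaction.
#' @param reaction_volume_ul Reaction volume in uL (default 20).
#' @param dilution_factor Template dilution factor (default 1).
#' @param filtered_volume_ml Seawater volume filtered, in mL.
#' @param copies_per_cell Marker copies per cell (default 64).
#' @return Cells per mL of sampled seawater.
#' @export
ddpcr_to_cells <- function(concentration, reaction_volume_ul = 20,
                           dilution_factor = 1, filtered_volume_ml,
                           copies_per_cell = 64) {
  if (any(filtered_volume_ml <= 0)) {
    stop("filtered volume must be positive", call. = FALSE)
  }
  if (any(copies_per_cell < 1)) {
    stop("copies per cell must be >= 1", call. = FALSE)
  }
  copies_per_ml <- concentration * reaction_volume_ul * dilution_factor /
    filtered_volume_ml
  copies_per_ml / copies_per_cell
}

#' Cell volume and carbon content of a spherical cell
#'
#' V = (4/3) pi R^3 and C = density x V. The carbon value is truncated to
#' whole femtograms, the convention used when quoting per-cell carbon (a
#' 2.5-um radius at 220 fg C/um^3 gives 14,398 fg C/cell).
#'
#' @param radius_um Cell radius in um (>= 0).
#' @param carbon_density Carbon per unit volume in fg C/um^3 (default 220).
#' @return A tibble with `volume_um3` and `carbon_fg` columns.
#' @export
cell_carbon <- function(radius_um, carbon_density = 220) {
  if (any(radius_um < 0)) stop("radius must be >= 0", call. = FALSE)
  v <- 4 / 3 * pi * radius_um^3
  tibble::tibble(volume_um3 = v, carbon_fg = trunc(carbon_density * v))
}

#' Carbon flux released by a declining cell population
#'
#' Cell loss rate between two average abundances, multiplied by per-cell
#' carbon. A growing population releases no demise carbon: negative losses
#' are clamped to zero with a warning.
#'
#' @param abundance_t1,abundance_t2 Average abundances (cells/mL) at the
#'   earlier and later time.
#' @param days_between Days separating the two abundances (> 0).
#' @param carbon_per_cell_pg Carbon content per cell in pg C.
#' @return A tibble with `cell_loss_per_ml_day`, `flux_pg_c_per_ml_day` and
#'   `flux_ug_c_per_l_day`.
#' @export
demise_carbon_flux <- function(abundance_t1, abundance_t2, days_between,
                               carbon_per_cell_pg) {
  if (days_between <= 0) stop("days_between must be > 0", call. = FALSE)
  loss <- (abundance_t1 - abundance_t2) / days_between
  if (loss < 0) {
    warning("population grew between the two time points; flux set to 0")
    loss <- 0
  }
  flux_pg <- loss * carbon_per_cell_pg
  tibble::tibble(cell_loss_per_ml_day = loss,
                 flux_pg_c_per_ml_day = flux_pg,
                 flux_ug_c_per_l_day = flux_pg * 1e-3)
}

#' Normalize carbohydrate microarray signals
#'
#' Replicate spots are averaged, the highest mean signal in the data set is
#' set to 100, all other values are scaled accordingly, and normalized
#' values below the cutoff are zeroed.
#'
#' @param signal A numeric matrix (antibodies x extracts) of mean signal
#'   intensities, or a 3-d array whose third dimension holds replicate spots
#'   (averaged first).
#' @param cutoff Post-scaling cutoff in arbitrary units (default 5).
#' @return The normalized matrix, maximum exactly 100.
#' @export
normalize_microarray <- function(signal, cutoff = 5) {
  if (length(dim(signal)) == 3) signal <- apply(signal, c(1, 2), mean)
  signal <- as.matrix(signal)
  if (any(signal < 0)) stop("signals must be non-negative", call. = FALSE)
  m <- max(signal)
  if (m <= 0) stop("all-zero signal matrix", call. = FALSE)
  out <- signal * (100 / m)
  out[out < cutoff] <- 0
  out
}
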