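# bloomcarbon

Quantifying how viral infection redirects carbon during coccolithophore
blooms.

When a bloom of the calcifying alga *Emiliania huxleyi* is terminated by
its lytic virus EhV, the fate of the bloom's carbon changes: infected
cells release more transparent exopolymer particles (TEP, acidic
polysaccharides that drive aggregation and sinking) and more particulate
inorganic carbon (PIC, the calcite of their coccoliths), while the
community of organic-matter recyclers — heterotrophic bacteria and
eukaryotic osmotrophs such as thraustochytrids — is reshuffled.
`bloomcarbon` implements the analysis pipeline for multi-enclosure
mesocosm experiments that measure these effects, plus a synthetic-data
generator so every stage is testable without any external dataset.

The package is written for ecologists and biogeochemists analyzing
per-enclosure time series: tidy tibbles in, tidy tibbles out, pipeable
verbs, `tidy()`/`glance()` methods on fitted objects, and `autoplot()`
methods for the main result types.

## The core model

Extracellular carbon pools are modeled as a recursive production–loss
balance on a daily grid,

    C(t) = (1 - d) C(t-1) + Σᵢ aᵢ Xᵢ(t),

with producers Xᵢ (for TEP: *E. huxleyi* E, naked nanophytoplankton N,
picophytoplankton P, in cells/mL), per-cell daily production rates aᵢ ≥ 0,
and a daily loss fraction d ∈ [0, 1). The recursion unrolls to
C(t) = Σ_{t'≤t} (1-d)^(t-t') Σᵢ aᵢ Xᵢ(t'), so for fixed d the fit is a
non-negative least-squares regression on discounted producer kernels; d is
chosen by scanning a grid and maximizing R². PIC uses the same loss term
but produces only on net host increases: PIC(t) = (1-d) PIC(t-1) +
a_E max(E(t) − E(t−1), 0).

On top of the pool models sits an infected-subpopulation analysis: with a
measured infected fraction f(t), bystander cells produce T per cell (fixed
from the least infected uncovered enclosures) and infected cells I × T;
the multiplier I is chosen by minimizing the squared deviation of the
two-subpopulation prediction from the observed pool.

Around that core the package provides Bray–Curtis turnover-rate fits,
cosine k-means succession clustering with silhouette-based cluster-count
selection, per-enclosure divergence, a Mann–Whitney differential-abundance
screen, trophic-trait aggregation, log-linear growth-rate fits with
shifted windows, paired-dilution growth/grazing/viral-lysis rates, and
ddPCR/biomass/carbon-budget conversions.

## Worked example

Generate a noise-free synthetic mesocosm experiment (7 enclosures, 24
days, two bloom peaks, a three-orders-of-magnitude viral-load gradient)
and fit the TEP model jointly across enclosures:

```r
library(bloomcarbon)

sc  <- mesocosm_scenario(noise_cv = 0, seed = 1)
ex  <- generate_experiment(sc)
fit <- fit_carbon_model_set(ex$chemistry, ex$abundances, "TEP",
                            c(ehux = "ehux", nano = "nano", pico = "pico"))
glance(fit)
#> # A tibble: 1 × 4
#>   variable      d    r2 n_bags
#>   <chr>     <dbl> <dbl>  <int>
#> 1 TEP      0.0925 0.999      7
```

The shared loss fraction lands just below the generating value 0.12
because the generator's infected cells secrete extra TEP (a deliberate
model misspecification at the population level); the full pipeline
resolves it by partitioning the host population:

```r
report <- run_pipeline(experiment = ex)
report
#> Mesocosm analysis pipeline report
#>   TEP: shared d = 0.0925, pooled R^2 = 0.9992
#>   POC: shared d = 0.1000, pooled R^2 = 1.0000
#>   CSP: shared d = 0.1500, pooled R^2 = 1.0000
#>   PIC: shared d = 0.0075, pooled R^2 = 1.0000
#>   infected-cell production multiplier I = 4.00
#>   succession clusters: 5
```

The recovered multiplier I = 4 and the PIC loss fraction 0.0075 equal the
generating truth exactly. Assay-level arithmetic is equally direct:

```r
cell_carbon(2.5)                     # 2.5 µm spherical cell, 220 fg C/µm³
#>   volume_um3 carbon_fg
#> 1       65.4     14398
demise_carbon_flux(57000, 18900, 2, 14.398)
#>   cell_loss_per_ml_day flux_pg_c_per_ml_day flux_ug_c_per_l_day
#> 1                19050              274282.                274.
copies_per_cell(40)                  # 18S rDNA copies at 40 Mb genome
#> [1] 64
```

A bloom losing 19,050 cells/mL/day at 14.398 pg C/cell releases about
274 µg C/L/day — the scale of dissolved carbon made available to
recyclers during demise.

A thin command-line wrapper (`inst/cli/bloomcarbon.R`) exposes `simulate`
and `run-all` subcommands over the same functions, and the methods
vignette (`vignettes/carbon-models.Rmd`) documents the models,
assumptions, defaults and limitations.

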