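# mineralkin

Kinetic analysis of cumulative ¹⁴CO₂ mineralization curves from soil
respirometry.

When a ¹⁴C-labelled pollutant (here phenanthrene, a three-ring PAH) is
incubated in soil slurries, the ¹⁴CO₂ evolved by microbial mineralization is
captured in an alkali trap and counted, giving a rising curve of cumulative
% of applied ¹⁴C over time. Bioremediation studies compare such curves
across treatments — untreated control, nutrient biostimulation,
bioaugmentation with a degrading strain, cyclodextrin (HPBCD)
bioavailability enhancement — by fitting kinetic models and reporting
half-times and goodness of fit. `mineralkin` is for environmental
microbiologists and soil scientists who need that analysis reproducible and
scriptable.

## What it computes

Three cumulative mineralization models, rising from 0 towards an amplitude
$M_{max} \le 100$:

* **SFO** — single first-order, $M(t) = M_{max}(1 - e^{-k_1 t})$;
* **FOMC** — first-order multi-compartment (Gustafson–Holden),
  $M(t) = M_{max}(1 - (1 + t/\beta)^{-\alpha})$;
* **HS** — hockey-stick: rate $k_1$ to a breakpoint $t_b$, then $k_2$.

For each curve the package gives bounded least-squares estimates
(seeded multi-start + polish, bit-reproducible), dissipation times by
closed form with an independent numeric-root oracle, e.g.
$DT_{50}^{FOMC} = \beta(2^{1/\alpha} - 1)$, and the χ² minimum error level

$$\mathrm{err}\% = \frac{100}{\bar O} \sqrt{\frac{\sum_i (O_i - C_i)^2}{\chi^2_{m-p,\,0.95}}},$$

with the conventional < 15% acceptability rule driving per-curve model
selection. A synthetic respirometry generator reproduces the experimental
design (triplicate flasks, 450 Bq and 50 mg kg⁻¹ applied, 120-day horizon,
additive counting noise) from a shipped truth map of published kinetic
parameters, so the full pipeline runs without any raw data. Helpers cover
the surrounding assay arithmetic: serial-dilution CFU g⁻¹ counts,
extractability percentages, and HPBCD dosing at a molar ratio.

## Worked example

Regenerate the CR-soil arm of the study (five treatments, triplicates,
σ = 1.5% counting noise), fit all three models per curve and keep the best
by χ² error:

```r
library(mineralkin)

truth <- published_truth(soils = "CR")                       # shipped preset
study <- simulate_study(study_config(truth = truth, seed = 42))
fits  <- fit_study(study, seed = 42)
format_fit_table(fits)
#> # A tibble: 5 × 11
#>   soil  treatment kinetic_model k1      k2      tb    alpha beta  dt50  extent_pct chi2_error_pct
#> 1 CR    A         HS            1.3e-02 2.1e-04 99.9  -     -     53.0  12.5       ...
#> 2 CR    B         SFO           5.7e-03 -       -     -     -     122   14.3       ...
#> 3 CR    C         FOMC          -       -       -     4.4   135   23.0  86.7       ...
#> 4 CR    D         FOMC          -       -       -     0.39  3.3   16.1  76.5       ...
#> 5 CR    E         FOMC          -       -       -     0.68  12.7  22.3  80.2       ...
```

Reading the table: the HPBCD-amended treatments (C–E) mineralize 76–87% of
the applied ¹⁴C in 120 days and are best described by FOMC kinetics with
half-times of 16–23 days, while the control (A) and nutrient-only (B)
curves stay below 15% — their half-times are extrapolations far beyond the
study horizon, which is why slow-curve model identities are not trustworthy
(see the vignette). Per-fit detail follows broom conventions:

```r
glance(fits$fit[[3]])[, c("model", "dt50", "dt90", "chi2_error_pct", "extent_observed")]
#>   model  dt50  dt90 chi2_error_pct extent_observed
#> 1 FOMC   23.0  92.8          0.997            86.7

dt_x(kin_params("FOMC", alpha = 2.0, beta = 64.4), x = c(50, 90))
#>       x value method      basis
#> 1    50  26.7 closed_form applied
#> 2    90 139.  closed_form applied
```

`autoplot()` on a fit draws observed-vs-fitted curves;
`plot_study_curves()` shows a whole study faceted by soil. A thin CLI
(`inst/cli/mineralkin`, or `mineralkin_cli()` in-process) wraps the same
functions: `simulate`, `fit`, `recover` (parameter-recovery experiment)
and `report`.

## Acceptance script

`scripts/acceptance.R` recomputes, from the installed package at run time,
the closed-form FOMC dissipation-time checks against published kinetic
parameters (the `dt_x` route shown above) and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
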