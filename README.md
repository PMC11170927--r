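# warmtrait

Tools for asking whether experimental soil warming acts differently on
soil microbial communities — and on the heterotrophic respiration (Rh)
they drive — in cool months than in warm ones. The package is aimed at
soil microbial ecologists and ecosystem modelers working with paired
warmed/control plot designs sampled monthly over a year.

It implements, end to end:

- **Community rrn copy number trait.** Per-ASV rRNA operon copy numbers
  assigned from an rrnDB-style lookup at the lowest confident (> 50%)
  taxonomic rank with child/parent fallback, aggregated per sample as

  &nbsp;&nbsp;&nbsp;&nbsp;*community rrn* = Σᵢ Sᵢ / Σᵢ (Sᵢ / nᵢ),

  where Sᵢ are read counts and nᵢ copy numbers (reads over implied
  organisms), compared between treatments by paired log-ratios
  ln(warmed/control). High values mark fast-growing, copiotrophic
  communities.
- **Season segmentation** of the year into early cool / warm / late cool
  from the first-derivative extrema of a smooth fit to monthly
  temperature.
- **Functional-gene microarray analysis**: spot QC (CV > 0.8, batch-wise
  SNR floors 7 / 3.5, minimum intensity 100, 50% detection), two-step
  between-array normalization, log response ratios rr = ln(x̄_w / x̄_c)
  with delta-method 95% CIs, and four-way probe classification.
- **A microbial-enzyme decomposition model** (MEND-type; ten pools,
  enzyme-mediated Michaelis–Menten decomposition, Monod uptake, dormancy)
  with intrinsic carbon use efficiency Yg(T) = Yg_ref + k_Yg (T − T_ref),
  calibrated against monthly Rh and gene-abundance series by minimizing
  J = w₁(1 − R²_Rh) + w₂(1 − r_EnzCo) + w₃(1 − r_EnzCh) with **SCE-UA**,
  and parameter uncertainty from the **Critical Objective Function
  Index**, J_cr = J_opt (1 + p/(n−p) · F₀.₀₅,p,n−p).
- **A first-order (CENTURY/TECO-type) baseline model** calibrated by
  Metropolis–Hastings MCMC, for R² comparison against the microbial model.
- **CUE temperature-sensitivity analytics**: per-treatment k_Yg slopes,
  their relative change under warming, and the crossover temperature
  T\* = T_ref + (Yg_ref,c − Yg_ref,w)/(k_w − k_c).

A seeded synthetic-data generator emulates the statistical structure of a
4-block × 12-month × 2-treatment field campaign (96 samples), so every
stage runs and is tested without external data.

## Worked example

```r
library(warmtrait)

design  <- study_design(seed = 1)          # 4 blocks x 12 months x 2 treatments
forcing <- gen_forcing(design)             # paired daily T / moisture / GPP

# 1. data-driven season boundaries from the site climatology
derive_partition(fit_annual_curve(site_climatology()))
#> Season partition (fastest rise between months 2 and 3 | fastest fall between 9 and 10 )
#>   early_cool Jan Feb
#>   warm       Mar Apr May Jun Jul Aug Sep
#>   late_cool  Oct Nov Dec

# 2. community rrn trait with a +0.12 cool-season log-effect implanted
com    <- gen_community(design, n_asvs = 300,
                        warming_trait_effect = c(early_cool = 0.12,
                                                 warm = 0, late_cool = 0.12))
traits <- trait_summaries(com$counts,
                          assign_rrn(com$taxonomy, com$lookup), design)
seasonal_trait_test(traits)
#>   season     n_pairs mean_warmed mean_control mean_difference  p_value
#> 1 early_cool       8        2.22         1.97         0.255   2.50e-10
#> 2 late_cool       12        2.22         1.97         0.255   6.76e-18
#> 3 warm            28        1.97         1.97        -0.00204 1.58e- 1

# 3. calibrate the decomposition model against synthetic monthly Rh + genes
fc    <- dplyr::filter(forcing, treatment == "control")
truth <- mend_params(Yg_ref = 0.43, k_Yg = -0.0035)
obs   <- gen_rh_observations(truth, fc, noise_sd = 0.07, seed = 2)
cal   <- calibrate_mend(obs, fc, base_params = truth,
                        budget = 2000, seed = 3)
cal
#> gMEND calibration (3 free parameters)
#> SCE-UA fit: J_opt = 0.0035513 after 1101 evaluations (converged)
#>   Yg_ref     k_Yg      V_g
#>  0.42485 -0.00374  0.22103
#> COFI: J_opt = 0.0035513  J_cr = 0.0081237  feasible points: 891

# 4. CUE temperature sensitivity of a calibrated treatment pair
cue_report(mend_params(Yg_ref = 0.4293, k_Yg = -0.0025), truth, forcing)
#> CUE temperature-sensitivity report
#>   intrinsic k_Yg (warmed, control): -0.0025 -0.0035
#>   relative change (intrinsic): 28.6%
#>   crossover temperature: 15.70 degC
```

Reading the numbers: the warmed plots' community trait exceeds control by
~0.25 copies only in the cool seasons (paired t-tests; the warm-season
difference is indistinguishable from zero) — the implanted effect
recovered from counts. The calibration recovers the generating CUE
parameters (Yg_ref 0.425 vs truth 0.430) with an R² of 0.998 on monthly
Rh, and the COFI threshold bounds the feasible parameter region used for
the coefficient-of-variation summaries. The warmed CUE line is 28.6% less
temperature-sensitive than control and crosses it at 15.7 °C: below that
temperature warming lowers CUE (more C respired per unit taken up),
above it the difference reverses.

`run_pipeline(pipeline_config(seed = 1))` chains every stage — generation,
traits, seasons, microarray, both calibrations, CUE report — into one run
directory with a checksum manifest; reruns with the same config are
byte-identical. `autoplot()` methods cover partitions, response-ratio
records, simulations and CUE reports; fitted objects have broom-style
`tidy()`/`glance()` methods.

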