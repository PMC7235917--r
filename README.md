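# graftquant

Background-referenced quantification of ^18^F-sodium-fluoride (NaF) PET/CT
uptake in posterolateral spinal bone grafts.

After non-instrumented lumbar fusion surgery, NaF-PET shows where new bone
mineral is being laid down long before structural fusion is visible on CT.
`graftquant` is for imaging researchers who want to quantify that graft
uptake reproducibly: instead of an absolute SUV cutoff, the patient's own
erector-spinae muscle — sampled in a cylindrical VOI restricted to a
0–250 HU CT window — supplies the background reference, and its SUVpeak
(mean of the hottest 1 cm³) becomes the patient-specific fixed lower
threshold for segmenting the graft VOIs. The package scripts the whole
procedure end to end and ships a digital phantom generator and cohort
simulator so every stage is testable against known ground truth.

## The method

For PET activity `C` (Bq/mL), body weight `w` (g) and injected dose `D₀`
decay-corrected to scan start with `T½ = 110` min:

```
SUV        = C / (D(t_scan) / w),      D(t) = D₀ · 2^(−Δt / T½)
threshold  = combine(SUVpeak_muscle_L, SUVpeak_muscle_R)     (default: mean)
graft mask = { v ∈ VOI : SUV(v) ≥ threshold },  26-connected components ≥ 1 cm³
SUVtotal   = SUVmean × volume (SUV·mL),  summed over levels and sides
cSUVtotal  = partial-volume-corrected SUVtotal:
             corrected mean = (observed mean − B·(1−r)) / r
```

where `r` is the in-mask mean of the Gaussian-PSF-convolved mask indicator
and `B` the background SUV from a shell around the mask. Cohort analysis
follows the explorative design of small fusion studies: median [min, max]
by fusion status, univariate logistic odds ratios with Wald 95% CIs, and
Spearman correlation of uptake with one-year change in each clinical score
(WLK-D, VAS-B, VAS-L, TAN, ODI, EQ-5D).

## Worked example

Quantify a synthetic patient with bilateral 4 cm³ grafts at true SUV 5 on a
true muscle background of SUV 1 (so the true summed graft uptake is
2 × 5 × 4 = 40 SUV·mL):

```r
library(graftquant)
pp  <- phantom_patient(noise_scale = 0.01, seed = 11)
res <- run_patient(pp$entry)
round(as.numeric(res$threshold), 3)
#> [1] 1.006
print(res$metrics, digits = 4)
#>          id      voi level   role volume_ml suv_mean suv_max suv_peak suv_total c_suv_total
#> 1 phantom01 muscle_L     1 muscle    19.968   0.8872   1.307   1.0120        NA          NA
#> 2 phantom01 muscle_R     1 muscle    19.968   0.8883   1.264   0.9993        NA          NA
#> 3 phantom01  graft_L     1  graft     7.840   2.6149   5.460   4.6821     20.50       25.79
#> 4 phantom01  graft_R     1  graft     7.824   2.6098   5.398   4.6487     20.42       25.68
#> 5 phantom01    total    NA  total    15.664       NA      NA       NA     40.92       51.46
```

The muscle SUVpeaks (1.012 and 0.999) bracket the true background of 1, and
the summed `SUVtotal` of 40.92 SUV·mL recovers the true 40 SUV·mL within
2.3% — the segmented volume exceeds the true 4 cm³ per side because the
threshold sits near background, but the blur-conserved activity brings the
total back to truth. `cSUVtotal` is larger, as the partial volume
correction compensates spill-out from the hot graft cores.

Cohort statistics on a simulated 18-patient study:

```r
ch  <- generate_cohort(cohort_spec(n = 18, seed = 6))
out <- run_cohort(ch)
print(out$report)
#> timepoint  variable  fused (n=5) med [min,max]  unfused (n=13) med [min,max]  OR [95% CI] (per unit)  p
#> baseline   age       65.2 [63.9, 76.2]          71.1 [61.5, 77.8]             0.92 [0.759, 1.11]      p=0.39
#> baseline   bmi       27.4 [22.5, 34.1]          27.5 [22.8, 34.3]             1.08 [0.807, 1.44]      p=0.61
#> ...
head(out$spearman, 3)
#>   uptake_metric variable    rho      p  n
#> 1     suv_total    wlk_d  0.540 0.0208 18
#> 2     suv_total    vas_b -0.203 0.4184 18
#> 3     suv_total    vas_l  0.273 0.2722 18
```

A thin command-line wrapper lives at `inst/cli/graftquant.R` with
subcommands `phantom`, `quantify`, `stats` and `run-all`, driven by a YAML
run config (image paths, calibration, VOI placements, manual rigid
adjustment, method parameters).

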