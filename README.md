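# bnmi

Wavelength selection for multivariate near-infrared (NIR) calibration by
**binning-normalized mutual information (B-NMI)**, with the classical
selectors it is usually benchmarked against and the full evaluation
machinery of a chemometric calibration study.

## The problem

Quantitative NIR analysis regresses a reference property — moisture mass
fraction, octane number, protein content — on a full absorbance spectrum
`X (m samples × n wavelengths)` with partial least squares (PLS). Most
spectral channels carry background or redundant signal; selecting the
informative wavelengths yields smaller, more robust, more interpretable
models. B-NMI ranks wavelengths by an information-theoretic relevance score
that captures linear *and* nonlinear dependence:

1. **Equal-interval binning.** Each variable (every absorbance column and the
   reference `y`) is discretized into `B` bins of width
   `B_wid = (D_max − D_min) / B`, damping minor measurement error.
2. **Normalized mutual information.** For each wavelength `i`,
   `NMI(X_i, Y) = 2·MI(X_i, Y) / (H(X_i) + H(Y)) ∈ [0, 1]`
   (symmetrical uncertainty), with
   `MI(X, Y) = H(X) − H(X|Y) = Σ_ij p_ij log2 [p_ij / (p_i p_j)]`.
3. **Forward accumulation.** Wavelengths are sorted by descending NMI and
   added one at a time to a PLS model (latent variables re-tuned by
   leave-one-out cross-validation at every step); the prefix with the
   smallest validation RMSEP is kept.
4. **Exhaustive bin enumeration.** Steps 1–3 repeat for every `B` in a grid
   (2 up to twice the calibration sample count); the `(B, k)` pair with the
   globally smallest RMSEP wins.

Also included: the five baseline selectors (correlation coefficient, VIP,
UVE, CARS, backward-interval PLS), a SIMPLS PLS1 engine with LOOCV,
Kennard–Stone splitting, SNV/mean-centering preprocessing, the
`RPD = SD_actual / RMSEP` metric set, F-test model comparison, and a
Beer–Lambert synthetic mixture generator with ground-truth informative
bands.

## Worked example

Two-band synthetic fixture: a three-component liquid mixture whose target
component absorbs at 1450 and 1940 nm (water-like bands), 60 samples,
200 wavelengths, 0.002 AU noise.

```r
library(bnmi)

spec <- two_band_spec()                                # seeded generator spec
ds   <- ks_assign(generate_dataset(spec), fraction = 0.75)  # Kennard-Stone split
res  <- bnmi_select(ds, stride = 8, lv_cap = 8)
res
#> <selection_result> method: B-NMI
#>   selected 129 of 200 wavelengths (bin count 50)
#>   RMSEP 0.0003348, RPD 94.83, 3 LV

recovery_score(res, spec)
#> # A tibble: 1 x 4
#>   n_selected n_informative precision recall
#> 1        129            42     0.287  0.881

full <- full_spectrum_pls(ds, lv_cap = 8)
comparison_table(list(res, full), n_val = 15)[,
  c("method", "r2_pred", "rmsep", "rpd", "n_vars", "n_lv")]
#>   method    r2_pred    rmsep   rpd n_vars  n_lv
#> 1 B-NMI       1.000 0.000335  94.8    129     3
#> 2 Full-PLSR   1.000 0.000408  77.8    200     3
```

The winning bin count is 50; the 129-wavelength prefix captures 88% of the
truly informative channels and predicts the target concentration (range
0.02–0.12 mass fraction) with RMSEP 3.3·10⁻⁴ — better than the
full-spectrum model under the same latent-variable rule. `plot_nmi_profile(res)`
and `plot_rmsep_curve(res)` draw the relevance profile and the
falls-then-rises accumulation curve; `tidy(res)` / `glance(res)` give the
per-wavelength and one-row summaries.

Real datasets enter through `read_spectra_csv()` (wavelengths as column
headers, one reference column); `run_pipeline(run_config(...))` executes
every configured selector on one split and writes a full artifact directory.
A thin CLI wrapper lives at `inst/cli/bnmi.R`
(`Rscript inst/cli/bnmi.R synth|select|compare ...`).

## Acceptance script

`scripts/acceptance.R` recomputes the package's analytic anchors from
scratch — NMI of a discretized series with itself, NMI of an exactly
factorized joint, and the maximum NMI over 1,000 seeded random series pairs —
and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
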