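---
title: "Methods: binning-normalized mutual information wavelength selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binning-normalized mutual information wavelength selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnmi)
```

## The model and its assumptions

Multivariate NIR calibration assumes the absorbance spectrum is, to a good
approximation, bilinear in the analyte concentrations (Beer–Lambert mixing)
plus baseline and noise, and that a PLS1 regression on a subset of
wavelengths can predict the reference property. Wavelength selection rests
on a second assumption: relevance is a per-channel property that can be
scored against the reference before modeling.

B-NMI scores each wavelength by normalized mutual information after
equal-interval discretization:

* binning: a variable with range $[D_{min}, D_{max}]$ is cut into $B$ bins
  of width $(D_{max}-D_{min})/B$; both the absorbance columns and the
  reference use the *same* $B$, each on its own calibration-row range;
* entropies are plug-in estimates in bits
  ($H = -\sum p \log_2 p$, $0\log 0 = 0$);
* $\mathrm{NMI} = 2\,\mathrm{MI}/(H(X)+H(Y))$, the symmetrical uncertainty,
  lies in $[0,1]$ and removes MI's bias toward high-cardinality variables.
  Two algebraically equivalent MI routes (entropy difference and the
  double sum over the joint histogram) are both implemented and
  cross-checked to $10^{-9}$; normalization happens only at the NMI stage.

The selection loop sorts wavelengths by descending NMI (ties broken by
ascending index for determinism), forward-accumulates them into PLS models
with the latent-variable (LV) count re-tuned by leave-one-out
cross-validation at every step, and records the validation RMSEP at each
prefix size. The bin count is not fixed a priori: the grid
$B \in \{2, \dots, 2 m_{cal}\}$ is enumerated exhaustively — "twice the
number of samples" is read as the *maximum* of the iteration, not a fixed
setting — and the globally minimal-RMSEP $(B, k)$ pair is returned.

## Tunable parameters

| Parameter | Default | Rationale |
|---|---|---|
| bin grid | $2..2m_{cal}$, `stride` 1 | exhaustive enumeration; a stride of 4–8 coarsens the grid for speed with little loss, since neighbouring $B$ give near-identical rankings |
| selection objective | validation RMSEP | the procedure's stated objective; `objective = "rmsecv"` is provided because selecting on the validation set leaks information into the subset choice — the default is faithful, the alternative is clean |
| LV rule | parsimonious, 2% tolerance | "smallest RMSECV or its inflection point": the smallest LV count within 2% of the curve minimum; `global_min` available |
| `lv_cap` | 10 | LOOCV is re-run at every accumulation step; real NIR models in this setting use 3–8 LVs |
| RMSE divisor | $m$ | the conventional definition. The printed formula divides by $m-1$, but the tabulated RPD values are consistent with divisor $m$ given the validation-set standard deviations, so $m$ is the default and `rmse_divisor = "m-1"` is exposed |
| UVE noise amplitude | $10^{-10}\max|X|$ | near-null perturbation, the customary choice |
| CARS runs | 50, 80% Monte-Carlo sampling | canonical settings; retention follows $r_i = a e^{-ki}$ with $r_1 = 1$, $r_N = 2/n$ |
| BIPLS intervals | 20 | conventional interval count |

## Numerical choices and degenerate inputs

* **Binning edges.** Interior edges are $D_{min} + jB_{wid}$; the top edge
  is pinned to $D_{max}$ exactly (guarding against floating-point drift) and
  the last interval is closed so the maximum is binnable. Intervals are
  otherwise left-closed.
* **Constant columns** get NMI 0 with a warning (dead instrument channels
  should not abort a run); a constant *reference* is an error — there is
  nothing to select for.
* **Rank exhaustion.** SIMPLS stops extracting components when the residual
  covariance norm underflows; LOOCV folds reuse the last extractable
  component's predictions for higher LV counts.
* **Ties.** Equal NMI: lower wavelength index first. Equal RMSEP along the
  accumulation curve: smallest prefix. Equal minimum across the bin grid:
  first (smallest) $B$. Kennard–Stone distance ties: lowest row index.
  All choices exist purely for replayability.
* **Determinism.** The stochastic stages (UVE noise, CARS sampling,
  synthetic generation) run under a locally seeded RNG that restores the
  caller's state, so a pipeline replay is byte-identical.

## The synthetic generator

`synthetic_spec()` states a mixture world: Gaussian-band pure-component
spectra, concentrations drawn uniformly within per-component ranges
(optionally closed to a constant total, as in constant-volume mixture
designs), a per-sample linear baseline, and iid Gaussian absorbance noise.
The default `two_band_spec()` fixture emulates a ternary liquid system: the
target absorbs at 1450 and 1940 nm (the water O–H first overtone and
combination bands), two interferents absorb elsewhere, 60 samples on
200 points over 1000–2500 nm, noise 0.002 AU. Unstated physical constants
were fixed once at field-typical values: band widths 30–45 nm, amplitudes
0.4–1.2 AU, baseline offset/slope 0.01/0.005 AU.

What it does *not* emulate: wavelength-correlated (pink) instrument noise,
stray light, scattering nonlinearity, temperature-dependent band shifts,
and reference-method error. A green recovery test therefore establishes
that the implementation ranks and accumulates correctly in a bilinear,
well-posed world — not that B-NMI outperforms alternatives on any real
instrument's data.

One subtlety of the closed (constant-total) design: interferent
concentrations are negatively correlated with the target, so interferent
bands legitimately carry reference information. Ground-truth recovery is
scored against the *target's* bands only, which makes precision
conservative on closed fixtures; recovery tests that need an unambiguous
mask use an open (unclosed) three-component fixture.

## Design decisions taken where the procedure was open

* **NMI on raw spectra.** Equal-interval binning on per-variable ranges is
  exactly invariant to per-variable affine maps, so mean centering cannot
  change an NMI ranking; rankings are computed on raw calibration
  absorbances. SNV (a per-sample transform) *can* change them and is applied
  before binning when enabled.
* **Per-B re-ranking.** The NMI profile depends on $B$, so the ranking is
  recomputed for every grid point rather than fixed once.
* **One $B$ for X and y.** A single bin count is shared by the spectra and
  the reference, the simplest faithful reading of a single $B$ parameter.
* **F-test construction.** Model comparison uses the two-tailed
  variance-ratio test $F = (\mathrm{RMSEP}_{large}/\mathrm{RMSEP}_{small})^2$
  with $(n_{val}-1, n_{val}-1)$ degrees of freedom — the standard reading of
  an F-test on RMSEP values at 95% confidence. Published per-dataset
  p-values obtained with unreported constructions are not reproduction
  targets.
* **Baseline selectors.** CC, VIP, UVE, CARS and BIPLS follow their
  canonical published algorithms with the stated objectives (RMSECV for
  CARS/BIPLS); free constants are exposed as configurable defaults. All
  selectors share the split, preprocessing and LV rule of the B-NMI run for
  a fair comparison, and emit the same `selection_result` contract.

## Known limitations

* The exhaustive $B$ grid with per-step LOOCV is $O(|grid| \cdot n \cdot
  m_{cal})$ PLS fits; on a single CPU a 200-wavelength, 45-sample problem
  takes a couple of minutes at stride 4. Use `stride`/`bin_grid` to trade
  search resolution for time.
* Selecting the prefix on validation RMSEP (the faithful default) uses the
  validation set twice; reported RMSEP for the winning subset is therefore
  mildly optimistic. Use `objective = "rmsecv"` for an unbiased protocol.
* Plug-in entropy estimates are biased upward at large $B$ relative to the
  sample size (null NMI of order $(B-1)^2/(2m\ln 2)$ against $H$); the NMI
  profile is a ranking device, not an unbiased dependence estimate.
* PLS1 only (single reference property); no PLS2, kernel PLS, or
  derivative/MSC preprocessing.
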