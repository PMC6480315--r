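---
title: "Methods: CDOM, spectral slope, and DOC retrievals from ocean color"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CDOM, spectral slope, and DOC retrievals from ocean color}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oceancdom)
```

This vignette is the package's own account of the models and procedures it
implements, the choices that were genuinely open, and what the test suite
does and does not demonstrate.

## The exponential CDOM model and slope fitting

CDOM absorption is modeled as a single exponential decay,
$a_g(\lambda) = a_g(\lambda_0)\,e^{-S_g(\lambda-\lambda_0)}$, accurate
within limited wavebands.  Because $S_g$ depends on the window, the package
fits it over the eight ranges in common use (`slope_windows()`): seven
hyperspectral ranges from 275–295 nm up to 412–600 nm, plus the six-band
multispectral 412–555 nm range used for filter-wheel instruments.

Two conventions matter and are fixed deliberately:

* **Fitting scale.** The least-squares objective is evaluated on the
  *untransformed* absorption, $\sum(a_g - \hat a_g)^2$, which weights the
  short-wavelength samples where absorption is largest and best measured.  A
  linear regression of $\log a_g$ would weight all wavelengths equally and
  is biased by the noisy long-wavelength tail; a regression test asserts
  that the two conventions disagree on noisy data.
* **Reference wavelength.** $\lambda_0$ is the window minimum — the shortest
  wavelength in the spectral range — and the fitted amplitude is reported
  there.

Numerical choices: Levenberg–Marquardt via `minpack.lm`, starting from
$S_g = 0.015$ nm$^{-1}$ (mid-range of the 0.005–0.05 nm$^{-1}$ plausibility
band) and the measured value nearest $\lambda_0$; convergence at a relative
residual-sum-of-squares change of $10^{-10}$ or 500 iterations, with
non-convergence reported on the `slope_fit` object rather than raised.
Window membership is inclusive at both endpoints, fewer than three in-window
points is an error, and all in-window samples are used (no subsampling).
When a window's lower bound is not covered by the spectrum the window is
skipped with a reason, since the reference wavelength would be extrapolated.

## The empirical MLR retrievals

The retrieval form is
$\ln \Upsilon = \beta_0 + \sum_{i=1}^{4}\beta_i \ln R_{rs}(\lambda_i)$ with
sensor-specific bands (MODIS 443/488/531/547 nm, SeaWiFS 443/490/510/555
nm).  The 31 published coefficient rows — six absorption bands and eight
slope windows per sensor, two reflectance-only DOC rows, and the
absorption-plus-salinity DOC row — are shipped as a delimited registry
(`inst/extdata/mlr_registry.csv`), loaded and verified against an embedded
checksum; the registry is data, not code, and the tests compare every cell
against an independently transcribed golden copy.

Decisions worth flagging:

* **MLR2 response scale.** The absorption-plus-salinity DOC row
  ($\beta_0 = 192.718$, $\beta_{a_g(355)} = 26.790$,
  $\beta_{S} = -3.558$) is applied on the *linear* scale,
  $DOC = \beta_0 + \beta_1 a_g(355) + \beta_2 S$: the printed magnitudes
  only produce realistic DOC (tens of µmol L$^{-1}$ at oceanic salinity) in
  linear space, while a log-log reading yields absurd values.  The transform
  is an explicit registry field, so the reading is overridable.
* **MLR1.** The reflectance-only DOC rows are implemented exactly as the
  ln-response form prints.  For realistic reflectances they produce
  implausible DOC magnitudes; they are shipped for completeness with a
  cautionary note in the registry, and the absorption-plus-salinity route is
  the recommended DOC algorithm.
* **Thresholds.** Absorption retrievals above the published 99th-percentile
  threshold for their band are outside the global algorithm's scope; the
  value is set to missing with `clipped = TRUE`, leaving disposition to the
  caller.
* **The positive 412–555 nm MODIS slope intercept (+4.195)** is unlike every
  other row but is implemented as printed, with a note in the registry.
* **Undefined retrievals.** Non-positive reflectances flag the retrieval
  `undefined` instead of raising, so gridded application continues.
* **Adjusted r².** The printed subtraction form
  $r^{2\prime} = r^2 - (1-r^2)\,\beta_n/(N-\beta_n-1)$ is implemented
  literally.  Algebraically it equals the classical Ezekiel adjustment
  $1-(1-r^2)(N-1)/(N-\beta_n-1)$; a test asserts the identity so the
  equivalence is documented rather than assumed.

`fit_mlr()` provides the same regression for re-tuning: ordinary least
squares in the transformed space, a degenerate-design error naming the
collinear columns on rank deficiency, and a full skill report of the fit.

## Partitioning dissolved and detrital absorption

Semi-analytical inversions retrieve only $a_{dg} = a_d + a_g$.  The
detrital share is estimated from combined absorption and total
backscattering, $a_d(410) = 0.06822\,a_{dg}(410) + 1.623\,b_{bt}(550) +
0.0002123$, and $a_g(410)$ follows by subtraction, floored at zero with a
flag (the published relation is silent on negative remainders).  The
partition is defined at 410 nm and no 410→412 nm shift is applied when
comparing with the 412 nm regression products; expansion to other
wavelengths uses the exponential model with $\lambda_0 = 410$ nm and
(typically) the empirical 412–555 nm slope retrieval.

## Quality control and match-up rules

All thresholds are implemented as stated bounds with these clarifications,
each a deliberate reading where the rule's letter is ambiguous:

* The 676 nm contamination test interpolates the red baseline linearly
  between the means of the 650–665 nm and 705–715 nm samples; a rise of
  0.006 m$^{-1}$ at 676 nm, *inclusive*, rejects the record.
* "Deeper than 5 m" (shelf) and "10 m" (off-shelf) are strict: a sample at
  exactly the cutoff is kept.  Shelf means bottom depth ≤ 1000 m, resolved
  from a caller-supplied bathymetry grid by great-circle nearest neighbor
  (ties to the northwest node) when the record carries none.
* Standard deviations are sample SDs ($N-1$) throughout the QC rules.
* Population filters are single-pass, computed on the whole set, so QC is
  order-stable: permuting records permutes verdicts identically.
* The upper-tail reflectance screen keeps values at or below the 95th
  percentile per band.
* Transect binning to 0.5 km uses a local equirectangular projection about
  the record centroid, binning per calendar day so distinct days never
  merge.
* The satellite time gate is inclusive (Δt = 8 h passes).  Within each 5×5
  array, negatives and pixels beyond 1.5 SD of the array mean are nulled
  first; then the band needs strictly more than 50% of non-land pixels
  valid and at least five valid pixels, and the mean is retained only when
  CV < 0.25 (strict).  L2 flag semantics are represented by the
  caller-supplied flag mask and are not re-implemented.
* Match ensembles discard members beyond 1.5 SD of the ensemble mean in a
  single pass, then require CV ≤ 0.25; the DOC percentile cut precedes
  ensemble averaging, following the assembly narrative's order.

## Skill metrics and diagram coordinates

`compute_skill()` implements RMSD, centered RMSD, signed-centered RMSD,
normalized bias, %Bias, and MAPD with divisor $N$ inside the RMSD-family
definitions, which makes the decompositions exact:
$RMSD^2 = RMSD'^2 + bias^2$ and the Taylor law
$RMSD'^2 = \sigma_m^2 + \sigma_r^2 - 2\sigma_m\sigma_r r$.  For the Taylor
law to hold to machine precision the standard deviations inside
`taylor_coordinates()` use the same divisor $N$; the `std_mod`/`std_ref`
fields of the skill report are conventional sample SDs ($N-1$), used to
normalize the target-diagram axes (which preserves the distance identity
for any common normalizer) and to sign the centered RMSD.  $r^2$ is the
squared Pearson correlation, not a through-origin regression $R^2$.  MAPD
is computed over nonzero references with the excluded count reported.

## Anomalies, residuals, and index correlation

Monthly anomalies are ratios to the per-calendar-month mean over the record
("mission-era" climatology), hence invariant to rescaling the series.  The
Chl−CDOM residual normalizes each composite by its own median over valid
pixels before differencing, so it is invariant to separate positive
rescalings of the two fields and zero wherever they covary proportionally —
the operational test of the Case 1 covariance assumption.  Box averages of
gridded fields are unweighted by default with an optional cos(latitude)
weighting.  Index correlations are Pearson with a two-sided p-value
assuming independent months; no autocorrelation correction is applied, a
known limitation for strongly persistent series such as ENSO indices.

## Synthetic fixtures: what they emulate and what they do not

The generators produce every input class the toolkit consumes with planted
ground truth: exponential CDOM spectra (slopes uniform on the
0.005–0.05 nm$^{-1}$ plausibility band, 412 nm amplitudes lognormal about
0.12 m$^{-1}$, a typical global-database mean, with sdlog 0.6), reflectance
regression sets (ln-reflectances multivariate normal, band means
0.002–0.008 sr$^{-1}$, ln-space SD 0.6 and inter-band correlation 0.4 —
chosen once on sampling-theory grounds so that coefficient recovery at
$n = 10^4$ and ln-noise 0.05 has standard errors well inside 2% of the
planted values), paired station tables with planted in/out-of-window
partners and depth violations, and pixel arrays spanning the full
2$^4$ gate matrix.  One global seed fans out through
`substream_seed()` so adding a generator never perturbs another's draws.

These fixtures establish *correctness of the rules and estimators*, not
field performance: they contain no radiative-transfer structure, no
geographic or seasonal covariance, no instrument artifacts beyond additive
Gaussian noise, and single-exponential CDOM shapes.  Passing tests
therefore show the machinery reproduces its defining equations and rules
exactly, not that retrieval skill on real imagery matches any published
statistic — the published optimization/validation statistics require the
underlying field databases and satellite archives.

Problem sizes used by the tests and the acceptance script (for example
200–1000 synthetic spectra across eight windows, $10^3$–$10^4$ draws for
the evaluation oracle and partition identities) were chosen as the smallest
sets that exercise every rule and estimator while keeping Monte-Carlo error
far from the asserted bounds.

## Known limitations

* MLR1 DOC is shipped as printed but not recommended (see above).
* The 0.5 km binning's equirectangular projection distorts near the poles;
  transects there should be binned in a caller-chosen projection.
* Flag-mask semantics, atmospheric correction, and semi-analytical
  inversion internals are out of scope; the partition consumes their
  outputs.
* p-values in `index_correlation()` ignore serial dependence.
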