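---
title: "Methylation-based age estimation with a tunable log/linear transformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-based age estimation with a tunable log/linear transformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiage)
```

## The model

DNA methylation at a small panel of CpG sites changes predictably with age
and is the basis of forensic "epigenetic clock" models. The complication is
that methylation changes several-fold faster through childhood and
adolescence than in adults, so a straight-line regression of age on
methylation is misspecified at the young end — exactly the ages (minors,
young adults) where forensic age assessment matters most.

`epiage` handles this with a piecewise transformation of chronological age
$y_c$ controlled by an *adult cut-off* $y_{c,adult}$:

$$
f(y_c;\,y_{c,adult}) \;=\;
\begin{cases}
\log(y_c+1) - \log(y_{c,adult}+1), & y_c \le y_{c,adult},\\[4pt]
\dfrac{y_c-y_{c,adult}}{y_{c,adult}+1}, & y_c > y_{c,adult}.
\end{cases}
$$

The transformed value $y_e = f(y_c)$ is the *epigenetic age*: logarithmic
(fast change) below the cut-off, linear above it, with value $0$ and slope
$1/(y_{c,adult}+1)$ matching at the joint, so $f$ is continuous and once
differentiable. Setting $y_{c,adult}=0$ makes $f$ the identity on
non-negative ages, i.e. the standard linear model — it is always carried
along as the baseline. The model itself is ordinary least squares on the
transformed scale,

$$ y_e = \beta_0 + \beta_1 x_1 + \dots + \beta_k x_k + \varepsilon, $$

with $x_j \in [0,1]$ the methylation proportions. Predictions are mapped
back to years through the exact inverse $f^{-1}$ (`horvath_inverse()`),
which is defined for every real input and bounded below by $-1$:
biologically impossible negative estimates are *reported and flagged*, not
clamped, so downstream users can see them.

Ages exactly at the cut-off are assigned to the log branch; both branches
agree there, so the choice is inert, but fixing it keeps results
bit-reproducible.

A slowing of epigenetic aging in the very old (80+) is real but not
modelled: the elderly are too sparse in cohorts of this design to support
a third branch.

## The cut-off as a hyperparameter

Rather than fixing $y_{c,adult}=20$ by convention, `tune_cutoff()` treats
it as a hyperparameter selected by repeated k-fold cross-validation on the
training set (default 10 folds, 100 repeats, grid 0–60 years in steps of
0.1 — the step matches the one-decimal precision at which tuned cut-offs
are meaningfully reported; both are configurable). Held-out errors are
computed **on the chronological scale after backtransformation** — CV RMSE
in "years" is only interpretable there — pooled over the held-out
predictions within a repeat, then averaged over repeats.

Two choices here were genuinely open:

* **Common fold partitions across the grid.** The same per-repeat fold
  assignments are reused for every candidate cut-off (common random
  numbers). This removes fold-assignment noise from the *comparison* of
  cut-offs, which is what the argmin cares about; per-cutoff RMSEs remain
  unbiased. The alternative (fresh folds per cut-off) only adds Monte-Carlo
  noise to the curve.
* **Pooling then averaging.** Within a repeat, errors are pooled over all
  folds before taking RMSE, then repeat-level RMSEs are averaged. The
  alternative (RMSE per fold, then average) weights small remainder folds
  more heavily; pooling weights every *sample* equally.

Fold assignment is a seeded shuffle followed by contiguous chunking, with
remainder samples given one each to the leading folds, so fold sizes never
differ by more than one. Ties in the RMSE curve break toward the smaller
cut-off (the simpler, more-linear model).

`fit_sexwise()` repeats the whole procedure on the male-only and
female-only subsets; sex enters the models only through this
stratification (coded 0 = male, 1 = female at interfaces), never as a
regression covariate. A subset too small to cross-validate is reported as
unavailable without failing the other scopes.

## Prediction intervals

Intervals are formed on the epigenetic scale and both endpoints are mapped
through the monotone $f^{-1}$, so the chronological interval is always
ordered. The default `residual_only` method uses
$\hat y_e \pm z_{1-\alpha/2}\, s$ with the standard-normal quantile and the
residual standard error $s$ — the procedure usable with a published model
for which only $s$ is known. The `leverage_t` method adds the proper OLS
leverage term $\sqrt{1 + x^\top(X^\top X)^{-1}x}$ and a Student-t quantile,
and is available for models fitted in-session (the published fixture
carries no design matrix, so it cannot support leverage).

A structural consequence of the backtransform: the log branch compresses
intervals for subjects estimated to be young, so interval width is
strictly increasing in $\hat y_e$ until the whole interval lies in the
linear branch, where it is constant at $2 z s (y_{c,adult}+1)$.

## Evaluation conventions

`evaluate_model()` fixes several conventions that the field often leaves
implicit:

* **MAD** is the mean of absolute errors; **RMSE** the root mean square.
* **$R^2$** is reported as the squared Pearson correlation between
  predicted and chronological age; the regression-style $1-\text{SSE/SST}$
  differs after backtransformation and is carried as the secondary field
  `r_squared_sse`. Adjusted $R^2$ uses $1-(1-R^2)(n-1)/(n-k-1)$ with $k$
  the number of model markers.
* **Bland–Altman** differences are estimated minus chronological age; the
  SD uses the $n-1$ denominator and the limits of agreement are fixed at
  $\pm 1.96\,\mathrm{SD}$ (not a t quantile).
* The **age-binned table** uses bins $[0,20), [20,40), [40,60), [60,90]$
  and error thresholds 3/4/5/6 years, with the boundary *inclusive*
  ($|e| \le t$). The pooled "All" row is computed on the pooled sample, so
  its MAD is exactly the n-weighted mean of the bin MADs and its
  percentages are count-consistent with the bins.
* `cpg_correlation_screen()` uses pairwise-complete observations per
  marker, so a marker with heavy drop-out is still screened on the samples
  it has (with its reduced `n_used` reported alongside); p-values come
  from the t-distribution on `n_used` − 2 df. Markers with constant values
  or fewer than 3 complete pairs are reported as unavailable rather than
  erroring.

Missing methylation is a first-class state (`NA` in memory, empty cell or
`NA` in files) — never 0, which is a legitimate proportion. Models are
complete-case throughout: no imputation anywhere, matching the practice of
removing a heavily missing marker wholesale (the missingness filter's
default threshold of 0.5 removes a marker missing in two thirds of
samples). How the original 161/69 train/validation split was drawn is not
recorded anywhere we could follow, so `split_train_validation()` defaults
to a seeded simple random split, with age-decade stratification as an
option.

## What the synthetic generator does and does not emulate

`generate_dataset()` inverts the model's direction: it puts the age signal
*into* the markers, $x_{ij} = \mathrm{clip}(b_j + s_j f(a_i; c_i) +
\epsilon_{ij},\,0,\,1)$, with per-sex generative cut-offs available to
emulate sex-specific epigenetic aging. The default configuration mirrors
the emulated study design: 230 donors, 102 male / 128 female exactly, ages
1–88 in whole years (uniform by default; the `"study"` preset skews to a
mean of ~38 via a scaled Beta(1.7, 2.3), matching the only three facts
known about the cohort's age distribution — minimum, maximum, mean), eight
markers whose slope signs reproduce the observed mix of positive and
negative age correlations, and an SST-like marker missing in two thirds of
samples. Default assay noise is 0.03 on the proportion scale, a realistic
replicate spread for minisequencing peak ratios.

What it does *not* emulate: inter-marker noise correlation (noise is
independent per marker), electrophoresis artefacts (peak tables are exact
two-channel ratios), environmental covariates of methylation, and the
old-age slowdown. Clipping to $[0,1]$ introduces mild nonlinearity at the
extremes; the generator records pre-clip values so exactness tests can
exclude clipped samples. Tests passing on this generator therefore
demonstrate that the *pipeline machinery* is correct — transform algebra,
CV selection, interval calibration, metric identities — not that any
particular accuracy level will transfer to real cohorts.

`generate_from_model()` is the complementary forward-direction generator
(draw $x$, add $\varepsilon$ on the epigenetic scale, backtransform to
age): under it OLS is correctly specified, which is what
coefficient-recovery and interval-coverage checks require. Note the
marker-direction generator is an errors-in-variables setting for the
regression, so exact coefficient recovery is only asserted there in the
noise-free case.

## Numerical choices and degenerate inputs

* OLS goes through a pivoted QR; rank deficiency is an error naming an
  aliased column rather than a silent `NA` coefficient.
* Residual SE is $\sqrt{\mathrm{SSE}/(n-k-1)}$; a zero SE yields a
  degenerate interval equal to the point estimate.
* `horvath_inverse()` underflows to exactly $-1$ for inputs below about
  $-43$; tests treat the $>-1$ bound as $\ge -1$ at double precision.
* Methylation tables serialise proportions with 8 significant digits, so a
  write/read round trip is exact to well below $10^{-6}$.
* Seeds: every stochastic operation takes an explicit integer seed and
  restores the caller's RNG state afterwards, so library calls never
  perturb user randomness.

## Problem sizes used in the shipped analyses

The numbered drivers under `analysis/` run the whole workflow on a
study-shaped simulation: 230 samples, grid 0–60 by 0.5 with 25 repeats of
10-fold CV for the tuning stage (the per-cutoff Monte-Carlo standard
errors are already an order of magnitude below the RMSE differences of
interest at 25 repeats; the `cv_config()` default of 100 repeats matches
the emulated protocol). The test suite and `scripts/acceptance.R` use
n = 2000 cohorts for cut-off recovery, n = 2000 for coefficient recovery,
and n = 5000 subjects for interval-coverage checks — sizes at which the
stochastic assertions (cut-off within ±2 years, coverage within ±2
percentage points) are comfortably stable under their fixed seeds.

## Known limitations

* The published seven-CpG fixture supports point predictions and
  residual-only intervals, but not leverage intervals and not re-derivation
  of its coefficients — the original cohort data are not publicly
  deposited, so headline accuracies of that study (MAD ≈ 4.7 y, RMSE ≈
  6.6 y on validation) cannot be recomputed from raw data here.
* Cut-off selection and error reporting share the same cross-validation
  (no nested CV); the held-out validation set plays the role of the
  unbiased check.
* The printed equation of the published model labels one term
  $x_{KLF4}$; the package takes this as the KLF14 marker, the only
  K-family marker in the panel.
* One marker in the emulated design shows strong age correlation computed
  from only the third of samples where it is present; the screen reports
  `n_used` precisely so such cases are visible.
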