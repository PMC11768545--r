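---
title: "Methods: estimating cell wall extensibility and yield threshold from creep tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating cell wall extensibility and yield threshold from creep tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wallmech)
```

## The measurement model

A constant-load creep test extends an isolated cell wall specimen under
a fixed tensile force and records its relative extension over time.
`wallmech` models the analysis of such experiments around a
Lockhart-type linear creep law: above a yield stress $y$ the relative
creep rate grows linearly with wall stress $\sigma$,

$$\dot\varepsilon(\sigma) = \phi\,(\sigma - y), \qquad \sigma > y,$$

and is zero below it. The slope $\phi$ (in % h$^{-1}$ MPa$^{-1}$) is
the *in vitro cell wall extensibility* — how sensitively creep responds
to stress — and the x-intercept $y$ (MPa) is the *in vitro yield
threshold*, the minimal stress at which creep starts. Both are
properties of the wall material, not of the loading geometry, provided
stress is computed per unit of wall cross-section.

The chain from raw data to these parameters involves three measured
quantities with quite different error structures, which drives most of
the statistical choices below:

* *creep traces*: per-specimen time series, ~10 specimens per load;
* *segment dry masses*: ~4 replicates per group, which determine the
  wall cross-section area $A = m/(\rho l)$ and hence the stress
  $\sigma = F/A$ each load generates;
* *derived summary points*: per-load means of creep rate (error from
  specimen scatter) and stress (error from mass replication) — errors
  in **both** coordinates of the rate-vs-stress plot.

## Creep-rate extraction

The relative creep rate of a specimen is the ordinary least-squares
slope of relative extension (%) versus time over a fit window,
converted to % h$^{-1}$. The window is a tunable parameter
(`window`, seconds; default `c(300, 900)`, i.e. the final ten minutes
of a fifteen-minute test). The early part of a trace mixes elastic and
viscoelastic transients with steady creep; restricting the fit to the
later window isolates the quasi-steady regime. Published creep
protocols rarely state the exact estimator (endpoint difference versus
regression slope, and over which interval), so this package fixes a
defensible convention — a regression slope over a configurable, logged
window — rather than guessing a historical one. On noiseless synthetic
traces the estimator recovers the generating rate to better than
$10^{-9}$ relative error, and it is exactly scale-equivariant and
time-shift invariant.

Specimens are never dropped automatically: a configurable $R^2$ floor
(`r2_floor`, default 0) only *flags* poor fits, because creep studies
typically state no exclusion rule and silent filtering would bias
group means.

## Stress from dry mass

With mass in µg, length in mm and density in g cm$^{-3}$, the area in
µm$^2$ is $A = 10^3\, m/(\rho l)$, and stress in MPa is
$\sigma = 10^6\, F/A$ with $F$ in newtons. Defaults: $\rho = 1.5$
g cm$^{-3}$ (the standard literature value for dense wall material;
exposed as `density_g_cm3` because it is an assumption, not a
measurement) and $g = 9.80665$ m s$^{-2}$ (standard gravity).

Because $1/m$ is convex, averaging per-replicate stresses gives a
slightly larger mean than computing stress from the mean mass (Jensen's
inequality; about $+\mathrm{CV}^2$ relatively, i.e. ~0.5% at the ~7%
mass CV typical of these measurements). Both conventions occur in
practice, so `group_stress_table()` implements both; the default
`per_replicate` also yields the replicate SD that the downstream
errors-in-variables fit needs. Rounding happens only in reports;
internal arithmetic is full precision.

## Bootstrap creep rate × stress⁻¹

Creep rate and stress are measured on disjoint specimens, so their
ratio has no paired observations. Each of `n_boot` (default 10,000)
bootstrap replicates draws `resample_size_rates` rates and
`resample_size_stress` stresses independently with replacement
(default 4 and 4 — the stress pool has exactly four members, and using
the same size for the rate pool keeps the two resample means equally
stable) and computes the ratio of resample means. The mean and SD over
replicates are reported. A `mean_of_ratios` variant (elementwise
ratios averaged within each replicate) is provided because the two
estimands differ slightly (again Jensen: $1/\sigma$ is convex);
`ratio_of_means` is the default as the more natural plug-in estimator
of $\bar{\dot\varepsilon}/\bar\sigma$.

Group contrasts treat the two bootstrap distributions as samples:
Welch $t$ from the bootstrap means, SDs and replicate counts, with
Benjamini–Hochberg step-up adjustment (`adjust_fdr()`) across the
whole batch of contrasts, controlling the false discovery rate at
`alpha` (default 0.05). Bootstrap child seeds are derived
deterministically per *condition* (load, pH, inactivation), not per
group, so two groups generated identically remain exactly null under
comparison.

## The errors-in-both-variables fit

With only $N \approx 4$ loads and comparable relative errors on both
axes, ordinary least squares is both attenuated (x-error bias) and
asymmetric in the choice of dependent variable. The package therefore
fits the maximum-likelihood functional relationship (a Deming-type
estimator): minimise

$$S(\alpha, \beta, \xi) = \sum_i
  \frac{(y_i - \alpha - \beta \xi_i)^2}{\sigma_{y,i}^2} +
  \frac{(x_i - \xi_i)^2}{\sigma_{x,i}^2}$$

over the line parameters and the latent true stresses $\xi_i$, with
error variances proportional to the observed squared standard errors.
Two weighting schemes are available: `per_point` (default;
$\sigma_{x,i} =$ `x_se[i]`, $\sigma_{y,i} =$ `y_se[i]`) and `pooled`
(a single variance ratio $\lambda$ from the mean squared SEs, which
reduces to classical Deming regression with its closed-form slope).
The per-point default uses all the information the replication
provides; the pooled option bounds the ambiguity when per-point SEs
are unreliable.

**Numerics.** Each $\xi_i$ and the intercept have closed-form optima
given $\beta$, so the problem reduces to one dimension:
$S(\beta) = \sum_i w_i (y_i - \alpha(\beta) - \beta x_i)^2$ with
$w_i = 1/(\sigma_{y,i}^2 + \beta^2 \sigma_{x,i}^2)$. The minimiser is
found by a dense grid scan over a bracket spanning both OLS
orientations (robust to the multiple local minima that small-$N$
instances can produce), golden-section refinement, and a final
safeguarded Newton polish of the gradient root to near machine
precision. The polish matters: the estimator's defining symmetry —
regressing x on y gives exactly the reciprocal slope — is verified at
$10^{-8}$ relative tolerance (`mlfr_symmetry_check()`), and the
x-intercept amplifies slope error by roughly $\bar x/\beta$.
Degenerate inputs are handled explicitly: all-equal $x$ is an error;
all-zero SEs with noisy data fall back to unweighted Deming
($\lambda = 1$) with a warning; two-point (leave-one-out) fits use the
exact line through the points.

**Uncertainty and significance.** Standard errors for $\phi$ and $y$
are leave-one-out jackknife estimates over the $N$ loads,
$\mathrm{SE} = \sqrt{\tfrac{N-1}{N}\sum_i (\theta_{(i)} -
\bar\theta)^2}$; a degenerate leave-one-out refit marks the SE
undefined rather than silently shrinking it. Slope significance is a
two-tailed $t$ test on $N - p - 1$ degrees of freedom ($p = 1$
predictor, so df $= 2$ at four loads). When the regression is not
significant at `alpha`, $\phi$ and $y$ are reported as ND (not
determined) in the fits table — a deliberately conservative
convention, since an x-intercept of a non-significant line is
meaningless. Parameters of two fits are compared with
$t = (c_1 - c_2)\big/\sqrt{0.5(\sigma_1^2 + \sigma_2^2)}$ on
$df_1 + df_2$ degrees of freedom. The $0.5$ factor makes the
denominator the SE of the difference of two equally weighted
estimates under an equal-variance convention; it is kept as the
field's published formula for this comparison.

At $N = 4$ the jackknife is noisy: the property suite verifies only
that its SE tracks the true sampling SD of the slope within ~50%
relative error, and that 95% jackknife-$t$ intervals for $\phi$ cover
the generating value in at least 80% of synthetic replicates — loose
bounds that reflect four-point resampling. Conclusions that depend on
precise coverage at $N = 4$ should not be drawn.

## What the synthetic generator emulates — and what it does not

`creep_scenario()` fixes the generating conditions of a two-group
experiment modelled on a typical hypocotyl creep study: four loads
(400–700 mg), ten creep specimens per load, four dry-mass replicates
per group, 15-minute traces sampled at 1 s with a 1% elastic jump at
load application. The default group parameters are the fitted values
of the reference experiment the package's tests reproduce: control
$\phi = 0.80$, $y = 15.23$, mean dry mass 1.52 µg (SD 0.11); treated
$\phi = 0.31$, $y = 5.42$, mean dry mass 2.30 µg (SD 0.13).

Noise enters at two levels. Specimen-level rate noise (one Gaussian
draw per specimen) reproduces the between-specimen scatter that
dominates real creep data; its default SDs (1.6 and 0.8 % h$^{-1}$ for
the two groups) correspond to standard errors of ~0.5 and ~0.25
% h$^{-1}$ on a 10-specimen mean, the noise scale used throughout the
recovery studies. Within-trace jitter (`trace_jitter_sd`, default 0)
is available separately but contributes little once a 600-point window
is averaged by the OLS slope. Dry masses are drawn from a Gaussian
truncated at zero — at ~7% CV the truncation is numerically
irrelevant but guarantees positivity.

The generator deliberately does **not** model: viscoelastic
transients after loading (traces are exactly linear plus noise, so the
fit-window convention cannot be validated against a real transient);
pH kinetics of wall-loosening proteins; any mechanistic
polymer/microfibril structure; or drift and autocorrelation of real
extensometer sensors. Passing recovery tests therefore demonstrates
the statistical machinery is unbiased and calibrated *under the
assumed measurement model*, not that the model captures every feature
of instrument data.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed; experiment-level
functions derive per-specimen and per-condition child seeds through a
fixed affine map modulo $2^{31}-1$, so runs are bit-reproducible and
independent of evaluation order. `run_pipeline()` embeds the resolved
configuration and its MD5 hash in `summary.json`; reruns are
byte-identical.

The test suite and the acceptance script scale simulations to sizes
chosen for fast, stable statistics: 200 replicates for recovery and
coverage studies, 100 pipeline runs (at 10–30 s trace sampling and
reduced bootstrap depth, which leave the fitted parameters essentially
unchanged) for the two-group discrimination study, $10^5$ draws for
moment checks, and exhaustive enumeration on reduced instances
(3 rates × 2 stresses, resamples of size 2) as the bootstrap oracle.

## Known limitations

* The creep-rate estimator assumes the chosen window is past the
  loading transient; with real traces that should be checked visually
  or via the reported $R^2$.
* The functional-relationship model treats the per-load SEs as known
  variances; with only 4 (stress) and 10 (rate) replicates they are
  themselves noisy, which the jackknife only partially absorbs.
* Comparisons between bootstrap ratio estimates use the bootstrap
  distributions as samples, which is anticonservative in principle;
  the FDR step and the small number of contrasts mitigate but do not
  remove this. The functional-relationship comparison is the more
  rigorous route for group differences.
* ND propagation means a group can yield no $\phi/y$ estimate at all;
  this is by design and downstream code must expect `NA`s.
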