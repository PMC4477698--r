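---
title: "Spatially-varying Bayesian calibration of TEX86: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially-varying Bayesian calibration of TEX86}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

TEX86 (TetraEther indeX of 86 carbons) is a sea-temperature proxy based on
the relative cyclization of glycerol dialkyl glycerol tetraether (GDGT)
membrane lipids produced by marine Thaumarchaeota and preserved in ocean
sediments:

$$\mathrm{TEX}_{86} =
\frac{[\mathrm{GDGT\mbox{-}2}]+[\mathrm{GDGT\mbox{-}3}]+[\mathrm{cren'}]}
     {[\mathrm{GDGT\mbox{-}1}]+[\mathrm{GDGT\mbox{-}2}]+[\mathrm{GDGT\mbox{-}3}]+[\mathrm{cren'}]}$$

The index is bounded in $[0,1]$ and increases with growth temperature, but
the TEX86-temperature relationship is not globally uniform: slopes are
lower at high latitudes and regional archaeal ecology leaves spatial
structure in single-slope regression residuals. This package calibrates
TEX86 with a regression whose intercept and slope vary smoothly in space,
and inverts that calibration to turn downcore TEX86 series into posterior
temperature distributions.

## The model

With core-top observations stacked in $P$, target temperatures on the
diagonal of $C$, and a site-to-box selection matrix $M$:

$$P = M\alpha + MC\beta + \varepsilon,\qquad
  \varepsilon \sim N(0, \tau^2 I)$$
$$\alpha \sim N(\mu_\alpha \mathbf{1},\ \sigma_\alpha^2 R(\nu,\phi)),\qquad
  \beta \sim N_{[0,\infty)}(\mu_\beta \mathbf{1},\ \sigma_\beta^2 R(\nu,\phi))$$

$\alpha$ and $\beta$ are fields on the centroids of $20^\circ \times
20^\circ$ grid boxes (9 latitude rows $\times$ 18 longitude columns = 162
boxes, edges anchored at $(-90, -180)$, half-open intervals with the top
row closed). $R$ is the Matern correlation with smoothness $\nu = 3/2$,
written so that $\phi$ (per km) is an inverse correlation length:
$R(d) = (1+\sqrt{3}\phi d)e^{-\sqrt{3}\phi d}$. The slope field is
truncated to positive values: warmer water never lowers TEX86 a priori.

Two calibration targets are supported. **SST** uses the archived surface
climatology value at each site. **Sub-T** uses a gamma-weighted average of
0-200 m temperatures, $\int w(z)T(z)\,dz$ with $w \propto$
Gamma(shape $a = 4.5$, scale $b = 15$ m), peaking at $(a-1)b = 52.5$ m --
a stand-in for the shallow-subsurface maximum of Thaumarchaeotal GDGT
production. At sites shallower than 200 m the weights are renormalized
over the available column; a plain 0-200 m mean degrades badly in shallow
seas, which is exactly what the weighting avoids. Sites north of
70 degrees N are excluded from both calibrations ("north of" read
strictly: latitude 70.0 itself is retained), reflecting the collapse of
the TEX86-temperature relationship in the Arctic.

## Distance metric: why chordal

The Gaussian-process machinery needs a distance between box centroids. The
Matern family is guaranteed positive definite against *chordal*
(through-the-sphere) distance but not against great-circle distance: on the
full 162-box grid the great-circle Matern-3/2 matrix acquires negative
eigenvalues as large as $-0.94$ at small $\phi$, which no reasonable jitter
repairs. The package therefore defaults to chordal distance (sphere radius
6371 km) and keeps great-circle available behind
`correlation_model(distance = "great_circle")` for strongly spatially
damped settings. The two metrics agree closely at sub-hemispheric
separations, where all of the statistical action is.

## Priors and the sampler

The weakly-informative defaults (all configurable through `prior_spec()`)
are package choices, not published values:

| parameter | prior | default | why |
|---|---|---|---|
| $\mu_\alpha$ | normal | mean 0.3, sd 0.3 | center of the observed TEX86 range |
| $\mu_\beta$ | normal | mean 0.02, sd 0.02 | known ~0.015-0.02 per-degC slope scale |
| $\tau^2$ | inverse-gamma | shape 2, scale 1e-3 | prior mean 1e-3, infinite variance |
| $\sigma_\alpha^2$ | inverse-gamma | shape 2, scale 5e-3 | mild; intercept spread ~0.07 |
| $\sigma_\beta^2$ | inverse-gamma | shape 2, scale 2e-5 | mild; slope spread ~0.0045 |
| $\phi$ | discrete grid | 20 log-spaced values, 1e-5 to 1e-2 per km, uniform | see below |

`fit_bayspar()` is a pure Gibbs sampler: a joint multivariate-normal draw
for $\alpha$; coordinate-wise draws for $\beta$, whose full conditionals
under the truncated-MVN prior are exactly univariate truncated normals;
inverse-gamma draws for $\tau^2$, $\sigma_\alpha^2$, $\sigma_\beta^2$; and
normal draws for $\mu_\alpha$, $\mu_\beta$. The $\mu_\beta$ and
$\sigma_\beta^2$ updates use the conjugate forms that ignore the truncated
prior's normalizing constant -- standard practice for this model class and
a negligible approximation when, as here, negativity is far in the prior
tail. The inverse range $\phi$ is hard to identify from 162 boxes, so the
default treatment is an exact categorical Gibbs update over a discrete
log-spaced grid (marginal likelihood of both fields evaluated per grid
value); a fixed-$\phi$ treatment is available and is what the replicate
simulation studies use for speed.

Truncated-normal draws use inverse-CDF sampling on the log scale of upper
tail probabilities, which stays exact when the truncation point is
thousands of standard deviations from the mean (the $\tau^2 \to 0$ regime);
naive `qnorm(p0 + u(1-p0))` returns `Inf` there, and naive rejection
stalls. Correlation matrices carry a 1e-8 diagonal jitter before Cholesky
factorization, escalated (to at most 1e-4) only if factorization fails.
Initialization is per-box ordinary least squares where a box has at least
three observations, prior means elsewhere, slopes floored at 1e-4. Default
schedule: 2 chains of 7,500 iterations, 2,500 warmup, thinning 5;
split-R-hat above 1.05 warns but does not fail, and effective sample sizes
are reported per scalar parameter.

## Inversion

Given a draw $(\alpha_j, \beta_j, \tau^2)$ for the site's box and a normal
temperature prior $N(\mu_0, \sigma_0^2)$, the temperature posterior is
normal with precision $1/\sigma_0^2 + \beta_j^2/\tau^2$ and mean
$(\mu_0/\sigma_0^2 + \beta_j(\mathrm{tex}-\alpha_j)/\tau^2)$ / precision.
`predict_downcore()` iterates this over a seeded subsample of posterior
draws (default 1,000, without replacement), so calibration uncertainty
propagates into the reconstruction. The default prior is deliberately weak:
mean equal to the box's modern calibration-mean temperature, sd 20 degC.
Replicate TEX86 values at one age are averaged before inversion. Sites
falling in boxes with no calibration data raise an explicit error; the
deep-time "analog" pathway for such sites is out of scope here.

Ensemble analytics follow the reconstruction: `warmest_interval_probability()`
finds each ensemble member's warmest time point (ties, possible only in
degenerate inputs, go to the earliest age) and bins the hits into
left-closed, right-open age bins anchored at the youngest age (default
width 0.5 kyr, i.e. 500 years); `epoch_difference()` forms member-wise
window-mean contrasts (e.g. LGM minus Late Holocene) and reports the 5th,
50th and 95th percentiles.

## The synthetic world

Because the archived 1095-record database requires a download, every stage
is testable against a generator with the exact statistical structure of
the model. Defaults are fixed once: $\mu_\alpha = 0.25$,
$\mu_\beta = 0.018$ per degC, $\tau = 0.03$ TEX86 units (the documented
interlaboratory uncertainty scale), $\sigma_\alpha = 0.03$,
$\sigma_\beta = 0.004$ (spreads that keep the slope field comfortably
positive while giving visible regional variation), and $\phi = 2.2\times
10^{-4}$ per km (correlation ~0.1 at 10,000 km, a plausibly basin-scale
range -- the fitted value is not published, so this is a package choice).
The truncated $\beta$ field is generated by redraw-until-positive, i.e.
conditioning rather than exact truncated-MVN sampling; negativity is rare
under the defaults, and the generator aborts if acceptance collapses. The
idealized climatology is a smooth, latitude-dominated field with
exponential depth decay and rectangular synthetic continents; it does not
emulate real bathymetry, seasonality, upwelling or water-mass structure.
TEX86 values that leave $[0,1]$ are clipped and counted, and a truth under
which more than 5% clip is rejected as insane. A green synthetic test
therefore establishes internal statistical correctness -- not that real
GDGT data obey the model.

One measurement-design note: interval *coverage* for a single downcore
site is dominated by that one box's parameter-estimation luck, because all
time points share the site's $(\alpha, \beta)$ draws. The end-to-end
coverage check therefore spreads its 200 intervals over the five
best-sampled boxes, which measures the calibration of the posterior
rather than a single box's realization.

## File formats

Plain-text throughout: core-top tables are CSV/TSV against a canonical
schema with a JSON column-mapping "dialect" for foreign headers (the
archive's exact headers are not standardized); climatologies are
long-format CSV (`lat, lon[, depth], temp`, blank = land); posterior
ensembles are a CSV of draws plus a JSON provenance sidecar (seed,
schedule, priors, convergence); configurations are JSON with unknown keys
rejected. NetCDF was deliberately not used: no R NetCDF reader is part of
this package's fixed dependency set, and the plain-text forms are
diff-able and round-trip exactly.

## Known limitations

- $\phi$ is weakly identified from 162 boxes; its posterior often
  concentrates on one or two grid values and should be read as a nuisance
  parameter, not an estimate of a physical correlation length.
- The $\mu_\beta$/$\sigma_\beta^2$ updates ignore the truncation
  normalizer (see above); with priors placing non-negligible mass near
  $\beta \le 0$ this approximation would bias the hierarchy.
- Coverage statements are calibrated under the model; real-world TEX86
  carries non-thermal variance (archaeal community, terrigenous input)
  that only widens honest uncertainties when $\tau^2$ absorbs it.
- No age-model uncertainty: downcore ages are taken as given.
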