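---
title: "Morphometric similarity networks and normative deviation mapping: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric similarity networks and normative deviation mapping: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `mindev`, the choices
behind their tunable parameters, what the synthetic cohort generator does
and does not emulate, and the numerical decisions a maintainer would want
on record. Everything quantitative stated here is computed by the test
suite or by the scripts under `analysis/`; nothing is asserted from
memory.

## The network metric

Each subject contributes five vertex-level morphometric features per
cortical region (cortical thickness, mean curvature, sulcal depth,
surface area, gray-matter volume). After pooled per-subject Z-scoring of
each feature across all vertices — so the five features share a scale —
a region is represented by its multivariate vertex distribution in the
standardized 5-D feature space. The similarity of two regions $a$, $b$ is

$$\mathrm{MIND}(a,b) = \frac{1}{1 + \mathrm{KL}(a,b)},$$

where $\mathrm{KL}(a,b)$ is the symmetric Kullback–Leibler divergence
$\hat D(a\|b) + \hat D(b\|a)$ estimated with the k-nearest-neighbour
density-ratio estimator: for each point the ratio of its $k$-th
neighbour distance within its own sample ($\rho_k$) to that in the other
sample ($\nu_k$) enters

$$\hat D(P\|Q) = \frac{d}{n}\sum_{i=1}^{n}
\log\frac{\nu_k(i)}{\rho_k(i)} + \log\frac{m}{n-1}.$$

The weighted degree of a region is its mean similarity to all other
regions (diagonal excluded) and is the measure carried through all
downstream analyses.

Numerical decisions:

* `k = 3` by default (exposed in every entry point). Per-region vertex
  counts at desk scale are in the tens to low hundreds; a small `k`
  preserves sensitivity there.
* Distances are Euclidean in the standardized 5-D space; the pooled
  Z-scoring is what licenses a common metric.
* Coincident points would break the log-distance terms, so a seeded
  Gaussian jitter of magnitude 1e-10 is added before neighbour searches.
  The jitter is applied in a canonical argument order so that the
  estimate is exactly symmetric under swapping the two samples.
* Negative raw estimates (possible at small divergence) are clipped to
  zero so similarities stay in $(0, 1]$.

Two estimator properties matter for interpretation and are verified by
the tests. First, consistency: the error against the closed-form
Gaussian divergence shrinks from $n = 500$ to $n = 5000$. Second, a
finite-sample multiplicative bias: at $n = 5000$, $d = 5$, $k = 3$ the
estimator sits about 13% below the closed-form value of a
unit-mean-shift Gaussian pair, decaying only like $O(n^{-1/d})$. We
verified the bias is a property of the estimator itself (an independent
k-d-tree implementation reproduces it to within a percentage point).
Because the divergence-to-similarity transform is monotone, this bias
compresses but never reorders similarities. A related estimator quirk
drives a generator choice below: inflating the variance of one sample
*raises* its estimated similarity to others at desk-scale vertex counts,
because widening a sample inflates its within-sample neighbour distances
faster than the cross distances.

## The normative model

For each region independently, the weighted degree $y$ of reference
controls is modelled as

$$y = \mu + \sigma\,\varepsilon_{\text{SHASH}}, \qquad
\mu = \beta_0 + \beta_1\,\mathrm{age}_c + \beta_2\,\mathrm{age}_c^2 +
\beta_3\,\mathrm{male} + u_{\text{site}},\qquad
\log\sigma = \gamma_0 + \gamma_1\,\mathrm{age}_c + v_{\text{site}},$$

with $\varepsilon$ a sinh–arcsinh (SHASH) variable with skewness
$\epsilon$ and tail weight $\delta$ ($\epsilon = 0,\ \delta = 1$ is the
standard normal). Age is centred and scaled by the training mean and SD.
Site offsets $u$ and $v$ are partially pooled through quadratic penalties
$u^2/2\tau_u^2$, $v^2/2\tau_v^2$ (defaults $\tau_u = 0.1$ in degree
units, $\tau_v = 0.5$ on the log-scale) — the penalized-maximum-likelihood
equivalent of Gaussian random site effects. Fitting is blockwise for the
Gaussian sub-model (exact weighted ridge for the location block,
quasi-Newton for the scale block), which makes the single-site
homoscedastic case agree with ordinary least squares to numerical
precision. The SHASH extension is optimized by L-BFGS-B from the Gaussian
solution with three deterministic shape starts, because the SHASH
likelihood is multimodal; box bounds $\epsilon \in [-2, 2]$,
$\log\delta \in [-1.5, 1.5]$ keep the quantile transform well
conditioned.

Under the default `family = "auto"`, a region keeps the Gaussian
sub-model unless a moment-based residual-normality test rejects (at
0.05), in which case the SHASH fit is attempted and retained only if it
improves AIC. This gives exactly testable Gaussian behaviour where the
data are Gaussian, and flexible tails where they are not.

Transfer to new acquisition sites re-estimates only $(u_s, v_s)$ per
site under the same penalties, with all population coefficients frozen.
Every site to be scored must appear in the adaptation data; scoring a
subject from an unseen site is an error rather than a silent
extrapolation. Ages outside the training range are scored but flagged.

Deviations are Gaussianized quantile residuals,

$$Z = \sinh\!\big(\delta\,\mathrm{asinh}\,r - \epsilon\big),
\qquad r = (y - \mu)/\sigma,$$

which reduce exactly to $(y-\mu)/\sigma$ for Gaussian regions. Extreme
deviations are $|Z| > 1.96$ (strictly; ties are measure-zero but the
convention is fixed), counted separately per direction. Z-scores are
residualized against eTIV within sex-by-diagnosis cells by a straight-line
fit whose intercept is retained, so cell means are preserved; cells under
3 subjects are skipped with a warning.

## Quality control

Subjects whose Euler index is worse than the cohort median by more than
2 scaled median absolute deviations are excluded. eTIV outliers are
removed per diagnosis-by-sex cell with Tukey fences at 1.5 IQR: the
literal "outside the interquartile range" rule (fence multiplier 0)
removes about half of any continuous sample, so 1.5 is the default and
the literal rule remains available as `fence_multiplier = 0`.

## Permutation inference

Regional overlap differences, network enrichment and effect-size maps
all use empirical p-values with the +1 correction,
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(N+1)$, and
Benjamini–Hochberg FDR applied within each group-by-direction-by-tail
family (the family definition is a package convention; pooling across
families is not reported anywhere).

The spatial null rotates each hemisphere's spherical centroids by a Haar
uniform rotation (QR decomposition of a Gaussian matrix with sign and
determinant correction), mirrored across hemispheres to preserve
homologue correspondence, and maps rotated centroids back to region
slots by minimum-total-distance Hungarian assignment. Each draw is a
within-hemisphere bijection, so every subject's flag count is conserved.
Each hemisphere's centroids tile a full unit sphere of their own (as
surface reconstructions do); this matters — projecting both hemispheres
onto halves of one sphere makes assignment-based rotations nearly
degenerate.

A conservativeness property of spin tests is worth stating because the
tests document it: when a disease effect is confined to one spatially
compact network, the rotation null's p-value for that network has a
geometric floor of roughly the probability that a random rotation
re-aligns the flag cluster with its own network (empirically 0.02–0.12
at 60 regions even for near-saturating effects). The group-label null
has no such floor; the two families answer different questions, and the
acceptance suite reflects that the label null reliably flags a focal
one-network effect while the spatial null frequently cannot, regardless
of effect or sample size.

## Clinical models

The clinical stages are deliberately standard fits with a fixed
covariate coding: diagnosis severity ordered
NC < MCI stable < MCI progressive < AD; genotype reference level e3/e3
with e2/e4 and missing genotypes excluded; female and least-severe group
as reference levels. The four-candidate APOE family (additive,
+genotype×age, +genotype×sex, full two- and three-way) is compared by
AIC with likelihood-ratio tests against the additive model; Tukey
genotype contrasts come from the additive model because pairwise
genotype contrasts are not well defined under genotype-by-covariate
interactions. Cox models check scaled Schoenfeld residuals per covariate
and, when diagnosis violates proportionality at p < 0.05, automatically
refit stratified-by-diagnosis and per-group models; Kaplan–Meier median
splits assign ties at the median to the low-burden group. ABC
neuropathology is modelled by proportional-odds logistic regression with
age, sex and time-to-death covariates and count-by-age /
count-by-time-to-death interaction candidates compared by AIC.

## The synthetic cohort generator

The generator is the package's study stand-in, not a fixture. Control
vertex features follow region-specific 5-D baselines with linear plus
quadratic age trends, additive sex effects, per-site location offsets
and scale multipliers, and subject-level noise. Site, sex and age
effects are region-specific; a uniform shift across all regions would be
removed by the per-subject feature standardization and would leave no
trace in the networks.

Disease subjects receive, in regions of the targeted networks only, a
mean shift along a fixed random direction in feature space plus mild
variance inflation, scaled by group (0.5 / 1.0 / 2.0 vertex-SD units for
stable MCI / progressive MCI / AD) and by a log-normal subject severity
(log-SD 0.3) modulated by APOE genotype with a female-e4/e4 excess. Two
calibration facts fixed these defaults before any acceptance run: the
estimator quirk above means variance inflation alone *raises* degree, so
the inflation slope is kept small (0.1 per severity unit) and the mean
shift carries the degree reduction; and a shift of 2 vertex-SD produces
roughly a −3.5 SD degree effect in targeted regions, a severe but not
pathological separation. Each subject expresses the effect in a random
60% subset of targeted regions (`target_fraction`), reproducing the
characteristic individual heterogeneity of neurodegeneration: group
overlap concentrates in the targeted networks while pairwise Hamming
distances between individual maps stay substantial.

Outcomes are coupled to the injected burden: survival times come from an
exponential proportional-hazards model (with administrative censoring
and a diagnosis effect that decays after 3 years, deliberately violating
proportional hazards for diagnosis the way clinical cohorts do); the
default burden log-hazard is zero, so that by default deviation burden
does not predict mortality and the survival stage is exercised as a null
recovery. The ABC score cuts a latent
logistic variable (burden and age effects) into 0–3, scored only for
deceased subjects. Euler indices have a heavy left tail with a 3%
"bad-reconstruction" fraction to exercise the MAD filter; eTIV carries a
sex effect and rare outliers for the fence filter.

What the generator does not emulate: real cortical geometry (centroids
are Fibonacci lattices, networks are k-means clusters of them),
realistic feature covariance within regions (features are conditionally
independent given the region mean), longitudinal structure, scanner
software differences beyond location/scale, and any genuine biology
behind the receptor-style reference maps (Gaussian processes with
distance-decaying covariance). Passing tests therefore demonstrate that
the machinery recovers known structure of this class — smooth covariate
trends, site effects, network-confined degradation, outcome couplings —
not that it would detect any particular effect in real cohorts.

## Problem sizes

The package's standard profiles, used by the tests, the analysis scripts
and the acceptance checks, are: 60 regions, 100 vertices per region, 4
sites and about 600 subjects for the full workflow; 360 regions only for
parcellation-scale checks; 2000 training plus 1000 held-out subjects
(simulated at the degree level, which is the generative family the
normative model fits) for calibration checks; n = 1500, 1300 and 240 for
the survival, genotype and neuropathology recovery suites, mirroring the
study's analysis subsamples. Permutation counts default to 10000 in the
analysis scripts and are reduced (200–1000) in tests, where the
quantities asserted are averages over seeds rather than single
p-values.

## Known limitations

* The k-NN divergence estimator's finite-sample bias (≈ −13% at
  n = 5000 in 5-D) is inherent; similarities are compressed toward the
  middle of their range. Analyses here only ever use them comparatively.
* The spin test is conservative for focal single-network effects (the
  geometric floor above); network conclusions should rest on both null
  families, which answer complementary questions.
* SHASH fits need a few thousand training subjects per region before the
  shape parameters are reliably supported; below that the AIC gate keeps
  the Gaussian sub-model, which is the better-calibrated choice at those
  sizes.
* The pipeline models weighted degree only; edge-level normative
  modelling is out of scope.
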