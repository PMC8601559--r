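---
title: "Dual-axis landscape gradients and occupancy: models, conventions, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-axis landscape gradients and occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradocc)
```

This vignette records the modelling choices behind `gradocc`: the smoothing
and ordination conventions that define the landscape gradients, the
occupancy likelihood and its selection machinery, what the synthetic-data
generators emulate (and what they do not), and the numerical decisions a
maintainer would otherwise have to reverse-engineer.

## 1. From categorical land cover to gradient surfaces

### Smoothing

A categorical land-cover raster assigns each cell one class code.  For
each class we form the binary indicator (1 = focal class) and compute a
Gaussian-kernel weighted average around every pixel, yielding a continuous
class fraction in [0, 1] that encodes landscape *context* rather than
point cover.

Conventions, all exposed as arguments:

* **Kernel scale.** "A 500-m kernel" means a Gaussian with standard
  deviation σ = 500 m.  Scale should track the organism: 500 m
  approximates a songbird breeding home range; 1 500 m is offered as a
  common comparison scale (`validate_run_config(..., preset = "scale1500")`).
* **Truncation.** The discrete kernel lives on a square support of
  half-width ⌊4σ/cell⌋ cells (< 1e-3 of mass discarded; at σ = 500 m and
  30-m cells, a 133 × 133 weight matrix), renormalised to sum to one.
  The kernel is separable, so smoothing is two 1-D passes.
* **Edges.** Default `edge_policy = "renormalize"`: at each pixel the
  kernel is rescaled to the weight mass that falls on the grid, so a
  constant field maps to itself and class layers still sum to one at the
  borders.  `"zero_pad"` (off-grid cells count as zero) is provided for
  parity with FFT-based smoothers.  Which convention a given published
  analysis used is rarely stated; results differ only within one kernel
  radius of the border, but the partition-of-unity identity below holds
  only under renormalisation.

Under `renormalize`, smoothed class layers form a partition of unity
(Σ_c z_c(x) = 1 at every pixel), which the test suite asserts to 1e-6 on
fifteen-class synthetic cities and which provides a strong end-to-end
check on the convolution machinery.

### Ordination

Pixels (pooled over all cities) are observations; the p smoothed class
fractions are variables.  We eigen-decompose the **correlation** matrix,
not the covariance matrix: class fractions have wildly unequal variances
(dominant classes would otherwise own the leading axes), and under the
correlation convention the percent variance explained by component *k* is
exactly 100·sdev_k²/p — the identity that lets published component
standard deviations be converted to variance shares (1.581 → 16.7 % at
p = 15).  Pooling uses streaming moment accumulators
(`accumulate_moments()`), so multi-city PCA never materialises the
concatenated pixel matrix; accumulation is associative and is tested
against the dense computation.

**Retention.** The broken-stick proportions b_k = (1/p)Σ_{i=k..p}1/i give
the expected variance shares if total variance were split at random; for
p = 15, b₁ = 22.1 %.  The default rule retains the smallest leading set of
axes whose *cumulative* variance share exceeds b₁.  The phrase "cumulative
broken-stick cut-off" admits other readings (e.g. compare each v_k with its
own b_k); the cumulative-vs-b₁ reading is the one consistent with retaining
exactly two axes when v = (16.7, 11.1, ...) and is the default, with the
per-component variant selectable (`rule = "per_component"`).

**Orientation.** Eigenvectors are sign-indeterminate.  Axes are anchored
to field semantics: axis 1 is flipped if needed so developed classes
(21–24) load negative — low values mean *hard* (built) landscapes — and
axis 2 so forest classes (41–43) load positive — high values mean *green*
(natural) rather than *brown* (agricultural).  Orientation is idempotent
and never changes eigenvalues.

**Surfaces.** The default gradient surface is the weighted average
s(x) = Σ_c z_c(x)·w_c of the *raw* smoothed fractions by the axis
loadings.  A true principal-component score (standardising each class
first) is available as `mode = "score"`; the raw-value average is the
default because the surface then inherits the [0, 1] scale of its inputs
and the published formulation implies unstandardised values.  The two
differ by an affine map per class, so downstream logit-linear models are
affected only through covariate scaling.

**Degenerate inputs.** Classes with zero variance across pooled pixels
have undefined correlations and are dropped with a warning (p reduced
accordingly, the drop recorded in the model) rather than imputed.

## 2. The occupancy engine

### Likelihood

Detection histories are ragged (sites differ in visit count J_i).  The
single-season likelihood marginalises the latent occupancy state:
L_i = ψ_i·Π_j p_ij^{y_ij}(1−p_ij)^{1−y_ij} + (1−ψ_i)·1[no detections].
Both submodels use logit links; computation is in log space (visit terms
aggregated per site with `rowsum`), and the test suite verifies exact
agreement (1e-10) with a brute-force latent-state enumeration oracle on
small data sets.

### Design matrices and K

Structures are R formulas under treatment coding, alphabetical first
factor level as reference, one intercept per submodel; `a*b` expands to
main effects plus interaction, and `city*(HS*BG)` to all mains, all
two-way terms, and the three-way.  `date` is the survey date scaled so one
unit is ten calendar days (April 1 → 0, September 30 → 18.2; this eases
interpretation and optimisation), and `date2` is its square, materialised
at design-build time rather than stored.  K is the total design width;
this convention reproduces the full set of published ten-city selection-
table parameter counts (44, 63, 24, 53, ...).

### Fitting and convergence

BFGS from a zero start with the analytic gradient, `reltol = 1e-12`, up to
three seeded jittered restarts, followed by damped Newton polishing with
the numerical Hessian.  A fit is *converged* only if the optimiser
succeeded, the gradient max-norm is below 1e-4, and the Hessian is
positive definite; otherwise the fit is flagged and retained — realistic
candidate sets routinely contain structures the data cannot support
(boundary estimates, collinearity, K approaching n), and non-convergence
must be a recorded outcome, not an exception.  AICc uses n = number of
sites (the sampling unit of the likelihood; the convention of standard
occupancy software) and is undefined when n ≤ K + 1.

### Candidate sets and two-stage selection

The shipped detection set (26 structures) comprises all additive
combinations of {city; date or date+date²; HS; BG} under marginality,
*minus* the full additive model, *plus* three single-interaction
structures (`city*date+date2+HS+BG`, `city*date+HS+BG`, `city*HS`).  Only
the set's total size and eight of its members are externally constrained;
the remainder is an editable configuration default, chosen to respect
marginality and the "single interaction terms only" rule.  The occupancy
set is the complete 16-structure family over {city, HS, BG} with
city-gradient interactions.  Stage one ranks detection structures with the
occupancy component fixed at the global (most complex) structure; stage
two fixes the winning detection structure and ranks occupancy structures.
Akaike weights are computed over converged models only.

### Goodness of fit

A detection-history frequency chi-square in the MacKenzie–Bailey style,
generalised to ragged designs: sites are grouped into cohorts by J; within
a cohort the observed count of each binary history is compared with its
expected count under the fitted model (all 2^J histories enumerated for
J ≤ 10, otherwise the observed histories plus one pooled remainder cell);
cells with expected count below 2 are pooled within their cohort.  The
null distribution comes from a parametric bootstrap (simulate from the
fitted model, refit starting at the fitted coefficients, recompute).  The
test-suite calibration experiment (100 replicates of self-generated data,
100 sites × 4 visits, n_boot = 200) checks the nominal-0.05 rejection rate
stays in [0.01, 0.12].

## 3. What the synthetic generators emulate

`generate_landscape()` builds city-like categorical rasters from one
latent field per class (white noise convolved with the same Gaussian
kernel machinery as the smoothing module — one code path, deliberately),
plus a shared radial urban score with per-class weights graded from
developed-open to developed-high-intensity (concentric rings), plus an
east-west sector field pulling agriculture one way and forest/wetland the
other.  Pixel class is the argmax of score + per-class offset; offsets are
adjusted iteratively (decaying gain, ≤ 100 rounds, best iterate kept) until
realised composition is within 0.02 of target.  The default recipe's
fifteen-class composition follows the aggregate cover mix typical of
mid-sized US urban-exurban regions (≈ one-fifth developed, one-quarter
forest, one-third agriculture).

`simulate_checklists()` lays survey sites uniformly over each city window,
draws visit counts from a Poisson (mean 3, minimum 1) and dates uniformly
over April–September, simulates detections from logit-linear occupancy and
detection models with city, gradient, and quadratic-date effects, and
deliberately salts the table with traveling-protocol and incomplete rows
so the filtering stage is exercised.

What these emulate well: multi-class spatial autocorrelation, an urban
core with intensity rings, separated agricultural/natural sectors (the
triangular hard/soft × brown/green structure), ragged visit counts,
protocol filtering, per-city imbalance and thinning.  What they do not:
road networks and hydrology, observer effects and effort covariates,
spatial clustering of survey sites near access points, temporal trends in
effort, and any particular real city's composition.  Passing tests
therefore demonstrate correctness of the machinery under known generating
conditions, not field realism of any specific estimate.

With three pooled synthetic cities the oriented axes consistently recover
the intended structure (axis-1 surface strongly negatively correlated with
smoothed developed fraction; axis-2 positive with forest, negative with
cropland).  With fewer cities or small windows the leading axes can mix,
exactly as pooled ordinations of few groups do on real data.

## 4. Numerical choices and problem sizes

* Composition matching tolerance 0.02 (absolute proportion), iterative
  offset adjustment with gain 3/it^0.3, best iterate kept.
* Kernel truncation 4σ (square support); smoothing is exact separable
  convolution, tested at 1e-10 against a direct double-loop oracle.
* Optimiser: BFGS + Newton polish; gradient tolerance 1e-4 (max-norm);
  Hessian positive-definiteness via Cholesky; SEs only for converged fits.
* Ties in the generator argmax break toward the first class listed;
  nearest-pixel extraction assigns far-edge points to the last cell.
* Every stochastic stage takes an explicit integer seed; there is no
  hidden global RNG state (seeds are set inside private RNG scopes and
  the caller's RNG state is restored).
* Test and demonstration problem sizes — grids of 60–200 cells per side at
  100-m cells, two to three cities, 100–1000 sites, bootstrap sizes of
  8–200 — were chosen as the smallest sizes at which the statistical
  properties under test (axis structure, parameter recovery, GoF
  calibration) are stable across seeds.

## 5. Known limitations

* GeoTIFF support targets the single-band, north-up, square-cell case with
  a world-file sidecar; integer codes round-trip exactly, continuous
  layers are limited to [0, 1] (the class-fraction range).  The ESRI ASCII
  format carries arbitrary values; reprojection and datum handling are out
  of scope.
* The PCA is a plain pooled ordination: no multi-group PCA, rotation, or
  alternative ordinations (NMDS, CA), which may be preferable when cities
  differ strongly in composition.
* Occupancy models assume closure within the season, independence across
  sites (no spatial autocorrelation in ψ), and no observer/effort
  covariates; model averaging of predictions is not provided (weights are
  reported, predictions come from the selected model).
* The 26-structure detection set beyond its externally constrained members
  is a default, not a canonical list; treat it as configuration.
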