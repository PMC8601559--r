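# gradocc

Dual-axis landscape gradients of human influence, linked to species
occurrence through single-season occupancy models.

## The problem

Ecological responses to human-dominated landscapes are usually studied
along a single gradient (percent impervious surface, percent forest).  But
human influence is at least two-dimensional: built-up *hard* environments
differ from unpaved *soft* ones, and soft landscapes split again into
agricultural (*brown*) and natural (*green*) cover.  Collapsing this onto
one axis confounds distinct ecological signals.

`gradocc` implements a standardized recipe for extracting those axes from
categorical land-cover data and using them as covariates in occupancy
analyses of detection/non-detection survey data (e.g. repeat-visit bird
checklists), where imperfect detection must be modelled explicitly.

## The method

**Landscape gradients.** For each land-cover class *c* in a 30-m-style
categorical raster, extract the binary indicator and smooth it with a
Gaussian kernel (σ = 500 m by default, a songbird breeding home-range
scale), giving continuous class fractions *z_c(x)* ∈ [0, 1].  Pool pixels
across study cities and run a PCA on the p × p Pearson **correlation**
matrix of the class fractions (so percent variance of component *k* is
100·λ_k/p).  Retain the leading axes whose cumulative variance share
exceeds the first broken-stick proportion

&nbsp;&nbsp;&nbsp;&nbsp;b_k = (1/p) Σ_{i=k..p} 1/i &nbsp;&nbsp;(b₁ = 22.1 % for p = 15),

orient axis 1 so developed classes load negative (**hard-to-soft**, HS) and
axis 2 so forest classes load positive (**brown-to-green**, BG), and map
each retained axis back onto the landscape as the weighted average
s(x) = Σ_c z_c(x)·w_c of the raw smoothed fractions by the axis loadings.

**Occupancy.** Detection histories y_ij over repeat visits j at sites i are
modelled with the zero-inflated Bernoulli likelihood

&nbsp;&nbsp;&nbsp;&nbsp;L_i = ψ_i Π_j p_ij^{y_ij}(1−p_ij)^{1−y_ij} + (1−ψ_i)·1[Σ_j y_ij = 0],

with logit-linear submodels for occupancy ψ (site covariates: city, HS, BG)
and detection p (plus scaled date and date²).  Fitting is by BFGS with the
analytic gradient.  Model selection is two-stage: 26 candidate detection
structures are ranked by AICc (n = sites) under the global occupancy
structure; the winner's detection structure is fixed and 16 occupancy
structures are ranked.  Fit is checked with a parametric-bootstrap
chi-square test on detection-history frequencies (cohorts by visit count),
reporting a p-value and the overdispersion ratio ĉ.

Everything runs end to end on seeded synthetic data: a generator for
city-like landscapes (urban core, agricultural and natural sectors,
spatially autocorrelated patches) and for checklist surveys over them.

## Worked example

```r
library(gradocc)

# two synthetic city landscapes (15 land-cover classes, 12 x 12 km at 100 m)
cities <- lapply(1:2, function(k)
  generate_landscape(default_city_recipe(seed = 40 + k),
                     n_rows = 120, n_cols = 120, cell_size = 100,
                     origin = c((k - 1) * 30000, 0)))

# smooth every class with a 500-m Gaussian kernel, pool, ordinate, orient
stacks <- lapply(cities, smooth_stack, sigma = 500)
model  <- orient_axes(gradient_pca(stacks))
model
#> <gradient_model: 15 classes, 28800 pixels, 3 axis(es) retained (broken stick 22.1%)>
#>                           PC1    PC2    PC3
#> Std.Dev.                1.293  1.249  1.137
#> Variance Explained (%) 11.145 10.392  8.624
#> Cumulative (%)         11.145 21.537 30.161
```

The first axis separates the built urban core (negative loadings on
developed classes) from vegetated cover; the second separates cropland from
forest.  Projecting a stack onto an axis gives a gradient surface raster:

```r
HS <- gradient_surface(stacks[[1]], model, axis = 1)   # hard-to-soft
BG <- gradient_surface(stacks[[1]], model, axis = 2)   # brown-to-green
```

Simulate a checklist survey over the surfaces, prepare detection histories
(protocol/season filter, per-city thinning to 250 sites, nearest-pixel
covariate extraction), and fit an occupancy model:

```r
fit <- occu_fit(~ city + HS + BG, ~ date + date2 + BG, d)
summary(fit)
#> Occupancy model  psi city+HS+BG,  p date+date2+BG
#>   sites: 500   K: 8   -logLik: 798.96   AICc: 1614.22   converged: TRUE
#>
#> Coefficients (logit scale):
#>                  Estimate Std. Error z value Pr(>|z|)
#> psi.(Intercept)  0.472056   0.176559   2.674 0.007503 **
#> psi.citycity02   0.454280   0.251216   1.808 0.070556 .
#> psi.HS           0.731307   0.605299   1.208 0.226980
#> psi.BG           0.968428   0.491220   1.971 0.048669 *
#> p.(Intercept)   -0.027106   0.210293  -0.129 0.897440
#> p.date           0.206449   0.053149   3.884 0.000103 ***
#> p.date2         -0.019159   0.002975  -6.439  1.2e-10 ***
#> p.BG             0.747868   0.301825   2.478 0.013219 *
```

Occupancy rises along brown-to-green (positive `psi.BG`: this simulated
species prefers natural over agricultural soft landscapes) and detection
peaks mid-season (positive `date`, negative `date2`).  Two-stage selection
and goodness of fit:

```r
sel <- occu_select(d,
  det_models = candidate_detection_models(c("1", "date", "date+date2+BG")),
  occ_models = candidate_occupancy_models(c("1", "HS+BG", "city+HS+BG")),
  global_psi = "city+HS+BG")
sel$occupancy
#>        model K    AICc dAICc weight negLogLik converged
#> 1 city+HS+BG 6 1659.47  0.00  0.664    823.65      TRUE
#> 2      HS+BG 5 1660.89  1.42  0.326    825.38      TRUE
#> 3          1 3 1667.79  8.32  0.010    830.87      TRUE

mb_gof(sel$best_fit, n_boot = 100, seed = 9)
#> Parametric-bootstrap goodness of fit (detection-history chi-square)
#>   observed chi-square: 28.846
#>   bootstrap mean:      27.361  (n_boot = 100)
#>   p-value: 0.400   c-hat: 1.054
```

The full default candidate sets (`candidate_detection_models()`, 26
structures; `candidate_occupancy_models()`, 16) and the complete pipeline
are wired together in `run_demo()`, which writes surfaces, selection
tables, and a seeded, byte-reproducible run report.

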