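---
title: "Spatial denoising of field trials: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial denoising of field trials: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models behind `fieldkrige`, the
assumptions they make, the defaults and why they were chosen, and the
places where the design was genuinely open and a choice had to be made.

## The problem

A split-plot field trial applies its planned treatments on top of soil that
is already heterogeneous: nutrients, salinity and pH form smooth spatial
gradients that act as unplanned covariates. Because only a subset of plots
is usually sampled for soil chemistry, three statistical tasks arise in
sequence: (i) infer each property's spatial covariance from sparse samples,
(ii) interpolate the property to every plot, and (iii) remove its influence
from the responses of interest without spending a degree of freedom per
property. `fieldkrige` implements this chain with variogram estimation,
ordinary kriging, and principal component regression.

## Stationarity by residualization

Variogram estimation assumes a stationary field: constant mean and a
covariance that depends only on separation. Raw soil measurements can
violate this through the design itself (watering treatments alter
salinity, genotypes alter rhizosphere chemistry), so each property is first
residualized on the full factorial design,

$$y = \mu + \mathrm{Trt} + \mathrm{Geno} + \mathrm{Trt{:}Geno} +
\varepsilon,$$

by ordinary least squares on the plots where the property was observed,
under sum-to-zero contrasts (required for the type-III tests downstream;
the choice of contrasts does not affect residuals). Rank-deficient designs
— a genotype unobserved under one treatment among the sampled plots — drop
the unestimable columns with a warning, mirroring standard linear-model
fitters.

A consequence worth knowing: when soil is sampled sparsely, this model can
be large relative to the data. With 48 treatment-by-genotype cells and ~96
sampled plots, the fitted cell means absorb roughly half of the *true*
spatial signal along with the design effects (each cell mean is the average
of ~2 spatially distant plots). The residual field is the right object for
variogram estimation, but any downstream adjustment can only remove the
portion of a gradient that survives this projection. Densifying the soil
sampling relaxes the limit; see "What the tests show" below.

## Variogram models and fitting

The empirical semivariogram uses the Matheron estimator on
equal-width distance bins up to a cutoff (default: one third of the maximum
inter-plot distance, 15 bins; lag positions are mean pair distances, empty
bins are dropped, zero-distance pairs excluded). Distances are Euclidean in
plot units on the integer grid — the field's physical dimensions are
irrelevant to the procedure as every distance-bearing parameter is in the
same units.

Six families are available, all with $\gamma(0) = 0$, nugget $n$, partial
sill $s$, and range parameter $r$:

| family | $\gamma(h)$ for $h > 0$ |
|---|---|
| nugget-only | $n$ |
| exponential | $n + s(1 - e^{-h/r})$ |
| spherical | $n + s(1.5\,h/r - 0.5\,(h/r)^3)$ for $h \le r$, else $n + s$ |
| Gaussian | $n + s(1 - e^{-(h/r)^2})$ |
| Matérn | $n + s\!\left(1 - \tfrac{2^{1-\kappa}}{\Gamma(\kappa)}(h/r)^\kappa K_\kappa(h/r)\right)$ |
| Stein's Matérn | Matérn form with argument $h\sqrt{2\kappa}/r$ |

The range parameter follows the reference geostatistics convention:
exponential and Gaussian approach the sill asymptotically and their
*effective* ranges ($3r$ and $\sqrt{3}r$) are reported as derived fields by
`tidy()`, to avoid silent disagreement with software that reports effective
ranges. Matérn evaluation uses exponentially scaled Bessel functions on the
log scale to stay finite at extreme arguments.

Fitting is weighted least squares with weights $N_h/h^2$ (the standard
default of the fitter used in this literature; $N_h$ and uniform weights
are selectable), box-constrained nonnegative, from multiple starts (range
at cutoff/10, cutoff/3, cutoff; observed variance split evenly between
nugget and partial sill). The Matérn smoothness $\kappa$ is profiled over
the fixed grid {0.3, 0.5, 1, 2, 5} rather than optimized continuously —
the likelihood in $\kappa$ is notoriously flat and joint optimization is
ill-conditioned. At $\kappa = 0.5$ both Matérn forms reduce exactly to the
exponential model, which the tests exploit.

Model selection minimizes the *unweighted* error sum
$\sum_h (\hat\gamma_h - \gamma(h))^2$; every family has the same three free
parameters, so no complexity penalty applies. Exact ties break by the
canonical family order (nugget-only < exponential < spherical < Gaussian <
Matérn < Stein), documented because selection among tied
reparameterizations is otherwise arbitrary.

**A known identifiability limit.** On a single 16 × 24 realization of an
exponential field whose effective range is half the field's long axis,
neither weighted least squares nor exact Gaussian maximum likelihood pins
the range parameter to much better than ~25–35% median relative error
(sills do somewhat better). We measured this by simulation against the
package's own generator and against a maximum-likelihood fit; it is a
property of the amount of information in one realization, not of the
fitting code. Parameter-recovery expectations for single fields should be
set accordingly; averaging over replicate fields, or fields whose range is
small relative to the extent, recovers parameters well.

## Evidence of spatial structure

Whether a property is spatially structured at all is tested separately
from family selection, by REML likelihood-ratio tests: an intercept-only
Gaussian model against the same model with spherical, exponential,
Gaussian, linear, or rational-quadratic correlation (this family set
intentionally differs from the kriging families; it is the conventional
set for correlation-structure testing in mixed-model software, and the two
procedures serve different purposes — detection versus interpolation).
Each LRT uses a plain $\chi^2_1$ reference for the extra correlation
parameter. Under the null the parameter sits on its boundary, so this
reference is conservative; simulations in the acceptance suite show the
realized false-flag rate of the any-structure union test at or below the
nominal 5%. A property is flagged spatial when any structure achieves
p < 0.05. Non-converging structures are skipped with a warning.

## Ordinary kriging

Interpolation solves, per target, the augmented system
$[\Gamma\; 1; 1^\top\; 0][\lambda; \mu] = [\gamma_0; 1]$ and reports
$\hat z_0 = \lambda^\top z$ with variance
$\lambda^\top\gamma_0 + \mu$. All observations enter every prediction
(global neighborhood): fields of a few hundred plots need no search-radius
machinery. Because $\gamma(0) = 0$ on the diagonal, kriging interpolates
exactly at observed plots even with a positive nugget. Distinct samples at
identical coordinates are separated by the nugget ($\gamma(0^+) = n$) off
the diagonal, so duplicates are permitted when $n > 0$ and raise a named
error when $n = 0$ (the system is genuinely singular there).

Leave-one-out cross-validation holds the variogram fixed across folds by
default (refitting per fold is selectable); standardized errors
$(\hat z_{-i} - z_i)/\sigma_{K,i}$ should resemble standard normal draws
under a well-specified model, and the acceptance suite verifies mean within
±0.15 and SD within 0.85–1.15 at 200 plots.

## Principal component regression

Residualized properties are centered and scaled to unit variance before
PCA — the properties span several orders of magnitude of raw units (ppm
versus percent versus mmho/cm), and an unscaled decomposition would simply
recover the most abundant cation. Loadings carry a deterministic sign
convention (largest-magnitude loading positive). Components are kept when
they explain at least 10% of the variance, at most `blocks − 3` of them, so
the design effects remain estimable afterwards. Selected scores are kriged
to all plots by the same variogram-selection-plus-kriging path as any
property.

Continuous traits are adjusted through the linear mixed model
$$y = \alpha + \textstyle\sum_j \beta_j \mathrm{PC}_{j,krig} + Z +
\varepsilon,$$
fitted by REML, where $Z$ is a block random intercept with exponential
spatial correlation among the plots of each block — the "spatial structure
nested within replicate" term. The exponential family for $Z$ is a
package choice (the nesting requirement does not dictate a family);
exponential is the least smooth of the standard options and therefore the
most conservative competitor to the fixed-effect soil terms. The adjusted
trait is $y - \sum_j \hat\beta_j \mathrm{PC}_{j,krig}$ — intercept and
design effects untouched, so adjusted values stay on the measurement
scale. The 95% change interval is the empirical 2.5/97.5 percentile band
of (adjusted − observed), a descriptive flag for strongly shifted plots,
deliberately not a model-based confidence interval. If the spatial mixed
model fails to converge the fit falls back to fixed effects with a
warning.

One behavior to be aware of: a flexible spatial random effect competes
with spatially smooth fixed covariates (the kriged scores are smooth by
construction), which can attenuate $\hat\beta$ on individual realizations
— the classic spatial-confounding phenomenon. It is inherent to this model
family; validation therefore aggregates over replicate simulated fields
rather than judging single realizations.

Counts are adjusted per OTU and per compartment with a zero-inflated
negative binomial: log-mean $\alpha + \sum_j b_j \mathrm{PC}_{j,krig}$ plus
a block random intercept, intercept-only zero-inflation, per-OTU
dispersion. The block intercept stands in for the nested spatial term — a
full spatially correlated ZINB is out of scope, and with 48 plots per
block the intercept captures most of the between-block structure.
Convergence requires a positive-definite Hessian and finite coefficients;
failing OTUs are dropped and tallied in a retention report (sparse OTUs
fail most often, which is why real tables retain only a minority of taxa).
Counts are rounded to integers for the likelihood only.

The back-transformation divides each observed count by the exponentiated
soil part of its own linear predictor,
$\mathrm{adj}_i = \mathrm{obs}_i / \exp(\sum_j \hat b_j
\mathrm{PC}_{j,krig,i})$. A constant-divisor variant
($\exp(b_1 + b_2 + b_3)$, i.e. the coefficients summed once rather than
evaluated per sample) is available behind `literal_constant = TRUE` for
comparability with analyses that used that form, but it rescales every
sample of an OTU identically and therefore adjusts nothing in relative
terms; the per-sample form is the default and the one all tests target.

## Association tests

Multivariate (microbiome) responses use the Canberra distance,
$d(x,y) = \sum_k |x_k - y_k|/(x_k + y_k)$ with 0/0 features skipped — not
counted and not rescaled; implementations disagree here, and the
convention is stated because it changes absolute distances (though not
test decisions that condition on a common implementation). Testing is
distance-based redundancy analysis: principal-coordinate embedding
(negative-eigenvalue axes dropped with a warning that logs the lost
inertia; no Lingoes/Cailliez correction), responses residualized on the
conditioning terms, pseudo-F for the tested term, and p-values from free
permutation of reduced-model residuals (Freedman–Lane). Free permutation
is the default because the tested soil covariates vary within and across
blocks; a within-stratum restricted scheme is available. With $B$
permutations the smallest attainable p is $1/(B+1)$ — 0.001 at the default
$B = 999$.

Continuous traits use the mixed model above with the design terms included
and a type-III Wald $\chi^2$ (1 df) for the kriged property. Design
partial $R^2$ values are marginal sums of squares from dropping each
term's sum-contrast columns from the full design matrix, over the total
sum of squares — the type-III construction; a span-based comparison would
zero out main effects whenever their interaction is present.

## Change-point screening

The hinge model $y = \mu + \beta(x - e)_+ + \varepsilon$ is profiled over
the grid of observed distinct abundances, excluding the three smallest and
largest so both segments keep at least three support points; at each
candidate threshold the remaining two parameters are solved in closed
form, and the minimal-RSS candidate wins (ties to the smallest threshold).
The p-value for $\beta$ is a permutation test — abundance permuted against
phenotype, the hinge re-profiled per permutation (computed for all
permutations in one matrix product) — because the estimated threshold
makes the usual F asymptotics invalid. Screening across OTUs applies
Benjamini–Hochberg FDR within each version (observed / adjusted) and
reports before/after/intersection counts.

## The synthetic generator

`simulate_field_study()` emulates the motivating study's design: a 16 × 24
grid of plots, 8 replicate blocks as vertical slabs, each split into two
whole-plots receiving the two watering treatments (randomized per block),
24 genotypes randomized within whole-plots. Soil properties are linear
mixes of three latent Gaussian random fields plus independent measurement
noise, shifted to positive raw units; the latent fields default to
exponential variograms with nugget 0.1, partial sill 1, and ranges 8, 5,
and 3 plot units — deliberately heterogeneous correlation lengths, matching
fields where one property forms broad bands while another varies over a
few plots. Soil is observed on a stride-2 lattice (~25% of plots) by
default, configurable to denser sampling. Phenotypes are built from
genotype, treatment, interaction, block and residual effects plus a linear
term in the latent fields; defaults give the height-like trait a soil
component loading mainly on the longest-range gradient. OTU counts are
zero-inflated negative binomial (dispersion 1, zero-inflation 0.2, half
the OTUs responding to the gradients) per compartment. All randomness
flows from one master seed through fixed per-stage sub-seeds
(`seed × 1009 + stage`, documented stream order), so every table is
reproducible independently of how many stages a caller consumes.

What the generator does *not* emulate: read-level sequencing noise and
compositional coupling between OTUs (counts are independent given the
latent fields), temporal drift of soil properties, anisotropy, and
non-Gaussian property distributions beyond the positivity shift. Passing
tests therefore demonstrate correct recovery of the generating model's
structure, not robustness to every failure mode of real fields.

## What the tests show (and problem sizes)

The test suite validates each stage by parameter recovery at desk scale:
variogram recovery and selection over 50 replicate 16 × 24 fields; kriging
exactness, the Σλ = 1 constraint, and agreement to 1e−6 with an
independently assembled brute-force solve on random 12-point systems;
LOOCV calibration at 200 plots over 20 replicates; LRT level (200 null
fields) and power (100 strong-gradient fields) at 96 lattice plots;
PERMANOVA type-I error over 200 null datasets of 48 samples × 199
permutations; ZINB recovery at 300 samples × 100 OTUs; and the
change-point screen's precision with 10 planted signals among 100 OTUs
over 20 cohorts. These sizes were chosen as the smallest at which the
Monte-Carlo error of each check is comfortably below its tolerance.

The end-to-end denoising check samples soil at *every* plot. That choice
isolates what it validates — the PCA → kriging → mixed-model →
residual-extraction chain — from the information ceiling described under
"Stationarity by residualization": with the default 25% mask, the
design-residualization step itself discards roughly half of the latent
gradient regardless of how well every later stage works, capping the
achievable correlation reduction. Under dense sampling the chain removes
most of the latent gradient (median correlation ratio well under 0.5) and
strictly increases the design terms' partial $R^2$; under the sparse
default the same directions hold with smaller magnitudes, and the
module-level tests verify exactly that.

## Known limitations

- Isotropic variograms only; no spatio-temporal extension.
- Range parameters of long-range fields are weakly identified from a
  single realization (see above); report sills and effective ranges with
  that caveat.
- The ZINB uses a block random intercept, not a spatially correlated one.
- Permutation tests are exchangeable-residual approximations; restricted
  schemes are available but not the default.
- The change-point screen fixes the hinge shape (flat, then linear);
  pre-threshold slopes or step responses are out of scope.
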