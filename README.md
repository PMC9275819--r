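# fieldkrige

Soil is not uniform. Across an agricultural field trial, nutrients, salinity,
pH and organic matter drift in smooth spatial gradients that act as unplanned
"microtreatments": they inflate the noise of every plot-level measurement and
can masquerade as — or mask — the effects of the treatments the experiment
was designed to test. `fieldkrige` is an R package for **identifying,
estimating, and removing the effects of spatially distributed soil
properties** on plant phenotypes and microbiome count tables from split-plot
field trials, using a small number of degrees of freedom.

The pipeline, for a trial with layout factors *Treatment*, *Genotype*, and
replicate blocks:

1. **Residualize** each measured soil property on the experimental design,
   `Property = µ + Treatment + Genotype + Treatment:Genotype + ε`, so the
   residual field is (approximately) stationary.
2. **Model spatial structure**: estimate the empirical semivariogram
   γ̂(h) = (1/2N_h) Σ (z_i − z_j)², fit six variogram families
   (no-structure, exponential, spherical, Gaussian, Matérn, Stein's Matérn)
   by weighted least squares, and select the minimum-SSE model. Evidence of
   spatial structure is tested separately by REML likelihood-ratio tests of
   spatial correlation structures against an intercept-only model.
3. **Krige**: interpolate each spatially structured property (and, later,
   principal-component scores) to every plot by ordinary kriging,
   ẑ₀ = Σ λᵢ zᵢ with Σ λᵢ = 1, with leave-one-out cross-validation as the
   calibration check.
4. **Test associations**: per-property type-III Wald χ² tests in mixed
   models with spatially correlated block effects (continuous traits), and
   Canberra-distance constrained permutation ANOVA (999 permutations) for
   microbiome composition.
5. **Denoise by principal component regression**: PCA of the residualized
   properties, keep components with ≥ 10% variance explained (at most
   `blocks − 3`), krige the scores, and fit
   `g(E(y)) = α + β₁PC1 + β₂PC2 + β₃PC3 + Z` — identity link for continuous
   traits (adjusted value = observed − Σβ̂ⱼPCⱼ), log-link zero-inflated
   negative binomial per OTU for counts (adjusted count = observed /
   exp(Σ b̂ⱼPCⱼ)).
6. **Screen change-points**: hinge (flat-then-linear) models of phenotype
   on OTU abundance, with permutation p-values and Benjamini–Hochberg FDR,
   before versus after adjustment.

A synthetic-data module (`sim_config()` / `simulate_field_study()`)
generates complete split-plot studies — Gaussian-random-field soil
gradients, design effects, zero-inflated negative-binomial OTU counts —
with every generating parameter recorded, so the whole chain is validated
by parameter recovery.

## Worked example

```r
library(fieldkrige)

sim <- simulate_field_study(sim_config(seed = 42))   # 16 x 24 plots, 8 blocks
res <- residualize(sim$soil, sim$layout)             # design-effect removal

# evidence of spatial structure for one property
coords <- sim$layout[match(res$plot_id, sim$layout$plot_id), c("row", "col")]
glance(test_spatial_structure(res$phosphate, coords))
#>   spatial best_structure min_p_value n_converged alpha
#> 1 TRUE    exponential       0.000193           5  0.05

# variogram fitting and model selection
ev <- empirical_variogram(res$phosphate, coords)
select_best_model(fit_all_variograms(ev))
#> <variogram_model> spherical
#>   nugget: 192.3634  partial sill: 398.0195  range: 6.402375
#>   sse: 6933.723

# principal components of the residual soil table
pc <- pca_residual_soil(res)
tidy(pc)
#>   component  sdev percent_var cumulative_var
#> 1         1  2.00        33.5           33.5
#> 2         2  1.88        29.6           63.1
#> 3         3  1.74        25.3           88.3

# krige the selected scores and strip their effect from a phenotype
pck <- krige_pc_scores(pc, sim$layout,
                       components = select_pcs(pc, n_blocks = 8))
adj <- pcr_adjust_continuous(sim$phenotypes$height, pck, sim$layout)
glance(adj)
#>     n mean_abs_change interval_lower interval_upper spatial_fit
#> 1 384            1.49          -4.43           3.87 TRUE
```

The spatial-structure test flags phosphate-like properties (p ≈ 2e-4
against the intercept-only model); the selected spherical variogram says
about 67% of the residual variance (partial sill 398 of sill 590) is
spatially structured with a ~6-plot range; the first three components carry
88% of the soil-property variance; and the height adjustment shifts plots
by ±4 cm at the 95% change interval. Because the generator records its
truth, you can verify the denoising directly: the correlation between
height and the latent soil gradient drops from 0.35 (observed) to 0.26
(adjusted) under the default sparse soil sampling, and much further when
soil is sampled densely (see the methods vignette).

`autoplot()` methods cover the main result types (empirical variograms with
fitted curves, kriged surfaces, scree/contribution plots, observed-vs-change
diagnostics, hinge fits); `tidy()`/`glance()` return tibbles everywhere.

A thin command-line front end ships at `inst/cli/fieldkrige`
(subcommands `simulate`, `residualize`, `variogram`, `krige`, `run`, ...),
and `run_pipeline(run_config(...))` orchestrates the whole chain with a
manifest (seed, parameter hash, output hashes) for reproducibility.

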