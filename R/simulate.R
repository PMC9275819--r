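#' Simulate a Gaussian random field on a set of locations
#'
#' Draws from the zero-mean multivariate normal whose covariance function is
#' implied by a variogram model, \eqn{C(h) = (nugget + psill) - \gamma(h)},
#' via dense Cholesky factorization — exact at the few-hundred-location
#' scale of a field trial. Used both to emulate spatially structured soil
#' properties and as the test oracle for the variogram and kriging stages.
#'
#' @param coords Two-column matrix/data frame of locations.
#' @param model A [variogram_model()].
#' @param seed Integer seed.
#' @return Numeric vector of simulated values, one per location.
#' @export
simulate_grf <- function(coords, model, seed) {
  stopifnot(inherits(model, "variogram_model"))
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) {
    abort("coordinates must be finite", class = "fieldkrige_domain_error")
  }
  n <- nrow(coords)
  sill <- model$nugget + model$psill
  set.seed(as.integer(seed))
  if (sill == 0) return(numeric(n))
  d <- as.matrix(dist(coords))
  C <- sill - matrix(model_semivariance(model, as.vector(d)), n, n)
  L <- tryCatch(
    chol(C + diag(1e-8 * sill, n)),
    error = function(e) {
      abort(paste0("covariance implied by the '", model$family,
                   "' model is not positive semi-definite after jitter"),
            class = "fieldkrige_psd_error")
    }
  )
  as.numeric(t(L) %*% rnorm(n))
}

# deterministic sub-seed per generation stage, all < 2^31
stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 1009 + stage) %% 2147483647
}

#' Configuration for a synthetic split-plot field study
#'
#' Defaults emulate the real trial the package was built around: 24
#' genotypes under 2 watering treatments (well-watered `WW`, water-stressed
#' `WS`) in 8 replicate blocks on a 16 x 24 plot grid. Blocks are vertical
#' slabs of `cols / n_blocks` columns; each block is split horizontally into
#' two whole-plots that receive the two treatments (randomized per block),
#' and every genotype appears once per whole-plot.
#'
#' Soil properties are linear mixes of `n_latent` latent Gaussian random
#' fields (inducing correlation blocks between properties) plus independent
#' measurement noise, shifted so all values are positive; soil is measured
#' only on a sparse regular lattice of plots (default every second row and
#' column, ~25% of the field). Phenotypes receive genotype, treatment,
#' interaction, block and residual effects plus a linear soil-gradient term
#' through the latent fields. OTU counts are zero-inflated negative
#' binomial with log-mean depending on the latent fields.
#'
#' @param rows,cols Grid dimensions (`rows * cols` plots).
#' @param n_blocks Number of replicate blocks (vertical slabs).
#' @param n_genotypes Number of genotypes; must equal
#'   `(rows / 2) * (cols / n_blocks)`.
#' @param treatments Two treatment labels.
#' @param n_latent Number of latent spatial gradients.
#' @param latent_model [variogram_model()] for each latent field (recycled
#'   if a single model is given; otherwise a list of length `n_latent`).
#'   The default gives the three gradients distinctly different
#'   correlation lengths (ranges 8, 5, 3 plot units), emulating fields in
#'   which some properties form broad bands while others vary over a few
#'   plots.
#' @param property_names Soil property names (default the 12 measured in
#'   the motivating trial).
#' @param property_noise_sd Independent noise added to each property on the
#'   latent (standardized) scale.
#' @param soil_mask_stride Soil is sampled at plots whose row and column
#'   indices are multiples of this stride (default 2, i.e. 25% of plots);
#'   `1` samples every plot.
#' @param traits Named list of phenotype configurations; each element is a
#'   list with `genotype_sd`, `treatment_effect`, `interaction_sd`,
#'   `soil_coefs` (length `n_latent`), `block_sd`, `resid_sd`, `intercept`.
#' @param n_otus Number of OTUs.
#' @param compartments Compartment labels sampled at every plot.
#' @param otu_baseline_range Range of per-OTU baseline log-means (log
#'   counts).
#' @param otu_effect_frac Fraction of OTUs whose log-mean responds to the
#'   latent soil gradients.
#' @param otu_coef_sd Standard deviation of nonzero soil-to-log-mean
#'   coefficients.
#' @param otu_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param zi_prob Zero-inflation probability in `[0, 1)`.
#' @param seed Integer master seed; all stage randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(rows = 16, cols = 24, n_blocks = 8, n_genotypes = 24,
                       treatments = c("WW", "WS"),
                       n_latent = 3,
                       latent_model = lapply(
                         c(8, 5, 3)[seq_len(min(n_latent, 3))],
                         function(r) variogram_model("exponential",
                                                     nugget = 0.1,
                                                     psill = 1, range = r)),
                       property_names = c(
                         "salinity", "nitrate", "sulfate", "calcium",
                         "magnesium", "phosphate", "potassium", "sodium",
                         "ph", "organic_matter", "cation_sum", "buffer_ph"),
                       property_noise_sd = 0.3,
                       soil_mask_stride = 2,
                       traits = NULL,
                       n_otus = 50,
                       compartments = c("root", "rhizosphere", "soil"),
                       otu_baseline_range = c(log(20), log(400)),
                       otu_effect_frac = 0.5,
                       otu_coef_sd = 0.5,
                       otu_dispersion = 1,
                       zi_prob = 0.2,
                       seed = 1) {
  if (rows %% 2 != 0 || cols %% n_blocks != 0) {
    abort("rows must be even and cols divisible by n_blocks",
          class = "fieldkrige_config_error")
  }
  if ((rows / 2) * (cols / n_blocks) != n_genotypes) {
    abort(paste0("grid does not hold the design: need (rows/2)*(cols/",
                 "n_blocks) == n_genotypes"),
          class = "fieldkrige_config_error")
  }
  if (length(treatments) != 2) {
    abort("exactly two treatment labels are required",
          class = "fieldkrige_config_error")
  }
  if (zi_prob < 0 || zi_prob >= 1) {
    abort("zi_prob must be in [0, 1)", class = "fieldkrige_config_error")
  }
  if (otu_dispersion <= 0) {
    abort("otu_dispersion must be > 0", class = "fieldkrige_config_error")
  }
  if (inherits(latent_model, "variogram_model")) {
    latent_model <- list(latent_model)
  }
  latent_model <- rep_len(latent_model, n_latent)
  if (is.null(traits)) {
    traits <- list(
      height = list(intercept = 100, genotype_sd = 8, treatment_effect = -12,
                    interaction_sd = 2, soil_coefs = c(5, 2, rep(0, max(0, n_latent - 2)))[seq_len(n_latent)],
                    block_sd = 3, resid_sd = 5),
      fresh_weight = list(intercept = 400, genotype_sd = 40,
                          treatment_effect = -80, interaction_sd = 10,
                          soil_coefs = c(10, 0, rep(0, max(0, n_latent - 2)))[seq_len(n_latent)],
                          block_sd = 15, resid_sd = 30)
    )
  }
  structure(
    list(rows = rows, cols = cols, n_blocks = n_blocks,
         n_genotypes = n_genotypes, treatments = treatments,
         n_latent = n_latent, latent_model = latent_model,
         property_names = property_names,
         property_noise_sd = property_noise_sd,
         soil_mask_stride = soil_mask_stride, traits = traits,
         n_otus = n_otus, compartments = compartments,
         otu_baseline_range = otu_baseline_range,
         otu_effect_frac = otu_effect_frac, otu_coef_sd = otu_coef_sd,
         otu_dispersion = otu_dispersion, zi_prob = zi_prob,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a complete split-plot field study
#'
#' Generates the four tables every downstream stage consumes — layout, soil
#' properties at the masked plots, plot-level phenotypes, and a wide OTU
#' count table — together with a `truth` record holding every generating
#' parameter and the latent fields, for parameter-recovery testing.
#'
#' @param cfg A [sim_config()].
#' @return A list `layout`, `soil`, `phenotypes`, `otus`, `truth`.
#' @export
simulate_field_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rows <- cfg$rows; cols <- cfg$cols
  nb <- cfg$n_blocks; ng <- cfg$n_genotypes
  block_cols <- cols / nb
  grid <- expand.grid(row = 0:(rows - 1), col = 0:(cols - 1))
  n_plots <- nrow(grid)
  block <- grid$col %/% block_cols + 1
  whole_plot <- ifelse(grid$row < rows / 2, 1L, 2L)

  # stage 1: treatment + genotype randomization
  set.seed(stage_seed(cfg$seed, 1))
  treatment <- character(n_plots)
  genotype <- character(n_plots)
  geno_labels <- sprintf("g%02d", seq_len(ng))
  for (b in seq_len(nb)) {
    trt_order <- sample(cfg$treatments)
    for (wp in 1:2) {
      idx <- which(block == b & whole_plot == wp)
      treatment[idx] <- trt_order[wp]
      genotype[idx] <- sample(geno_labels)
    }
  }
  layout <- tibble(
    plot_id = sprintf("plot_%03d", seq_len(n_plots)),
    row = grid$row, col = grid$col,
    block = factor(block), treatment = factor(treatment, cfg$treatments),
    genotype = factor(genotype, geno_labels)
  )

  # stage 2: latent spatial gradients
  coords <- cbind(layout$row, layout$col)
  latent <- vapply(seq_len(cfg$n_latent), function(j) {
    simulate_grf(coords, cfg$latent_model[[j]],
                 seed = stage_seed(cfg$seed, 10 + j))
  }, numeric(n_plots))
  colnames(latent) <- paste0("latent", seq_len(cfg$n_latent))

  # stage 3: soil properties = mixes of latent fields + noise, positive scale
  set.seed(stage_seed(cfg$seed, 2))
  np <- length(cfg$property_names)
  mixing <- matrix(0, cfg$n_latent, np,
                   dimnames = list(colnames(latent), cfg$property_names))
  # each property loads mainly on one latent field -> correlation blocks
  main <- rep(seq_len(cfg$n_latent), length.out = np)
  for (p in seq_len(np)) {
    w <- rnorm(cfg$n_latent, 0, 0.2)
    w[main[p]] <- sample(c(-1, 1), 1) * runif(1, 0.8, 1.2)
    mixing[, p] <- w
  }
  soil_std <- latent %*% mixing +
    matrix(rnorm(n_plots * np, 0, cfg$property_noise_sd), n_plots, np)
  # shift/scale to plausible positive raw units per property
  prop_scale <- runif(np, 0.5, 50)
  prop_center <- prop_scale * runif(np, 4, 10)
  soil_raw <- sweep(sweep(soil_std, 2, prop_scale, "*"), 2, prop_center, "+")
  soil_raw <- pmax(soil_raw, 0.01)
  mask <- layout$row %% cfg$soil_mask_stride == 0 &
    layout$col %% cfg$soil_mask_stride == 0
  soil <- bind_cols(tibble(plot_id = layout$plot_id),
                    as_tibble(soil_raw))[mask, ]

  # stage 4: phenotypes
  set.seed(stage_seed(cfg$seed, 3))
  gi <- as.integer(layout$genotype)
  ti <- as.integer(layout$treatment)
  bi <- as.integer(layout$block)
  trait_truth <- list()
  phen <- tibble(plot_id = layout$plot_id)
  for (tn in names(cfg$traits)) {
    tc <- cfg$traits[[tn]]
    g_eff <- rnorm(ng, 0, tc$genotype_sd)
    i_eff <- matrix(rnorm(2 * ng, 0, tc$interaction_sd), 2, ng)
    b_eff <- rnorm(nb, 0, tc$block_sd)
    t_eff <- c(-0.5, 0.5) * tc$treatment_effect
    soil_part <- as.numeric(latent %*% tc$soil_coefs)
    y <- tc$intercept + g_eff[gi] + t_eff[ti] + i_eff[cbind(ti, gi)] +
      b_eff[bi] + soil_part + rnorm(n_plots, 0, tc$resid_sd)
    phen[[tn]] <- y
    trait_truth[[tn]] <- list(genotype = g_eff, treatment = t_eff,
                              interaction = i_eff, block = b_eff,
                              soil_coefs = tc$soil_coefs,
                              soil_part = soil_part)
  }

  # stage 5: OTU counts (zero-inflated negative binomial)
  set.seed(stage_seed(cfg$seed, 4))
  no <- cfg$n_otus
  otu_names <- sprintf("otu_%04d", seq_len(no))
  baseline <- runif(no, cfg$otu_baseline_range[1], cfg$otu_baseline_range[2])
  responds <- runif(no) < cfg$otu_effect_frac
  b_coef <- matrix(0, no, cfg$n_latent,
                   dimnames = list(otu_names, colnames(latent)))
  b_coef[responds, ] <- rnorm(sum(responds) * cfg$n_latent, 0, cfg$otu_coef_sd)
  comp_eff <- matrix(rnorm(no * length(cfg$compartments), 0, 0.7), no,
                     dimnames = list(otu_names, cfg$compartments))
  otu_rows <- list()
  for (comp in cfg$compartments) {
    logmu <- outer(rep(1, n_plots), baseline + comp_eff[, comp]) +
      latent %*% t(b_coef)
    mu <- exp(logmu)
    counts <- matrix(rnbinom(n_plots * no, mu = mu, size = cfg$otu_dispersion),
                     n_plots, no)
    counts[matrix(runif(n_plots * no) < cfg$zi_prob, n_plots, no)] <- 0L
    colnames(counts) <- otu_names
    otu_rows[[comp]] <- bind_cols(
      tibble(sample_id = paste0(layout$plot_id, "_", comp),
             plot_id = layout$plot_id, compartment = comp),
      as_tibble(counts)
    )
  }
  otus <- bind_rows(otu_rows)

  truth <- list(
    config = cfg, latent = latent, mixing = mixing,
    soil_mask = mask, prop_scale = prop_scale, prop_center = prop_center,
    traits = trait_truth,
    otu = list(baseline = baseline, coefs = b_coef, responds = responds,
               compartment_effects = comp_eff,
               dispersion = cfg$otu_dispersion, zi_prob = cfg$zi_prob)
  )
  list(layout = layout, soil = soil, phenotypes = phen, otus = otus,
       truth = truth)
}
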