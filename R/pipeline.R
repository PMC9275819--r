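#' Default pipeline configuration
#'
#' Stage parameters default to the values of the motivating study where it
#' states them: permutation tests use 999 iterations, components need at
#' least 10% variance explained, OTU QC keeps samples with >= 10000 reads
#' and OTUs with a grand total in \[100, 200000\].
#'
#' @param layout,soil,phenotypes,otus Input table paths (all `NULL` to
#'   simulate instead).
#' @param simulate `TRUE` to generate the inputs with
#'   [simulate_field_study()].
#' @param sim Options passed to [sim_config()] when simulating.
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param n_lags,cutoff Empirical variogram settings.
#' @param min_pct PC selection threshold (percent variance).
#' @param n_perm Permutation count for PERMANOVA and change-point tests.
#' @param min_sample_depth,min_otu_total,max_otu_total OTU QC thresholds.
#' @param alpha Significance level used for flags.
#' @param screen Options for the change-point screen: `trait`,
#'   `treatment`, `compartment` (NULL skips the screen).
#' @return A `run_config` list.
#' @export
run_config <- function(layout = NULL, soil = NULL, phenotypes = NULL,
                       otus = NULL, simulate = is.null(layout),
                       sim = list(), out_dir = "fieldkrige_out", seed = 1,
                       n_lags = 15, cutoff = NULL, min_pct = 10,
                       n_perm = 999, min_sample_depth = 10000,
                       min_otu_total = 100, max_otu_total = 200000,
                       alpha = 0.05,
                       screen = list(trait = NULL, treatment = NULL,
                                     compartment = NULL)) {
  structure(
    list(layout = layout, soil = soil, phenotypes = phenotypes, otus = otus,
         simulate = simulate, sim = sim, out_dir = out_dir,
         seed = as.integer(seed), n_lags = n_lags, cutoff = cutoff,
         min_pct = min_pct, n_perm = n_perm,
         min_sample_depth = min_sample_depth,
         min_otu_total = min_otu_total, max_otu_total = max_otu_total,
         alpha = alpha, screen = screen),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "fieldkrige_config_error")
  }
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full denoising pipeline
#'
#' Orchestrates: input loading (or simulation), design-effect
#' residualization of the soil properties, the spatial-structure LRT per
#' property, variogram fitting and ordinary kriging of the spatially
#' structured properties, PCA of the residualized properties with PC
#' selection and kriging of the selected scores, phenotype adjustment by
#' principal component regression, OTU QC / depth scaling / count
#' adjustment, design partial R-squared before and after adjustment, and
#' (optionally) the change-point screen. All tabular outputs are TSV,
#' model summaries JSON; a manifest records the package version, seed, and
#' a hash of the configuration and of every written file.
#'
#' @param cfg A [run_config()].
#' @return The manifest (a list), invisibly; outputs under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (p in c("layout", "soil", "phenotypes", "otus")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      abort(paste0("input path does not exist: ", cfg[[p]]),
            class = "fieldkrige_config_error")
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(tbl, name) {
    path <- file.path(cfg$out_dir, name)
    write_field_table(tbl, path)
    written <<- c(written, path)
    path
  }
  emit_json <- function(x, name) {
    path <- file.path(cfg$out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <<- c(written, path)
    path
  }

  if (cfg$simulate) {
    sim <- simulate_field_study(do.call(sim_config,
                                        c(cfg$sim, list(seed = cfg$seed))))
    layout <- sim$layout; soil <- sim$soil
    phen <- sim$phenotypes; otus <- sim$otus
    emit(layout, "layout.tsv"); emit(soil, "soil.tsv")
    emit(phen, "phenotypes.tsv"); emit(otus, "otus.tsv")
  } else {
    inputs <- read_field_tables(cfg$layout, cfg$soil, cfg$phenotypes,
                                cfg$otus)
    layout <- inputs$layout; soil <- inputs$soil
    phen <- inputs$phenotypes; otus <- inputs$otus
  }

  # 1. residualize soil properties on the design
  resid <- residualize(soil, layout)
  emit(resid, "soil_residuals.tsv")
  coords_obs <- layout[match(resid$plot_id, layout$plot_id), c("row", "col")]
  props <- setdiff(names(resid), "plot_id")

  # 2. spatial-structure evidence per property
  struct <- map(props, function(p) {
    g <- glance(test_spatial_structure(resid[[p]], coords_obs,
                                       alpha = cfg$alpha))
    mutate(g, property = p, .before = 1)
  }) %>% bind_rows()
  emit(struct, "spatial_structure.tsv")
  spatial_props <- struct$property[struct$spatial]

  # 3. variogram + kriging for the spatially structured properties
  vgm_records <- list()
  kriged <- tibble(plot_id = layout$plot_id)
  for (p in spatial_props) {
    ev <- empirical_variogram(resid[[p]], coords_obs, n_lags = cfg$n_lags,
                              cutoff = cfg$cutoff)
    fits <- fit_all_variograms(ev)
    best <- select_best_model(fits)
    vgm_records[[p]] <- list(
      best = unclass(best)[c("family", "nugget", "psill", "range",
                             "kappa", "sse")],
      sse_by_family = lapply(fits, `[[`, "sse")
    )
    kf <- krige_field(layout, resid[[p]], resid$plot_id, model = best)
    kriged[[p]] <- kf$predicted
  }
  emit_json(vgm_records, "variograms.json")
  if (length(spatial_props) > 0) emit(kriged, "kriged_properties.tsv")

  # 4. PCA, PC selection, kriged scores
  pc <- pca_residual_soil(resid)
  sel <- select_pcs(pc, min_pct = cfg$min_pct,
                    n_blocks = nlevels(layout$block))
  emit(tidy(pc), "pca_scree.tsv")
  emit(bind_rows(lapply(seq_along(pc$percent_var)[seq_len(min(3,
         length(pc$percent_var)))], function(k)
         property_contributions(pc, k))), "pca_contributions.tsv")
  scores_k <- NULL
  if (length(sel) > 0) {
    scores_k <- krige_pc_scores(pc, layout, components = sel,
                                n_lags = cfg$n_lags, cutoff = cfg$cutoff)
    emit(scores_k, "kriged_pc_scores.tsv")
  }

  # 5. phenotype adjustment + association tests
  assoc <- list()
  traits <- setdiff(names(phen), "plot_id")
  adj_phen <- tibble(plot_id = layout$plot_id)
  r2_rows <- list()
  for (tr in traits) {
    yv <- phen[[tr]][match(layout$plot_id, phen$plot_id)]
    for (p in spatial_props) {
      a <- type3_property_test(yv, kriged[[p]], layout)
      assoc[[paste(tr, p)]] <- mutate(a, trait = tr, property = p,
                                      .before = 1)
    }
    if (!is.null(scores_k)) {
      at <- pcr_adjust_continuous(yv, scores_k, layout)
      adj_phen[[tr]] <- at$adjusted
      dd <- as.data.frame(layout)
      r2_rows[[paste(tr, "before")]] <- mutate(
        design_partial_r2(yv, dd), trait = tr, version = "observed")
      r2_rows[[paste(tr, "after")]] <- mutate(
        design_partial_r2(at$adjusted, dd), trait = tr,
        version = "adjusted")
    }
  }
  if (length(assoc) > 0) emit(bind_rows(assoc), "associations.tsv")
  if (ncol(adj_phen) > 1) emit(adj_phen, "adjusted_phenotypes.tsv")
  if (length(r2_rows) > 0) emit(bind_rows(r2_rows), "design_partial_r2.tsv")

  # 6. OTU QC, scaling, adjustment, PERMANOVA
  retention <- NULL
  if (!is.null(otus) && !is.null(scores_k)) {
    otus_f <- filter_otu_table(otus, cfg$min_sample_depth,
                               cfg$min_otu_total, cfg$max_otu_total)
    otus_s <- scale_to_common_depth(otus_f)
    perm_rows <- list()
    if (length(spatial_props) > 0) {
      d <- canberra_distance(otus_s)
      dat <- as.data.frame(layout[match(otus_s$plot_id, layout$plot_id), ])
      dat$compartment <- factor(otus_s$compartment)
      multi_comp <- nlevels(dat$compartment) > 1
      test_term <- if (multi_comp) "prop_krig:compartment" else "prop_krig"
      cond <- c("treatment", "genotype", "treatment:genotype",
                if (multi_comp) "compartment")
      for (p in spatial_props) {
        dat$prop_krig <- kriged[[p]][match(otus_s$plot_id, layout$plot_id)]
        pr <- constrained_permanova(
          d, dat, test_term, condition_terms = cond,
          n_perm = cfg$n_perm, seed = stage_seed(cfg$seed, 20))
        perm_rows[[p]] <- mutate(pr, property = p, .before = 1)
      }
      emit(bind_rows(perm_rows), "permanova.tsv")
    }
    otu_adj <- pcr_adjust_counts(otus_s, scores_k, layout)
    retention <- attr(otu_adj, "retention")
    emit(otu_adj, "adjusted_otus.tsv")
    emit_json(retention, "retention.json")

    sc <- cfg$screen
    if (!is.null(sc$trait)) {
      keep <- rep(TRUE, nrow(otu_adj))
      if (!is.null(sc$compartment)) {
        keep <- keep & otu_adj$compartment == sc$compartment
      }
      if (!is.null(sc$treatment)) {
        trt <- layout$treatment[match(otu_adj$plot_id, layout$plot_id)]
        keep <- keep & trt == sc$treatment
      }
      scr <- screen_otus(otu_adj[keep, ], phen, trait = sc$trait,
                         alpha = cfg$alpha, n_perm = cfg$n_perm,
                         seed = stage_seed(cfg$seed, 30))
      emit(scr, "changepoint_screen.tsv")
      emit_json(as.list(attr(scr, "summary")), "changepoint_summary.json")
    }
  }

  manifest <- list(
    package = "fieldkrige",
    version = as.character(packageVersion("fieldkrige")),
    seed = cfg$seed,
    config_hash = hash({
      h <- unclass(cfg)
      h$out_dir <- NULL  # the parameter hash identifies the analysis,
      h                  # not where it was written
    }),
    spatial_properties = spatial_props,
    selected_pcs = sel,
    retention = if (!is.null(retention)) as.list(retention) else NULL,
    outputs = lapply(setNames(nm = basename(written)), function(b) {
      hash(readBin(file.path(cfg$out_dir, b), "raw",
                   file.size(file.path(cfg$out_dir, b))))
    })
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
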