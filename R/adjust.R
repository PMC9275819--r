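#' Remove kriged soil-gradient effects from a continuous phenotype
#'
#' Fits the linear mixed model
#' \deqn{y = \alpha + \sum_j \beta_j \mathrm{PC}_{j,krig} + Z + \varepsilon}
#' by REML, where `Z` is a block random intercept with exponential spatial
#' correlation among the plots of each block (the spatial structure nested
#' within each split-plot replicate), and returns the soil-property-invariant
#' phenotype: `adjusted = observed - sum(beta_j * PCj_krig)`. The intercept
#' and design effects are untouched, so adjusted values stay on the original
#' measurement scale. If the spatial mixed model fails to converge a
#' fixed-effects-only fit is used with a warning.
#'
#' @param y Phenotype values, one per layout plot (NA allowed).
#' @param pcs Kriged PC scores from [krige_pc_scores()] (tibble with
#'   `plot_id` and `PC<k>_krig` columns).
#' @param layout A validated layout.
#' @param level Coverage of the empirical change interval (default 0.95);
#'   interval bounds are empirical percentiles of `adjusted - observed`
#'   across plots, flagging observations whose soil-driven shift is
#'   unusually large.
#' @return An `adjusted_table` tibble: `plot_id`, `observed`, `adjusted`,
#'   `change` (= adjusted - observed), `outside_interval`; coefficient
#'   estimates in attribute `coefficients`, interval in attribute
#'   `change_interval`, convergence flag in attribute `spatial_fit`.
#' @export
pcr_adjust_continuous <- function(y, pcs, layout, level = 0.95) {
  layout <- validate_layout(layout)
  stopifnot(length(y) == nrow(layout))
  pc_cols <- grep("^PC\\d+_krig$", names(pcs), value = TRUE)
  if (length(pc_cols) == 0) {
    abort("pcs has no PC<k>_krig columns", class = "fieldkrige_schema_error")
  }
  idx <- match(layout$plot_id, pcs$plot_id)
  if (anyNA(idx)) {
    abort("pcs must cover every layout plot",
          class = "fieldkrige_referential_error")
  }
  dat <- data.frame(y = y, block = layout$block,
                    x1 = layout$row, x2 = layout$col)
  for (cn in pc_cols) dat[[cn]] <- pcs[[cn]][idx]
  obs <- is.finite(dat$y)
  if (sum(obs) < 20) {
    abort("need at least 20 observed plots",
          class = "fieldkrige_domain_error")
  }
  fml <- as.formula(paste("y ~", paste(pc_cols, collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(nlme::lme(
      fml, random = ~ 1 | block,
      correlation = nlme::corExp(form = ~ x1 + x2 | block),
      data = dat[obs, ], method = "REML",
      control = nlme::lmeControl(returnObject = FALSE)
    )),
    error = function(e) NULL
  )
  spatial_fit <- !is.null(fit)
  if (!spatial_fit) {
    warn("spatial mixed model did not converge; using fixed-effects fit")
    fit <- lm(fml, data = dat[obs, ])
  }
  beta <- if (spatial_fit) nlme::fixef(fit) else coef(fit)
  beta <- beta[pc_cols]
  soil_part <- as.numeric(as.matrix(dat[pc_cols]) %*% beta)
  adjusted <- y - soil_part
  change <- adjusted - y
  qs <- quantile(change[obs], probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                 na.rm = TRUE, names = FALSE)
  out <- tibble(
    plot_id = layout$plot_id, observed = y, adjusted = adjusted,
    change = change,
    outside_interval = is.finite(change) & (change < qs[1] | change > qs[2])
  )
  structure(out, class = c("adjusted_table", class(tibble())),
            coefficients = beta, change_interval = qs,
            spatial_fit = spatial_fit)
}

#' @export
glance.adjusted_table <- function(x, ...) {
  ci <- attr(x, "change_interval")
  tibble(
    n = sum(is.finite(x$observed)),
    mean_abs_change = mean(abs(x$change), na.rm = TRUE),
    interval_lower = ci[1], interval_upper = ci[2],
    spatial_fit = attr(x, "spatial_fit") %||% NA
  )
}

#' Observed-versus-change diagnostic plot
#'
#' Mirrors the standard equitability check for a soil-gradient adjustment:
#' observed values against their adjustment, with the empirical change
#' interval as dashed lines. An unbiased adjustment shows no trend.
#'
#' @param object An `adjusted_table`.
#' @param ... Unused.
#' @export
autoplot.adjusted_table <- function(object, ...) {
  ci <- attr(object, "change_interval")
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$observed, y = .data$change,
                                    colour = .data$outside_interval)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "grey25"),
                                 guide = "none") +
    ggplot2::labs(x = "observed", y = "change after adjustment")
  if (!is.null(ci)) {
    p <- p + ggplot2::geom_hline(yintercept = ci, linetype = "dashed",
                                 colour = "darkgreen")
  }
  p
}

#' Back-transform counts given soil-gradient coefficients
#'
#' The count-scale adjustment divides each observed count by the
#' exponentiated soil part of its linear predictor,
#' `adjusted = observed / exp(lp)`. Identities that follow directly:
#' a zero linear predictor leaves counts untouched, zeros stay zero,
#' and the adjustment direction follows the sign of the linear predictor
#' (positive soil effect shrinks the count, negative inflates it).
#'
#' @param observed Nonnegative counts (real-valued allowed).
#' @param linear_predictor Per-observation soil linear predictor
#'   \eqn{\sum_j b_j PC_{j,krig}}.
#' @return Adjusted counts.
#' @export
adjust_count_values <- function(observed, linear_predictor) {
  if (any(observed < 0, na.rm = TRUE)) {
    abort("counts must be nonnegative", class = "fieldkrige_domain_error")
  }
  observed / exp(linear_predictor)
}

# one ZINB fit; returns NULL on any failure
fit_zinb_one <- function(counts, X, block) {
  dat <- data.frame(y = counts, X, block = block, check.names = FALSE)
  fml <- as.formula(paste("y ~", paste(colnames(X), collapse = " + "),
                          "+ (1 | block)"))
  fit <- tryCatch(
    suppressWarnings(glmmTMB::glmmTMB(
      fml, ziformula = ~ 1, family = glmmTMB::nbinom2, data = dat,
      control = glmmTMB::glmmTMBControl(
        optCtrl = list(iter.max = 200, eval.max = 400))
    )),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) return(NULL)
  ok <- isTRUE(fit$sdr$pdHess) && all(is.finite(unlist(glmmTMB::fixef(fit))))
  if (!ok) return(NULL)
  fit
}

#' Adjust OTU counts for kriged soil-gradient effects
#'
#' Per OTU and per compartment independently, fits the zero-inflated
#' negative binomial regression
#' \deqn{\log E(\mathrm{count}) = \alpha + \sum_j b_j \mathrm{PC}_{j,krig}
#'   + u_{block}}
#' (intercept-only zero-inflation, per-OTU dispersion, block random
#' intercept standing in for the nested spatial term), then divides each
#' observed count by the exponentiated soil part of its own linear
#' predictor:
#' \deqn{\mathrm{adjusted}_i = \mathrm{observed}_i /
#'   \exp(\textstyle\sum_j \hat b_j \mathrm{PC}_{j,krig,i}).}
#' Zeros stay zero and positive counts stay positive. OTUs whose fit fails
#' to converge are dropped and tallied in the retention report. Counts are
#' rounded to integers for the likelihood only; the adjustment divides the
#' (possibly depth-scaled, real-valued) observed counts.
#'
#' `literal_constant = TRUE` instead divides every sample of an OTU by the
#' same constant \eqn{\exp(b_1 + \dots + b_k)} — the printed form of the
#' adjustment formula in the source analysis. That rescales all samples of
#' an OTU identically and leaves relative abundances untouched, so the
#' per-sample form is the default.
#'
#' @param otus A filtered, depth-scaled wide OTU tibble.
#' @param pcs Kriged PC scores from [krige_pc_scores()].
#' @param layout A validated layout.
#' @param compartments Compartments to model (default all present).
#' @param literal_constant Use the constant divisor form (default `FALSE`).
#' @return An `otu_adjusted` long tibble: `sample_id`, `plot_id`,
#'   `compartment`, `otu`, `observed`, `adjusted`; per-OTU coefficients in
#'   attribute `coefficients` (tibble), retention report in attribute
#'   `retention` (tibble per compartment: attempted, converged, retained
#'   fraction).
#' @export
pcr_adjust_counts <- function(otus, pcs, layout, compartments = NULL,
                              literal_constant = FALSE) {
  layout <- validate_layout(layout)
  check_plot_ids(otus, layout, "OTU table")
  pc_cols <- grep("^PC\\d+_krig$", names(pcs), value = TRUE)
  if (length(pc_cols) == 0) {
    abort("pcs has no PC<k>_krig columns", class = "fieldkrige_schema_error")
  }
  compartments <- compartments %||% unique(otus$compartment)
  counts_all <- otu_counts(otus)
  pidx <- match(otus$plot_id, pcs$plot_id)
  bidx <- match(otus$plot_id, layout$plot_id)
  Xall <- as.matrix(as_tibble(pcs)[pc_cols])[pidx, , drop = FALSE]
  colnames(Xall) <- pc_cols
  block_all <- layout$block[bidx]
  rows <- list()
  coefs <- list()
  retention <- list()
  for (comp in compartments) {
    in_comp <- otus$compartment == comp
    X <- Xall[in_comp, , drop = FALSE]
    block <- droplevels(block_all[in_comp])
    cm <- counts_all[in_comp, , drop = FALSE]
    n_conv <- 0L
    for (otu in colnames(cm)) {
      obs <- cm[, otu]
      fit <- fit_zinb_one(round(obs), X, block)
      if (is.null(fit)) next
      n_conv <- n_conv + 1L
      b <- glmmTMB::fixef(fit)$cond[pc_cols]
      lp <- if (literal_constant) {
        rep(sum(b), length(obs))
      } else {
        as.numeric(X %*% b)
      }
      rows[[paste(comp, otu)]] <- tibble(
        sample_id = otus$sample_id[in_comp],
        plot_id = otus$plot_id[in_comp],
        compartment = comp, otu = otu,
        observed = obs, adjusted = adjust_count_values(obs, lp)
      )
      coefs[[paste(comp, otu)]] <- tibble(
        compartment = comp, otu = otu,
        term = c("(Intercept)", pc_cols),
        estimate = c(glmmTMB::fixef(fit)$cond[["(Intercept)"]], unname(b))
      )
    }
    retention[[comp]] <- tibble(
      compartment = comp, attempted = ncol(cm), converged = n_conv,
      retained_frac = if (ncol(cm) > 0) n_conv / ncol(cm) else NA_real_
    )
  }
  out <- bind_rows(rows)
  structure(out, class = c("otu_adjusted", class(tibble())),
            coefficients = bind_rows(coefs),
            retention = bind_rows(retention))
}

#' Pivot an OTU adjustment back to a wide count table
#'
#' @param adj An `otu_adjusted` tibble from [pcr_adjust_counts()].
#' @param value `"adjusted"` (default) or `"observed"`.
#' @return A wide OTU tibble (`sample_id`, `plot_id`, `compartment`, one
#'   column per retained OTU).
#' @export
otu_adjusted_wide <- function(adj, value = c("adjusted", "observed")) {
  value <- match.arg(value)
  pivot_wider(as_tibble(adj)[c(otu_meta_cols, "otu", value)],
              names_from = "otu", values_from = all_of(value))
}
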