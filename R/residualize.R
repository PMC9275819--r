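#' Remove experimental-design effects from plot-level variables
#'
#' Fits, for each requested column, the full-factorial fixed-effects model
#' `value ~ treatment * genotype` by ordinary least squares on the plots
#' where the value is observed, and returns residuals
#' (observed - fitted). Spatial modeling downstream assumes stationarity;
#' removing the design effects first is what makes the residual field
#' (approximately) stationary. Sum-to-zero contrasts are used throughout so
#' later type-III tests are meaningful.
#'
#' Rank-deficient designs (e.g. a genotype absent under one treatment) are
#' handled by the pivoting of the underlying least-squares fit: unestimable
#' columns are dropped with a warning and the fit proceeds.
#'
#' @param tbl A soil or phenotype tibble with a `plot_id` column; missing
#'   values are allowed (unsampled plots are simply not fitted).
#' @param layout A validated layout (see [validate_layout()]).
#' @param columns Columns of `tbl` to residualize; default all numeric
#'   columns except `plot_id`.
#' @return A `residual_table` tibble: `plot_id`, then for each input column
#'   `<name>` the residual, with the fitted values in attribute `fitted`
#'   (same shape). Residual + fitted reproduces the observed value exactly.
#' @examples
#' sim <- simulate_field_study(sim_config(rows = 4, cols = 4, n_blocks = 2,
#'                                        n_genotypes = 4, seed = 1))
#' res <- residualize(sim$soil, sim$layout)
#' @export
residualize <- function(tbl, layout, columns = NULL) {
  layout <- validate_layout(layout)
  check_plot_ids(tbl, layout, "input table")
  columns <- columns %||%
    names(tbl)[vapply(tbl, is.numeric, logical(1)) & names(tbl) != "plot_id"]
  idx <- match(tbl$plot_id, layout$plot_id)
  design <- tibble(
    treatment = layout$treatment[idx],
    genotype = droplevels(layout$genotype[idx])
  )
  out <- tibble(plot_id = tbl$plot_id)
  fitted_tbl <- tibble(plot_id = tbl$plot_id)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  for (cn in columns) {
    y <- tbl[[cn]]
    obs <- is.finite(y)
    r <- rep(NA_real_, length(y))
    f <- rep(NA_real_, length(y))
    if (sum(obs) > 0) {
      dat <- cbind(design[obs, ], y = y[obs])
      dat$genotype <- droplevels(dat$genotype)
      dat$treatment <- droplevels(dat$treatment)
      fit <- lm(y ~ treatment * genotype, data = dat)
      if (anyNA(coef(fit))) {
        warn(paste0("design is rank deficient for '", cn,
                    "'; unestimable columns dropped"))
      }
      f[obs] <- fitted(fit)
      r[obs] <- y[obs] - f[obs]
    }
    out[[cn]] <- r
    fitted_tbl[[cn]] <- f
  }
  structure(out, class = c("residual_table", class(tibble())),
            fitted = fitted_tbl)
}

#' @importFrom stats fitted
NULL
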