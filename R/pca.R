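#' Principal component analysis of residualized soil properties
#'
#' Centers and scales each property to unit variance (the properties live on
#' wildly different unit scales — ppm, mmho/cm, percent — so an unscaled
#' decomposition would be dominated by the most abundant cation), then
#' performs PCA. Loadings carry a deterministic sign convention: within each
#' component the largest-magnitude loading is positive.
#'
#' @param resid A `residual_table` from [residualize()] (or any tibble with
#'   `plot_id` and numeric property columns); only rows complete across all
#'   properties are used.
#' @return A `pc_model` with elements `loadings` (property x component,
#'   orthonormal), `scores` (tibble: `plot_id` + one column per component),
#'   `percent_var`, `center`, `scale`, `sdev`.
#' @export
pca_residual_soil <- function(resid) {
  props <- setdiff(names(resid)[vapply(resid, is.numeric, logical(1))],
                   "plot_id")
  if (length(props) < 2) {
    abort("need at least 2 properties for PCA",
          class = "fieldkrige_domain_error")
  }
  X <- as.matrix(resid[props])
  keep <- complete.cases(X)
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < 3) {
    abort("need at least 3 complete plots for PCA",
          class = "fieldkrige_domain_error")
  }
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant property column(s): ",
                 paste(props[sds == 0], collapse = ", ")),
          class = "fieldkrige_domain_error")
  }
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  # sign convention: largest |loading| positive per component
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- bind_cols(tibble(plot_id = resid$plot_id[keep]),
                      as_tibble(pc$x))
  structure(
    list(loadings = pc$rotation, scores = scores, percent_var = pct,
         center = pc$center, scale = pc$scale, sdev = pc$sdev),
    class = "pc_model"
  )
}

#' @export
print.pc_model <- function(x, ...) {
  cat("<pc_model> ", ncol(x$loadings), " components, ",
      nrow(x$scores), " plots\n", sep = "")
  cat("  percent variance:",
      paste(sprintf("%.1f", head(x$percent_var, 6)), collapse = ", "),
      if (length(x$percent_var) > 6) "...", "\n")
  invisible(x)
}

#' @export
tidy.pc_model <- function(x, ...) {
  tibble(component = seq_along(x$percent_var),
         sdev = x$sdev,
         percent_var = x$percent_var,
         cumulative_var = cumsum(x$percent_var))
}

#' Select principal components for regression
#'
#' Keeps, in order, the components explaining at least `min_pct` percent of
#' the total variance, truncated to at most `n_blocks - 3` components so
#' the experimental-design effects remain estimable after the regression
#' spends its degrees of freedom.
#'
#' @param pc A `pc_model`, or directly a numeric vector of percent
#'   variances.
#' @param min_pct Minimum percent variance explained (default 10).
#' @param n_blocks Number of replicate blocks (must be >= 4).
#' @return Integer vector of selected component indices (possibly empty).
#' @export
select_pcs <- function(pc, min_pct = 10, n_blocks = 8) {
  if (is.numeric(pc)) pc <- list(percent_var = pc)
  if (n_blocks < 4) {
    abort("need at least 4 blocks to select any components",
          class = "fieldkrige_domain_error")
  }
  sel <- which(pc$percent_var >= min_pct)
  head(sel, n_blocks - 3)
}

#' Per-property contributions to a principal component
#'
#' With orthonormal loadings the squared loadings of a component sum to one,
#' so `100 * loading^2` decomposes each component's variance share across
#' properties.
#'
#' @param pc A `pc_model`.
#' @param k Component index.
#' @return A tibble `property`, `contribution` (percent, sums to 100).
#' @export
property_contributions <- function(pc, k) {
  if (k < 1 || k > ncol(pc$loadings)) {
    abort("component index out of range", class = "fieldkrige_domain_error")
  }
  tibble(property = rownames(pc$loadings),
         component = k,
         contribution = unname(100 * pc$loadings[, k]^2))
}

#' Krige selected principal component scores across the field
#'
#' Each selected component's scores (observed at the soil-sampled plots)
#' are treated like any other spatial variable: empirical variogram, all
#' six families fitted, minimum-SSE model selected, then ordinary kriging
#' to every plot of the layout.
#'
#' @param pc A `pc_model`.
#' @param layout A validated layout.
#' @param components Component indices (default `select_pcs(pc)` with
#'   `n_blocks` taken from the layout).
#' @param ... Passed to [empirical_variogram()].
#' @return A tibble `plot_id`, then one `PC<k>_krig` column per component;
#'   chosen variogram models in attribute `models`.
#' @export
krige_pc_scores <- function(pc, layout, components = NULL, ...) {
  layout <- validate_layout(layout)
  components <- components %||%
    select_pcs(pc, n_blocks = nlevels(layout$block))
  if (length(components) == 0) {
    abort("no components selected to krige",
          class = "fieldkrige_selection_error")
  }
  out <- tibble(plot_id = layout$plot_id)
  models <- list()
  for (k in components) {
    cn <- paste0("PC", k)
    kf <- krige_field(layout, pc$scores[[cn]], pc$scores$plot_id, ...)
    out[[paste0(cn, "_krig")]] <- kf$predicted
    models[[cn]] <- attr(kf, "model")
  }
  attr(out, "models") <- models
  out
}

#' Scree / contribution plots for a PC model
#'
#' @param object A `pc_model`.
#' @param type `"scree"` (percent variance per component) or
#'   `"contributions"` (per-property squared loadings for `components`).
#' @param components Components shown for `type = "contributions"`.
#' @param ... Unused.
#' @export
autoplot.pc_model <- function(object, type = c("scree", "contributions"),
                              components = 1:3, ...) {
  type <- match.arg(type)
  if (type == "scree") {
    d <- tidy(object)
    d <- d[seq_len(min(10, nrow(d))), ]
    ggplot2::ggplot(d, ggplot2::aes(x = .data$component,
                                    y = .data$percent_var)) +
      ggplot2::geom_col() +
      ggplot2::geom_hline(yintercept = 10, linetype = "dashed") +
      ggplot2::labs(x = "component", y = "% variance explained")
  } else {
    d <- bind_rows(lapply(components, function(k)
      property_contributions(object, k)))
    ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$component),
                                    y = .data$contribution,
                                    fill = .data$property)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "component", y = "contribution (%)")
  }
}
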