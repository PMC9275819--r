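#' Ordinary kriging
#'
#' Interpolates a spatial variable at target locations as the weighted
#' average of all observations, \eqn{\hat z_0 = \sum_i \lambda_i z_i} with
#' \eqn{\sum_i \lambda_i = 1} (the unbiasedness constraint of ordinary
#' kriging). Weights come from the variogram: per target the augmented
#' system
#' \deqn{\begin{pmatrix}\Gamma & 1\\ 1^\top & 0\end{pmatrix}
#'       \begin{pmatrix}\lambda\\ \mu\end{pmatrix} =
#'       \begin{pmatrix}\gamma_0\\ 1\end{pmatrix}}
#' is solved, where \eqn{\Gamma_{ij} = \gamma(\|x_i - x_j\|)} between
#' observations and \eqn{\gamma_0} holds target-to-observation
#' semivariances. The kriging variance is
#' \eqn{\lambda^\top \gamma_0 + \mu}. All observations are used for every
#' target (global neighborhood — appropriate for fields of a few hundred
#' plots). Because \eqn{\gamma(0) = 0}, kriging interpolates exactly at
#' observed locations even with a positive nugget.
#'
#' @param model A [variogram_model()].
#' @param values Observed values.
#' @param coords Observation coordinates (two columns, plot units).
#' @param targets Target coordinates (two columns). Default: the
#'   observation locations themselves.
#' @return A `kriging_result` tibble with one row per target: `row`, `col`,
#'   `predicted`, `krig_var`; the weight matrix (targets x observations) is
#'   attached as attribute `weights`.
#' @export
krige <- function(model, values, coords, targets = coords) {
  stopifnot(inherits(model, "variogram_model"))
  coords <- as.matrix(coords)
  targets <- as.matrix(targets)
  ok <- is.finite(values) & complete.cases(coords)
  values <- values[ok]
  coords <- coords[ok, , drop = FALSE]
  n <- length(values)
  if (n < 2) {
    abort("ordinary kriging needs at least 2 observations",
          class = "fieldkrige_domain_error")
  }
  dobs <- as.matrix(dist(coords))
  if (model$nugget <= 0) {
    dup <- which(dobs == 0 & upper.tri(dobs), arr.ind = TRUE)
    if (nrow(dup) > 0) {
      abort(paste0(
        "duplicate observation coordinates with a zero-nugget model make ",
        "the kriging system singular (observation rows ",
        paste(unique(c(dup)), collapse = ", "), ")"),
        class = "fieldkrige_singular_error")
    }
  }
  Gm <- matrix(model_semivariance(model, as.vector(dobs)), n, n)
  # distinct samples at identical coordinates differ by the nugget
  # (gamma(0+)), only the self-pair diagonal is exactly 0
  Gm[dobs == 0] <- model$nugget
  diag(Gm) <- 0
  A <- rbind(cbind(Gm, 1), c(rep(1, n), 0))
  Ai <- tryCatch(solve(A), error = function(e) {
    abort(paste0("kriging system is singular: ", conditionMessage(e)),
          class = "fieldkrige_singular_error")
  })
  # target-to-observation distances, vectorized over targets
  dt <- sqrt(outer(targets[, 1], coords[, 1], "-")^2 +
             outer(targets[, 2], coords[, 2], "-")^2)
  g0 <- matrix(model_semivariance(model, as.vector(dt)), nrow(targets), n)
  G0 <- cbind(g0, 1)  # (targets) x (n+1)
  sol <- G0 %*% t(Ai)                            # rows: (lambda, mu)
  lambda <- sol[, seq_len(n), drop = FALSE]
  mu <- sol[, n + 1]
  pred <- as.numeric(lambda %*% values)
  kv <- rowSums(lambda * G0[, seq_len(n), drop = FALSE]) + mu
  out <- tibble(row = targets[, 1], col = targets[, 2],
                predicted = pred, krig_var = kv)
  structure(out, class = c("kriging_result", class(tibble())),
            weights = lambda, model = model)
}

#' Leave-one-out cross-validation of kriging predictions
#'
#' Each observation is predicted in turn from all the others; the
#' standardized error \eqn{e_i = (\hat z_{-i} - z_i)/\sqrt{\sigma^2_{K,i}}}
#' should resemble a standard normal draw when the variogram model is
#' well specified — a calibration check of both the interpolation and its
#' uncertainty.
#'
#' @inheritParams krige
#' @param refit If `TRUE` the variogram is refitted on each leave-one-out
#'   subset (`model` is then taken as the family to refit); default `FALSE`
#'   holds the supplied model fixed across folds.
#' @param ... Passed to [empirical_variogram()] when `refit = TRUE`.
#' @return A tibble with one row per observation: `observed`, `predicted`,
#'   `krig_var`, `error` (predicted - observed), `std_error`.
#' @export
krige_loocv <- function(model, values, coords, refit = FALSE, ...) {
  coords <- as.matrix(coords)
  ok <- is.finite(values) & complete.cases(coords)
  values <- values[ok]
  coords <- coords[ok, , drop = FALSE]
  n <- length(values)
  if (n < 3) {
    abort("leave-one-out cross-validation needs at least 3 observations",
          class = "fieldkrige_domain_error")
  }
  res <- map(seq_len(n), function(i) {
    m_i <- model
    if (refit) {
      ev <- empirical_variogram(values[-i], coords[-i, , drop = FALSE], ...)
      m_i <- select_best_model(fit_all_variograms(ev))
    }
    k <- krige(m_i, values[-i], coords[-i, , drop = FALSE],
               targets = coords[i, , drop = FALSE])
    c(pred = k$predicted[1], kv = k$krig_var[1])
  })
  pred <- map_dbl(res, "pred")
  kv <- pmax(map_dbl(res, "kv"), 0)
  tibble(
    observed = values, predicted = pred, krig_var = kv,
    error = pred - values,
    std_error = (pred - values) / sqrt(kv)
  )
}

#' Krige a plot-level variable across a whole field layout
#'
#' Convenience wrapper: fits all variogram families to the observed plots,
#' selects the minimum-SSE model, and kriges to every plot of the layout.
#'
#' @param layout A validated layout (see [validate_layout()]).
#' @param values Named numeric vector or tibble column of observed values,
#'   aligned with `obs_plots`.
#' @param obs_plots `plot_id`s at which `values` were observed.
#' @param model Optional [variogram_model()]; default fits and selects one.
#' @param ... Passed to [empirical_variogram()].
#' @return A tibble with one row per layout plot: `plot_id`, `observed`
#'   (NA where unsampled), `predicted`, `krig_var`, plus the chosen model in
#'   attribute `model`.
#' @export
krige_field <- function(layout, values, obs_plots, model = NULL, ...) {
  layout <- validate_layout(layout)
  idx <- match(obs_plots, layout$plot_id)
  if (anyNA(idx)) {
    abort("obs_plots contains plot_ids absent from the layout",
          class = "fieldkrige_referential_error")
  }
  coords <- cbind(layout$row[idx], layout$col[idx])
  keep <- is.finite(values)
  if (is.null(model)) {
    ev <- empirical_variogram(values[keep], coords[keep, , drop = FALSE], ...)
    model <- select_best_model(fit_all_variograms(ev))
  }
  k <- krige(model, values[keep], coords[keep, , drop = FALSE],
             targets = cbind(layout$row, layout$col))
  obs <- rep(NA_real_, nrow(layout))
  obs[idx[keep]] <- values[keep]
  out <- tibble(plot_id = layout$plot_id, row = layout$row,
                col = layout$col, observed = obs,
                predicted = k$predicted, krig_var = k$krig_var)
  attr(out, "model") <- model
  out
}

#' @export
autoplot.kriging_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$predicted)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "magenta", mid = "white",
                                  high = "darkgreen",
                                  midpoint = mean(object$predicted)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", fill = "kriged")
}
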