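#' Variogram model families
#'
#' The six semivariance families available for fitting and kriging, in their
#' canonical order (also the tie-break order of [select_best_model()]).
#' @export
variogram_families <- c("nugget_only", "exponential", "spherical",
                        "gaussian", "matern", "stein_matern")

#' Construct a variogram model
#'
#' A variogram model is a parametric semivariance function
#' \eqn{\gamma(h)} with \eqn{\gamma(0) = 0}, a nugget (micro-scale variance,
#' the jump of \eqn{\gamma} at the origin), a partial sill (the spatially
#' structured variance, so sill = nugget + partial sill), a range parameter
#' (in plot units), and for the Matern-type families a smoothness `kappa`.
#' The exponential and Gaussian families approach the sill asymptotically;
#' their *effective* ranges (distance at which \eqn{\gamma} reaches 95% of
#' the structured variance) are `3 * range` and `sqrt(3) * range`
#' respectively, reported by [tidy()] as `effective_range`. The spherical
#' family reaches the sill exactly at `h = range`.
#'
#' @param family One of [variogram_families].
#' @param nugget,psill Nugget and partial sill, both `>= 0`, in squared value
#'   units.
#' @param range Range parameter `> 0` in plot units (ignored for
#'   `nugget_only`).
#' @param kappa Smoothness for `matern` / `stein_matern` (default 0.5, at
#'   which both reduce to an exponential shape).
#' @param sse Optional fit criterion carried by [fit_variogram()].
#' @return An object of class `variogram_model`.
#' @export
variogram_model <- function(family, nugget, psill, range = NA_real_,
                            kappa = 0.5, sse = NA_real_) {
  family <- match.arg(family, variogram_families)
  if (!is.finite(nugget) || nugget < 0) {
    abort("nugget must be finite and >= 0", class = "fieldkrige_domain_error")
  }
  if (!is.finite(psill) || psill < 0) {
    abort("partial sill must be finite and >= 0",
          class = "fieldkrige_domain_error")
  }
  if (family != "nugget_only" && (!is.finite(range) || range <= 0)) {
    abort("range must be finite and > 0", class = "fieldkrige_domain_error")
  }
  if (family %in% c("matern", "stein_matern") &&
      (!is.finite(kappa) || kappa <= 0)) {
    abort("kappa must be finite and > 0", class = "fieldkrige_domain_error")
  }
  structure(
    list(family = family, nugget = nugget, psill = psill,
         range = range, kappa = kappa, sse = sse),
    class = "variogram_model"
  )
}

#' @export
print.variogram_model <- function(x, ...) {
  cat("<variogram_model> ", x$family, "\n", sep = "")
  cat("  nugget: ", format(x$nugget), "  partial sill: ", format(x$psill),
      if (x$family != "nugget_only") paste0("  range: ", format(x$range)),
      if (x$family %in% c("matern", "stein_matern"))
        paste0("  kappa: ", format(x$kappa)),
      "\n", sep = "")
  if (is.finite(x$sse)) cat("  sse: ", format(x$sse), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.variogram_model <- function(x, ...) {
  eff <- switch(x$family,
    exponential = 3 * x$range,
    gaussian = sqrt(3) * x$range,
    x$range
  )
  tibble(
    family = x$family, nugget = x$nugget, psill = x$psill,
    sill = x$nugget + x$psill, range = x$range,
    effective_range = eff, kappa = x$kappa, sse = x$sse
  )
}

# Matern correlation term (2^(1-k)/Gamma(k)) x^k K_k(x); 1 at x = 0.
matern_term <- function(x, kappa) {
  out <- numeric(length(x))
  pos <- x > 1e-12
  xp <- x[pos]
  lt <- (1 - kappa) * log(2) - lgamma(kappa) + kappa * log(xp) +
    log(besselK(xp, kappa, expon.scaled = TRUE)) - xp
  out[pos] <- exp(lt)
  out[!pos] <- 1
  # guard against Bessel under/overflow at extreme arguments
  out[!is.finite(out)] <- 0
  pmin(pmax(out, 0), 1)
}

#' Evaluate a variogram model's semivariance
#'
#' Closed forms, with \eqn{\gamma(0) = 0} for every family:
#' \describe{
#'   \item{nugget_only}{\eqn{n \cdot 1[h > 0]}}
#'   \item{exponential}{\eqn{n + s (1 - e^{-h/r})}}
#'   \item{spherical}{\eqn{n + s (1.5 h/r - 0.5 (h/r)^3)} for
#'     \eqn{h \le r}, else \eqn{n + s}}
#'   \item{gaussian}{\eqn{n + s (1 - e^{-(h/r)^2})}}
#'   \item{matern}{\eqn{n + s (1 - \frac{2^{1-\kappa}}{\Gamma(\kappa)}
#'     (h/r)^\kappa K_\kappa(h/r))}}
#'   \item{stein_matern}{the Matern form with argument
#'     \eqn{h\sqrt{2\kappa}/r} (Stein's parameterization, in which the range
#'     is comparable across smoothness values)}
#' }
#'
#' @param model A [variogram_model()].
#' @param h Nonnegative distances (plot units).
#' @return Semivariances, same length as `h`.
#' @export
model_semivariance <- function(model, h) {
  stopifnot(inherits(model, "variogram_model"))
  if (any(h < 0)) {
    abort("distances must be >= 0", class = "fieldkrige_domain_error")
  }
  n <- model$nugget; s <- model$psill; r <- model$range; k <- model$kappa
  g <- switch(model$family,
    nugget_only = rep(n, length(h)),
    exponential = n + s * (1 - exp(-h / r)),
    spherical = {
      hr <- pmin(h / r, 1)
      n + s * (1.5 * hr - 0.5 * hr^3)
    },
    gaussian = n + s * (1 - exp(-(h / r)^2)),
    matern = n + s * (1 - matern_term(h / r, k)),
    stein_matern = n + s * (1 - matern_term(h * sqrt(2 * k) / r, k))
  )
  g[h == 0] <- 0
  g
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Bins all pairs of observations by separation distance and estimates the
#' semivariance per bin as
#' \eqn{\hat\gamma(h) = \frac{1}{2 N_h} \sum_{(i,j) \in h} (z_i - z_j)^2}.
#' Bin `j` collects pairs with distance in `((j-1) w, j w]` where
#' `w = cutoff / n_lags`; the reported lag distance is the mean pair
#' distance in the bin. Empty bins are dropped. Zero-distance pairs
#' (co-located samples) are excluded.
#'
#' @param values Numeric observations (typically design residuals).
#' @param coords Two-column matrix or data frame of coordinates (plot units).
#' @param n_lags Number of distance bins (default 15).
#' @param cutoff Maximum pair distance considered; default one third of the
#'   maximum inter-plot distance.
#' @return An `empirical_variogram` tibble with columns `lag` (mean pair
#'   distance), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(values, coords, n_lags = 15, cutoff = NULL) {
  coords <- as.matrix(coords)
  ok <- is.finite(values) & complete.cases(coords)
  values <- values[ok]
  coords <- coords[ok, , drop = FALSE]
  if (length(values) < 2) {
    abort("need at least 2 observations", class = "fieldkrige_domain_error")
  }
  dmat <- as.matrix(dist(coords))
  cutoff <- cutoff %||% (max(dmat) / 3)
  if (!is.finite(cutoff) || cutoff <= 0) {
    abort("cutoff must be > 0", class = "fieldkrige_domain_error")
  }
  iu <- which(upper.tri(dmat), arr.ind = TRUE)
  d <- dmat[iu]
  keep <- d > 0 & d <= cutoff
  if (!any(keep)) {
    abort("all observation pairs are beyond the cutoff distance",
          class = "fieldkrige_domain_error")
  }
  d <- d[keep]
  sqdiff <- (values[iu[keep, 1]] - values[iu[keep, 2]])^2
  width <- cutoff / n_lags
  bin <- pmin(ceiling(d / width), n_lags)
  lag <- as.numeric(tapply(d, bin, mean))
  gamma <- as.numeric(tapply(sqdiff, bin, mean)) / 2
  n_pairs <- as.integer(tapply(d, bin, length))
  out <- tibble(lag = lag, gamma = gamma, n_pairs = n_pairs)
  out <- out[order(out$lag), ]
  structure(out, class = c("empirical_variogram", class(tibble())),
            cutoff = cutoff, n_lags = n_lags)
}

# objective pieces shared by all parametric fits
vgm_wls_weights <- function(ev, weights = c("npairs_h2", "npairs", "uniform")) {
  weights <- match.arg(weights)
  switch(weights,
    npairs_h2 = ev$n_pairs / ev$lag^2,
    npairs = as.numeric(ev$n_pairs),
    uniform = rep(1, nrow(ev))
  )
}

#' Fit one variogram family to an empirical variogram
#'
#' Weighted least squares over (nugget, partial sill, range), box-constrained
#' nonnegative, minimizing \eqn{\sum_h w_h (\hat\gamma_h - \gamma(h))^2}.
#' The default weights are \eqn{N_h / h^2} (more pairs and shorter lags count
#' more). Several starting values are tried — range in
#' `cutoff * c(1/10, 1/3, 1)` with the observed variance split evenly between
#' nugget and partial sill — and the best converged start is kept. For the
#' Matern-type families `kappa` is profiled over a fixed grid (a full
#' continuous optimization of the smoothness is ill-conditioned).
#'
#' The reported `sse` is the *unweighted* \eqn{\sum_h (\hat\gamma_h -
#' \gamma(h))^2}, so fits are comparable across families and with published
#' per-family error tables.
#'
#' @param ev An [empirical_variogram()].
#' @param family One of [variogram_families].
#' @param weights Weighting scheme: `"npairs_h2"` (default), `"npairs"`, or
#'   `"uniform"`.
#' @param kappa_grid Smoothness values profiled for the Matern families.
#' @return A [variogram_model()] with `sse` filled in.
#' @export
fit_variogram <- function(ev, family, weights = "npairs_h2",
                          kappa_grid = c(0.3, 0.5, 1, 2, 5)) {
  family <- match.arg(family, variogram_families)
  stopifnot(inherits(ev, "empirical_variogram"))
  w <- vgm_wls_weights(ev, weights)
  if (family == "nugget_only") {
    if (nrow(ev) < 1) {
      abort("need at least 1 lag", class = "fieldkrige_fit_error")
    }
    nug <- sum(w * ev$gamma) / sum(w)
    m <- variogram_model("nugget_only", nugget = nug, psill = 0)
    m$sse <- sum((ev$gamma - model_semivariance(m, ev$lag))^2)
    return(m)
  }
  if (nrow(ev) < 3) {
    abort("need at least 3 lags to fit a 3-parameter model",
          class = "fieldkrige_fit_error")
  }
  cutoff <- attr(ev, "cutoff") %||% max(ev$lag)
  sill0 <- max(mean(ev$gamma), max(ev$gamma) / 2, 1e-10)
  starts <- expand.grid(range = cutoff * c(0.1, 1 / 3, 1),
                        nug_frac = 0.5)
  kappas <- if (family %in% c("matern", "stein_matern")) kappa_grid else NA
  obj <- function(par, kappa) {
    m <- list(family = family, nugget = par[1], psill = par[2],
              range = par[3], kappa = kappa)
    class(m) <- "variogram_model"
    sum(w * (ev$gamma - model_semivariance(m, ev$lag))^2)
  }
  best <- NULL
  for (kappa in kappas) {
    for (i in seq_len(nrow(starts))) {
      p0 <- c(sill0 * starts$nug_frac[i], sill0 * (1 - starts$nug_frac[i]),
              starts$range[i])
      fit <- tryCatch(
        optim(p0, obj, kappa = kappa, method = "L-BFGS-B",
              lower = c(0, 0, cutoff * 1e-4),
              upper = c(Inf, Inf, cutoff * 100),
              control = list(factr = 1e4, maxit = 500)),
        error = function(e) NULL
      )
      if (is.null(fit) || any(!is.finite(fit$par))) next
      fit$par <- pmax(fit$par, c(0, 0, cutoff * 1e-4))
      if (is.null(best) || fit$value < best$value) {
        best <- fit
        best$kappa <- kappa
      }
    }
  }
  if (is.null(best)) {
    abort(paste0("variogram fit failed for family '", family,
                 "' from every starting value"),
          class = "fieldkrige_fit_error")
  }
  m <- variogram_model(family, nugget = best$par[1], psill = best$par[2],
                       range = best$par[3],
                       kappa = if (is.na(best$kappa)) 0.5 else best$kappa)
  m$sse <- sum((ev$gamma - model_semivariance(m, ev$lag))^2)
  m
}

#' Fit all variogram families to an empirical variogram
#'
#' @param ev An [empirical_variogram()].
#' @param families Families to fit (default all six).
#' @inheritParams fit_variogram
#' @return A named list of [variogram_model()] fits; families whose fit
#'   failed are dropped with a warning.
#' @export
fit_all_variograms <- function(ev, families = variogram_families,
                               weights = "npairs_h2") {
  fits <- lapply(families, function(f) {
    tryCatch(fit_variogram(ev, f, weights = weights),
             error = function(e) {
               warn(paste0("variogram family '", f, "' failed to fit: ",
                           conditionMessage(e)))
               NULL
             })
  })
  names(fits) <- families
  compact(fits)
}

#' Select the best-fitting variogram model
#'
#' Picks the fit with the minimal (unweighted) sum-of-squared errors.
#' All families have the same three free parameters, so no complexity
#' penalty is applied. Exact ties are broken by the canonical family order
#' `nugget_only < exponential < spherical < gaussian < matern <
#' stein_matern`.
#'
#' @param fits A list of [variogram_model()] objects (e.g. from
#'   [fit_all_variograms()]).
#' @return The selected [variogram_model()].
#' @export
select_best_model <- function(fits) {
  fits <- compact(fits)
  if (length(fits) == 0) {
    abort("no successful variogram fits to select from",
          class = "fieldkrige_selection_error")
  }
  sses <- map_dbl(fits, "sse")
  fam_rank <- map_dbl(fits, ~ match(.x$family, variogram_families))
  ord <- order(sses, fam_rank)
  fits[[ord[1]]]
}

#' @export
autoplot.empirical_variogram <- function(object, model = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$lag, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::scale_size_area(name = "pairs") +
    ggplot2::labs(x = "lag distance (plot units)",
                  y = "semivariance") +
    ggplot2::expand_limits(y = 0)
  if (!is.null(model)) {
    hh <- seq(0, max(object$lag), length.out = 200)
    line <- tibble(lag = hh, gamma = model_semivariance(model, hh))
    p <- p + ggplot2::geom_line(data = line, linewidth = 0.8,
                                colour = "#2166ac") +
      ggplot2::ggtitle(paste0(model$family,
                              " (nugget ", signif(model$nugget, 3),
                              ", psill ", signif(model$psill, 3),
                              ", range ", signif(model$range, 3), ")"))
  }
  p
}
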