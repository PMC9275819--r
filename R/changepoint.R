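#' Fit a hinge (flat-then-linear) change-point model
#'
#' Models a phenotype as constant below an abundance threshold and linear
#' above it, continuous at the threshold:
#' \deqn{y = \mu + \beta (x - e)_+ + \varepsilon.}
#' The threshold `e` is profiled over the grid of observed distinct `x`
#' values (excluding the 3 smallest and 3 largest so both segments remain
#' estimable); at each candidate the two remaining parameters are solved by
#' least squares and the candidate with minimal residual sum of squares
#' wins (ties go to the smallest threshold). Because the threshold makes
#' the usual F asymptotics invalid, the p-value for \eqn{\beta} comes from
#' a permutation test: `x` is permuted against `y` and the hinge model
#' re-profiled each time, comparing the achieved reduction in RSS over the
#' flat model.
#'
#' @param x Abundance values.
#' @param y Phenotype values (same length).
#' @param n_perm Number of permutations for the p-value (default 999; use
#'   `0` to skip the test).
#' @param seed Integer seed for the permutation stream.
#' @return A `hinge_fit` list: `threshold`, `mu` (pre-threshold mean),
#'   `beta` (post-threshold slope), `rss`, `rss_flat`, `p_value`, `n`.
#' @export
fit_hinge <- function(x, y, n_perm = 999, seed = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) {
    abort("hinge fit needs at least 10 observations",
          class = "fieldkrige_domain_error")
  }
  ux <- sort(unique(x))
  if (length(ux) < 5) {
    abort("hinge fit needs at least 5 distinct abundance values",
          class = "fieldkrige_domain_error")
  }
  cand <- if (length(ux) >= 7) ux[4:(length(ux) - 3)]
          else ux[ceiling(length(ux) / 2)]
  prof <- hinge_profile(x, cand)
  stat <- hinge_stats(prof, y)
  best <- which(stat$rss <= min(stat$rss) + 1e-12)[1]  # smallest e on ties
  rss_flat <- sum((y - mean(y))^2)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(as.integer(seed))
    obs_gain <- rss_flat - stat$rss[best]
    # batch the permutations: columns of Yp are permuted responses, so one
    # crossprod profiles the hinge for every permutation at once
    Yp <- vapply(seq_len(n_perm), function(b) y[sample.int(n)],
                 numeric(n))
    Shy <- crossprod(prof$Hc, Yp)                  # candidates x perms
    gains <- apply(Shy^2 / prof$shh, 2, max)       # explained SS, max over e
    p <- (1 + sum(gains >= obs_gain - 1e-12)) / (1 + n_perm)
  }
  structure(
    list(threshold = cand[best], mu = stat$mu[best], beta = stat$beta[best],
         rss = stat$rss[best], rss_flat = rss_flat, p_value = p, n = n,
         candidates = cand),
    class = "hinge_fit"
  )
}

# precompute, per candidate threshold, the hinge basis and its sufficient
# statistics so repeated (permutation) solves are two dot products each
hinge_profile <- function(x, cand) {
  n <- length(x)
  H <- outer(x, cand, function(xx, ee) pmax(xx - ee, 0))
  hbar <- colMeans(H)
  Hc <- sweep(H, 2, hbar)
  shh <- colSums(Hc^2)
  list(n = n, H = H, Hc = Hc, hbar = hbar, shh = pmax(shh, 1e-300))
}

hinge_stats <- function(prof, y) {
  ybar <- mean(y)
  syy <- sum((y - ybar)^2)
  shy <- as.numeric(crossprod(prof$Hc, y))
  beta <- shy / prof$shh
  rss <- syy - beta * shy
  list(rss = rss, beta = beta, mu = ybar - beta * prof$hbar)
}

#' @export
print.hinge_fit <- function(x, ...) {
  cat("<hinge_fit> n = ", x$n, "\n", sep = "")
  cat(sprintf("  threshold %.4g, pre-mean %.4g, slope %.4g\n",
              x$threshold, x$mu, x$beta))
  cat(sprintf("  RSS %.4g (flat %.4g)", x$rss, x$rss_flat))
  if (is.finite(x$p_value)) cat(sprintf(", permutation p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}

#' @export
tidy.hinge_fit <- function(x, ...) {
  tibble(threshold = x$threshold, mu = x$mu, beta = x$beta,
         rss = x$rss, rss_flat = x$rss_flat, p_value = x$p_value, n = x$n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values \eqn{\tilde p_{(i)} = \min_{j \ge i}
#' (m / j) p_{(j)}}, capped at 1, with monotonicity enforced.
#'
#' @param p Vector of p-values in `[0, 1]` (NA passed through).
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "fieldkrige_domain_error")
  }
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  o <- order(p[ok], decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[ok][o]))[ro]
  out[ok] <- adj
  out
}

#' Screen OTUs for change-point associations with a phenotype
#'
#' Fits [fit_hinge()] of the phenotype on each OTU's abundance, both for
#' the observed and the adjusted counts of an [pcr_adjust_counts()] result,
#' within an optional sample subset (e.g. a single treatment and
#' compartment, where the biology predicts threshold effects). Reports
#' per-OTU fits with BH-FDR adjusted p-values and the before/after/
#' intersection counts of significant OTUs.
#'
#' @param adj An `otu_adjusted` long tibble from [pcr_adjust_counts()], or
#'   any tibble with columns `sample_id`, `otu`, `observed`, `adjusted`.
#' @param phenotype Named numeric vector of phenotype values indexed by
#'   `plot_id`, or a tibble with `plot_id` and one trait column.
#' @param trait Trait column name when `phenotype` is a tibble.
#' @param subset Optional logical-expression string or logical vector
#'   selecting samples of `adj` (e.g. `compartment == "soil"` rows already
#'   filtered by the caller); default uses all rows.
#' @param alpha Significance level applied to the FDR-adjusted p-values.
#' @param n_perm,seed Passed to [fit_hinge()].
#' @return An `otu_screen` tibble with one row per OTU and per version
#'   (`observed` / `adjusted`): `otu`, `version`, `threshold`, `beta`,
#'   `p_value`, `p_adjusted`, `significant`, `error`; summary counts in
#'   attribute `summary` (`n_sig_observed`, `n_sig_adjusted`,
#'   `n_intersection`).
#' @export
screen_otus <- function(adj, phenotype, trait = NULL, subset = NULL,
                        alpha = 0.05, n_perm = 999, seed = 1) {
  adj <- as_tibble(adj)
  if (!is.null(subset)) adj <- adj[subset, ]
  if (is.data.frame(phenotype)) {
    trait <- trait %||% setdiff(names(phenotype), "plot_id")[1]
    phen <- setNames(phenotype[[trait]], phenotype$plot_id)
  } else {
    phen <- phenotype
  }
  adj$y <- unname(phen[adj$plot_id])
  rows <- list()
  for (version in c("observed", "adjusted")) {
    per_otu <- split(adj, adj$otu)
    for (otu in names(per_otu)) {
      d <- per_otu[[otu]]
      fit <- tryCatch(
        fit_hinge(d[[version]], d$y, n_perm = n_perm,
                  seed = stage_seed(seed, match(version, c("observed",
                                                           "adjusted")))),
        error = function(e) e
      )
      rows[[paste(version, otu)]] <- if (inherits(fit, "error")) {
        tibble(otu = otu, version = version, threshold = NA_real_,
               beta = NA_real_, p_value = NA_real_,
               error = conditionMessage(fit))
      } else {
        tibble(otu = otu, version = version, threshold = fit$threshold,
               beta = fit$beta, p_value = fit$p_value, error = NA_character_)
      }
    }
  }
  out <- bind_rows(rows)
  out <- out %>%
    group_by(.data$version) %>%
    mutate(p_adjusted = fdr_bh(.data$p_value),
           significant = !is.na(.data$p_adjusted) &
             .data$p_adjusted < alpha) %>%
    ungroup()
  sig_obs <- out$otu[out$version == "observed" & out$significant]
  sig_adj <- out$otu[out$version == "adjusted" & out$significant]
  structure(out, class = c("otu_screen", class(tibble())),
            summary = tibble(
              n_sig_observed = length(sig_obs),
              n_sig_adjusted = length(sig_adj),
              n_intersection = length(intersect(sig_obs, sig_adj))
            ))
}

#' @export
glance.otu_screen <- function(x, ...) {
  attr(x, "summary")
}

#' Hinge-fit display for one OTU / phenotype pair
#'
#' @param object A `hinge_fit`.
#' @param x,y The data the model was fitted to.
#' @param ... Unused.
#' @export
autoplot.hinge_fit <- function(object, x, y, ...) {
  d <- tibble(x = x, y = y)
  e <- object$threshold
  seg <- tibble(
    x = c(min(x, na.rm = TRUE), e, e, max(x, na.rm = TRUE)),
    y = c(object$mu, object$mu, object$mu,
          object$mu + object$beta * (max(x, na.rm = TRUE) - e)),
    part = c("pre", "pre", "post", "post")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = e, linetype = "dashed") +
    ggplot2::geom_line(data = seg,
                       ggplot2::aes(group = .data$part,
                                    colour = .data$part),
                       linewidth = 1) +
    ggplot2::scale_colour_manual(values = c(pre = "#b2182b",
                                            post = "#2166ac"),
                                 guide = "none") +
    ggplot2::labs(x = "abundance", y = "phenotype")
}
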