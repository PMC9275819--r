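#' Canberra distance matrix
#'
#' \eqn{d(x, y) = \sum_k |x_k - y_k| / (x_k + y_k)} over the features where
#' \eqn{x_k + y_k > 0}; 0/0 terms are skipped (not counted and not
#' rescaled — note some implementations divide by the number of nonzero
#' terms instead). The heavy weighting of rare features makes this the
#' customary beta-diversity transform for sparse count tables.
#'
#' @param m Sample x feature matrix (or wide OTU tibble) with nonnegative
#'   entries.
#' @return A symmetric `dist`-convertible matrix with zero diagonal and
#'   sample rownames.
#' @export
canberra_distance <- function(m) {
  if (is.data.frame(m) && all(otu_meta_cols %in% names(m))) {
    m <- otu_counts(m)
  }
  m <- as.matrix(m)
  if (any(m < 0, na.rm = TRUE)) {
    abort("Canberra distance requires nonnegative entries",
          class = "fieldkrige_domain_error")
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    rest <- m[(i + 1):n, , drop = FALSE]
    num <- abs(sweep(rest, 2, xi, "-"))
    den <- sweep(rest, 2, xi, "+")
    term <- num / den
    term[den == 0] <- 0
    dd <- rowSums(term)
    d[i, (i + 1):n] <- dd
    d[(i + 1):n, i] <- dd
  }
  d
}

# principal-coordinate embedding of a distance matrix; drops negative axes
pcoa_embed <- function(d, warn_negative = TRUE) {
  d <- as.matrix(d)
  n <- nrow(d)
  G <- -0.5 * d^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))   # sequential sweeps double-center exactly
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  neg_inertia <- sum(e$values[e$values < -tol])
  if (warn_negative && neg_inertia < -tol) {
    warn(sprintf(
      "dropping principal-coordinate axes with negative eigenvalues (summed inertia %.4g)",
      neg_inertia))
  }
  Y <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(Y) <- rownames(d)
  Y
}

design_model_matrix <- function(layout, terms_chr, data = NULL) {
  dat <- data %||% as.data.frame(layout)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fml <- as.formula(paste("~", paste(terms_chr, collapse = " + ")))
  model.matrix(fml, data = dat)
}

hat_matrix <- function(X) {
  qx <- qr(X)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Constrained permutation ANOVA on a distance matrix
#'
#' Distance-based redundancy analysis: the distance matrix is embedded by
#' principal coordinates (axes with negative eigenvalues dropped with a
#' warning), responses are residualized on the conditioning terms, and a
#' pseudo-F for the tested term is computed from constrained versus
#' residual sums of squares. Significance comes from free permutation of
#' the reduced-model residuals (Freedman-Lane): under the null the
#' residual rows are exchangeable after the conditioned effects are removed.
#' A within-block restricted scheme is available for designs where plots
#' are only exchangeable within blocks.
#'
#' @param d Distance matrix (samples x samples), rows aligned with `data`.
#' @param data Data frame holding the model variables, one row per sample
#'   (e.g. the layout joined to per-sample covariates).
#' @param test_term Model term to test (character, e.g. `"prop_krig"` or
#'   `"prop_krig:compartment"`).
#' @param condition_terms Character vector of terms conditioned on
#'   (may be empty).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param strata Optional factor restricting permutations to occur within
#'   its levels.
#' @return An `assoc_result` tibble (one row): `term`, `statistic`
#'   (pseudo-F), `df`, `p_value`, `n_perm`, `conditioned`.
#' @export
constrained_permanova <- function(d, data, test_term,
                                  condition_terms = character(),
                                  n_perm = 999, seed = 1, strata = NULL) {
  Y <- pcoa_embed(d)
  n <- nrow(Y)
  stopifnot(nrow(data) == n)
  Xc <- design_model_matrix(NULL, c("1", condition_terms), data = data)
  Xf <- design_model_matrix(NULL, c("1", condition_terms, test_term),
                            data = data)
  rank_c <- qr(Xc)$rank
  rank_f <- qr(Xf)$rank
  q <- rank_f - rank_c
  if (q < 1) {
    abort("test term is collinear with the conditioning terms",
          class = "fieldkrige_collinear_error")
  }
  Hc <- hat_matrix(Xc)
  Hf <- hat_matrix(Xf)
  Yr <- Y - Hc %*% Y                       # reduced-model residuals
  Ht <- Hf - Hc                            # projector onto the tested space
  Hres <- diag(n) - Hf
  df_res <- n - rank_f
  ss <- function(Yp) {
    c(sum((Ht %*% Yp)^2), sum((Hres %*% Yp)^2))
  }
  s_obs <- ss(Yr)
  f_obs <- (s_obs[1] / q) / (s_obs[2] / df_res)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- if (is.null(strata)) {
      sample.int(n)
    } else {
      p <- seq_len(n)
      for (lv in levels(factor(strata))) {
        i <- which(strata == lv)
        p[i] <- i[sample.int(length(i))]
      }
      p
    }
    s_p <- ss(Yr[perm, , drop = FALSE])
    f_p <- (s_p[1] / q) / (s_p[2] / df_res)
    if (f_p >= f_obs) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (1 + n_perm)
  structure(
    tibble(term = test_term, statistic = f_obs, df = q, p_value = p,
           n_perm = n_perm,
           conditioned = paste(condition_terms, collapse = " + ")),
    class = c("assoc_result", class(tibble()))
  )
}

#' Type-III test of a kriged soil property on a phenotype
#'
#' Fits the association mixed model
#' `y ~ treatment * genotype + prop_krig` with a block random intercept and
#' exponential spatial correlation within blocks, under sum-to-zero
#' contrasts, and reports the type-III Wald chi-squared statistic (1 df)
#' for the kriged property — the property's effect with every design term
#' held in the model. Falls back to a generalized least squares fit without
#' the spatial term (with a warning) if the mixed model does not converge.
#'
#' @param y Phenotype values, one per layout plot.
#' @param prop_krig Kriged property values, one per layout plot.
#' @param layout A validated layout.
#' @return An `assoc_result` tibble (one row): `term`, `statistic`
#'   (Wald chi-squared), `df`, `p_value`, `conditioned`.
#' @export
type3_property_test <- function(y, prop_krig, layout) {
  layout <- validate_layout(layout)
  stopifnot(length(y) == nrow(layout), length(prop_krig) == nrow(layout))
  dat <- data.frame(
    y = y, prop_krig = prop_krig, treatment = layout$treatment,
    genotype = layout$genotype, block = layout$block,
    x1 = layout$row, x2 = layout$col
  )
  dat <- dat[is.finite(dat$y) & is.finite(dat$prop_krig), ]
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit <- tryCatch(
    suppressWarnings(nlme::lme(
      y ~ treatment * genotype + prop_krig, random = ~ 1 | block,
      correlation = nlme::corExp(form = ~ x1 + x2 | block),
      data = dat, method = "REML",
      control = nlme::lmeControl(returnObject = FALSE)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warn("spatial mixed model did not converge; using gls without spatial term")
    fit <- tryCatch(
      nlme::gls(y ~ treatment * genotype + prop_krig, data = dat,
                method = "REML"),
      error = function(e) lm(y ~ treatment * genotype + prop_krig,
                             data = dat)
    )
  }
  if (inherits(fit, "lm")) {
    # least-squares fallback computed directly so a (near-)perfect fit
    # does not error: marginal SS from dropping the property column
    X <- model.matrix(fit)
    asg <- attr(X, "assign")
    j <- which(attr(terms(fit), "term.labels") == "prop_krig")
    rss_f <- sum(resid(fit)^2)
    rss_r <- sum(qr.resid(qr(X[, asg != j, drop = FALSE]), fit$model$y)^2)
    df <- sum(asg == j)
    df_res <- nrow(X) - qr(X)$rank
    stat <- ((rss_r - rss_f) / df) / max(rss_f / df_res, 1e-300)
    pv <- max(stats::pf(stat, df, df_res, lower.tail = FALSE), 1e-300)
  } else {
    a <- car::Anova(fit, type = 3)
    row <- a["prop_krig", ]
    stat <- row[["Chisq"]]; df <- row[["Df"]]; pv <- row[["Pr(>Chisq)"]]
  }
  structure(
    tibble(term = "prop_krig",
           statistic = stat, df = df, p_value = pv,
           n_perm = NA_integer_,
           conditioned = "treatment * genotype"),
    class = c("assoc_result", class(tibble()))
  )
}

#' Partial R-squared of the experimental-design terms
#'
#' For each design term, the marginal (type-II-style) sum of squares with
#' every other design term already in the model, divided by the total sum
#' of squares. Works for a univariate response (classical ANOVA
#' decomposition) and for a distance matrix (the trace-based multivariate
#' analogue on the principal-coordinate embedding). Comparing these values
#' before and after a soil-gradient adjustment measures how much design
#' resolution the adjustment recovered.
#'
#' @param response Numeric vector (one per row of `data`) or a distance
#'   matrix.
#' @param data Data frame with the design variables.
#' @param terms_chr Design terms (default treatment, genotype, and their
#'   interaction).
#' @return A tibble `term`, `partial_r2`.
#' @export
design_partial_r2 <- function(response, data,
                              terms_chr = c("treatment", "genotype",
                                            "treatment:genotype")) {
  Y <- if (is.matrix(response) && nrow(response) == ncol(response) &&
           isTRUE(all.equal(response, t(response)))) {
    pcoa_embed(response, warn_negative = FALSE)
  } else {
    matrix(as.numeric(response), ncol = 1)
  }
  stopifnot(nrow(Y) == nrow(data))
  Yc <- sweep(Y, 2, colMeans(Y))
  ss_total <- sum(Yc^2)
  # type-III style: drop only the term's sum-contrast columns from the
  # full design matrix (a span comparison would zero out main effects
  # whenever their interaction is present)
  Xf <- design_model_matrix(NULL, c("1", terms_chr), data = data)
  asg <- attr(Xf, "assign")
  Hf <- hat_matrix(Xf)
  labels <- attr(terms(as.formula(
    paste("~", paste(terms_chr, collapse = " + ")))), "term.labels")
  out <- map(terms_chr, function(tm) {
    i <- match(tm, labels)
    Xr <- Xf[, asg != i, drop = FALSE]
    ss_term <- sum(((Hf - hat_matrix(Xr)) %*% Y)^2)
    tibble(term = tm, partial_r2 = ss_term / ss_total)
  })
  bind_rows(out)
}
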