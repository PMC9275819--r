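test_that("closed-form semivariances match hand evaluation", {
  g <- variogram_model("gaussian", nugget = 0.1, psill = 1, range = 2)
  expect_equal(model_semivariance(g, 2), 0.1 + (1 - exp(-1)),
               tolerance = 1e-12)
  for (fam in variogram_families) {
    m <- variogram_model(fam, 0.3, 0.7, range = 2, kappa = 1)
    expect_identical(model_semivariance(m, 0), 0)
  }
  s <- variogram_model("spherical", 0.2, 1, range = 5)
  expect_equal(model_semivariance(s, 5), 1.2)
  expect_equal(model_semivariance(s, 9), 1.2)
  # Matern at kappa = 0.5 reduces to the exponential shape
  mm <- variogram_model("matern", 0, 1, 3, kappa = 0.5)
  me <- variogram_model("exponential", 0, 1, 3)
  h <- c(0.2, 1, 2.5, 6)
  expect_equal(model_semivariance(mm, h), model_semivariance(me, h),
               tolerance = 1e-9)
  expect_error(model_semivariance(me, -1), class = "fieldkrige_domain_error")
})

test_that("semivariance is nondecreasing in distance for random valid models", {
  set.seed(14)
  h <- seq(0, 40, length.out = 400)
  for (i in 1:30) {
    fam <- sample(variogram_families, 1)
    m <- variogram_model(fam, nugget = runif(1, 0, 2),
                         psill = runif(1, 0, 3), range = runif(1, 0.5, 10),
                         kappa = sample(c(0.3, 0.5, 1, 2, 5), 1))
    g <- model_semivariance(m, h)
    expect_true(all(diff(g) > -1e-9), info = fam)
  }
})

test_that("empirical variogram matches a brute-force pair loop", {
  # two-point case: one bin, gamma = (1/2)(1-0)^2
  ev2 <- empirical_variogram(c(0, 1), rbind(c(0, 0), c(0, 1)),
                             n_lags = 1, cutoff = 2)
  expect_equal(ev2$gamma, 0.5)
  expect_equal(ev2$n_pairs, 1L)

  ev0 <- empirical_variogram(rep(3, 10),
                             cbind(runif(10), runif(10)), n_lags = 4,
                             cutoff = 1.5)
  expect_true(all(ev0$gamma == 0))

  set.seed(6)
  coords <- cbind(runif(50, 0, 10), runif(50, 0, 10))
  z <- rnorm(50)
  n_lags <- 8; cutoff <- 5
  ev <- empirical_variogram(z, coords, n_lags = n_lags, cutoff = cutoff)
  # O(n^2) oracle
  width <- cutoff / n_lags
  acc_g <- acc_n <- acc_d <- numeric(n_lags)
  for (i in 1:49) for (j in (i + 1):50) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d > 0 && d <= cutoff) {
      b <- min(ceiling(d / width), n_lags)
      acc_g[b] <- acc_g[b] + (z[i] - z[j])^2
      acc_n[b] <- acc_n[b] + 1
      acc_d[b] <- acc_d[b] + d
    }
  }
  keep <- acc_n > 0
  expect_equal(ev$gamma, (acc_g[keep] / acc_n[keep]) / 2, tolerance = 1e-12)
  expect_equal(ev$n_pairs, as.integer(acc_n[keep]))
  expect_equal(ev$lag, acc_d[keep] / acc_n[keep], tolerance = 1e-12)
})

test_that("fitting recovers exact generating parameters and closed forms", {
  truth <- variogram_model("spherical", nugget = 0.2, psill = 1, range = 5)
  lags <- seq(0.5, 9.5, by = 1)
  ev <- make_ev(lags, model_semivariance(truth, lags),
                n_pairs = rep(40, 10), cutoff = 10)
  fit <- fit_variogram(ev, "spherical")
  expect_lt(abs(fit$nugget - 0.2), 1e-5)
  expect_lt(abs(fit$psill - 1), 1e-5)
  expect_lt(abs(fit$range - 5), 1e-4)
  expect_lt(fit$sse, 1e-9)

  # nugget-only fit is the weighted mean of the empirical semivariances
  set.seed(31)
  ev2 <- make_ev(1:6, runif(6, 0.5, 1.5), n_pairs = c(5, 9, 20, 31, 40, 55))
  nug <- fit_variogram(ev2, "nugget_only")
  w <- ev2$n_pairs / ev2$lag^2
  expect_equal(nug$nugget, sum(w * ev2$gamma) / sum(w), tolerance = 1e-12)
})

test_that("fitted parameters are never negative", {
  set.seed(12)
  for (i in 1:25) {
    ev <- make_ev(seq(0.8, 8, length.out = 9),
                  pmax(rnorm(9, 0.5, 0.4), 0.001),
                  n_pairs = sample(5:80, 9, replace = TRUE))
    for (fam in c("exponential", "spherical", "gaussian")) {
      fit <- fit_variogram(ev, fam)
      expect_true(fit$nugget >= 0 && fit$psill >= 0 && fit$range > 0)
    }
  }
})

test_that("model selection is minimum-SSE with documented tie-breaking", {
  mk <- function(fam, sse) {
    m <- variogram_model(fam, 0.1, 1, range = 3)
    m$sse <- sse
    m
  }
  nitrate <- list(mk("nugget_only", 203.668), mk("exponential", 41.2651),
                  mk("spherical", 25.5247), mk("gaussian", 22.3183),
                  mk("matern", 23.0069), mk("stein_matern", 23.0069))
  expect_equal(select_best_model(nitrate)$family, "gaussian")
  phosphate <- list(mk("nugget_only", 149688), mk("exponential", 27556.2),
                    mk("spherical", 32351.9), mk("gaussian", 100531),
                    mk("matern", 18961.6), mk("stein_matern", 18827.8))
  expect_equal(select_best_model(phosphate)$family, "stein_matern")
  # exact tie -> earlier family in canonical order
  tie <- list(mk("stein_matern", 1), mk("spherical", 1), mk("gaussian", 2))
  expect_equal(select_best_model(tie)$family, "spherical")
  # permutation invariance away from ties
  set.seed(2)
  expect_equal(select_best_model(sample(nitrate))$family, "gaussian")
  expect_error(select_best_model(list()),
               class = "fieldkrige_selection_error")
})

test_that("spatial-structure LRT is nonnegative, deterministic, and guarded", {
  coords <- expand.grid(row = 0:7, col = 0:7)
  m <- variogram_model("exponential", 0.1, 1, 3)
  z <- simulate_grf(coords, m, seed = 3)
  t1 <- test_spatial_structure(z, coords)
  t2 <- test_spatial_structure(z, coords)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_true(all(t1$lrt[t1$converged] >= 0))
  expect_true(glance(t1)$spatial)  # strong GRF must be flagged
  expect_error(test_spatial_structure(rnorm(5), cbind(1:5, 1)),
               class = "fieldkrige_domain_error")
})
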