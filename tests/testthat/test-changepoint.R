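test_that("noiseless hinge data are recovered exactly", {
  x <- seq(0, 10, by = 0.5)           # threshold 5 is an observed value
  y <- 10 + 2 * pmax(x - 5, 0)
  h <- fit_hinge(x, y, n_perm = 0)
  expect_equal(h$threshold, 5)
  expect_equal(h$beta, 2, tolerance = 1e-8)
  expect_equal(h$mu, 10, tolerance = 1e-8)
  expect_lt(h$rss, 1e-10)
  # chosen threshold is the RSS argmin over the whole candidate grid
  prof <- fieldkrige:::hinge_profile(x, h$candidates)
  rss_all <- fieldkrige:::hinge_stats(prof, y)$rss
  expect_true(all(h$rss <= rss_all + 1e-12))
  expect_error(fit_hinge(x[1:5], y[1:5]),
               class = "fieldkrige_domain_error")
  expect_error(fit_hinge(rep(1:2, 10), rnorm(20)),
               class = "fieldkrige_domain_error")
})

test_that("hinge fits are shift- and scale-equivariant", {
  set.seed(44)
  x <- runif(40, 0, 10)
  y <- 5 + 1.5 * pmax(x - 4, 0) + rnorm(40, 0, 0.3)
  h0 <- fit_hinge(x, y, n_perm = 0)
  hshift <- fit_hinge(x, y + 100, n_perm = 0)
  expect_equal(hshift$mu, h0$mu + 100, tolerance = 1e-8)
  expect_equal(hshift$threshold, h0$threshold)
  expect_equal(hshift$beta, h0$beta, tolerance = 1e-8)
  hscale <- fit_hinge(3 * x, y, n_perm = 0)
  expect_equal(hscale$threshold, 3 * h0$threshold, tolerance = 1e-8)
  expect_equal(hscale$beta, h0$beta / 3, tolerance = 1e-8)
})

test_that("flat responses give uniform permutation p-values", {
  set.seed(45)
  ps <- replicate(100, {
    x <- runif(30, 0, 10)
    y <- rnorm(30)
    fit_hinge(x, y, n_perm = 99, seed = sample.int(1e6, 1))$p_value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.06)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("BH adjustment matches hand computation and the reference", {
  expect_equal(fdr_bh(0.037), 0.037)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(46)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(fdr_bh(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  # monotone in the sorted order
  p <- runif(25)
  adj <- fdr_bh(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(fdr_bh(c(0.5, 1.2)), class = "fieldkrige_domain_error")
  expect_equal(fdr_bh(c(0.2, NA)), c(0.2, NA))
})

test_that("the OTU screen keeps its books and controls false positives", {
  set.seed(47)
  n <- 60; n_otu <- 30
  plot_ids <- sprintf("p%03d", 1:n)
  phen <- tibble::tibble(plot_id = plot_ids, height = rnorm(n, 100, 10))
  adj <- tidyr::expand_grid(otu = sprintf("otu_%02d", 1:n_otu),
                            plot_id = plot_ids)
  adj$sample_id <- paste0(adj$plot_id, "_soil")
  adj$compartment <- "soil"
  adj$observed <- rnbinom(nrow(adj), mu = 40, size = 1)
  adj$adjusted <- adj$observed * exp(rnorm(nrow(adj), 0, 0.1))
  scr <- screen_otus(adj, phen, trait = "height", n_perm = 99, seed = 2)
  expect_equal(nrow(scr), 2 * n_otu)
  expect_true(all(table(scr$version) == n_otu))
  smry <- glance(scr)
  # null data: significant-after-FDR calls should be (near) absent
  expect_lte(smry$n_sig_adjusted, 2)
  expect_lte(smry$n_sig_observed, 2)
  # raw false-positive rate near nominal before FDR
  raw <- scr$p_value[scr$version == "observed"]
  expect_lt(mean(raw < 0.05, na.rm = TRUE), 0.2)
})
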