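test_that("a phenotype that is exactly a PC multiple adjusts to a constant", {
  sim <- small_study(seed = 2)
  pcs <- fake_pcs(sim$layout, k = 2, seed = 4)
  y <- 2 * pcs$PC1_krig
  at <- suppressWarnings(pcr_adjust_continuous(y, pcs, sim$layout))
  expect_lt(diff(range(at$adjusted)), 1e-6)
  # the algebraic identity change = -sum(beta_j PCj)
  beta <- attr(at, "coefficients")
  expect_equal(at$change,
               -as.numeric(as.matrix(pcs[, -1]) %*% beta),
               tolerance = 1e-10)
})

test_that("adjustment against unrelated PCs is near-null and idempotent", {
  sim <- small_study(seed = 2)
  pcs <- fake_pcs(sim$layout, k = 2, seed = 9)
  set.seed(31)
  y <- rnorm(nrow(sim$layout), 50, 2)
  at <- pcr_adjust_continuous(y, pcs, sim$layout)
  expect_lt(mean(abs(at$change)), 1)
  # re-adjusting the adjusted phenotype finds ~no remaining soil effect
  at2 <- pcr_adjust_continuous(at$adjusted, pcs, sim$layout)
  expect_lt(max(abs(attr(at2, "coefficients"))),
            max(abs(attr(at, "coefficients"))) + 0.2)
  expect_lt(mean(abs(at2$change)), mean(abs(at$change)) + 0.1)
})

test_that("null-PC coefficient intervals cover zero at the nominal rate", {
  sim <- small_study(seed = 6)
  pcs <- fake_pcs(sim$layout, k = 1, seed = 3)
  covered <- logical(60)
  for (r in seq_len(60)) {
    set.seed(1000 + r)
    y <- rnorm(nrow(sim$layout))
    dat <- data.frame(y = y, x = pcs$PC1_krig,
                      block = sim$layout$block,
                      x1 = sim$layout$row, x2 = sim$layout$col)
    fit <- tryCatch(
      nlme::lme(y ~ x, random = ~ 1 | block,
                correlation = nlme::corExp(form = ~ x1 + x2 | block),
                data = dat, method = "REML"),
      error = function(e) NULL)
    if (is.null(fit)) { covered[r] <- NA; next }
    tt <- summary(fit)$tTable["x", ]
    covered[r] <- abs(tt[["Value"]]) < 1.99 * tt[["Std.Error"]]
  }
  expect_gte(mean(covered, na.rm = TRUE), 0.85)
})

test_that("count adjustment identities hold exactly", {
  obs <- c(0, 1, 5.5, 100)
  expect_identical(adjust_count_values(obs, rep(0, 4)), obs)
  lp <- c(1, 1, -1, 0)
  adj <- adjust_count_values(obs, lp)
  expect_true(all(adj[lp > 0 & obs > 0] < obs[lp > 0 & obs > 0]))
  expect_true(all(adj[lp < 0 & obs > 0] > obs[lp < 0 & obs > 0]))
  expect_identical(adj[obs == 0], 0)
  expect_error(adjust_count_values(-1, 0), class = "fieldkrige_domain_error")
})

test_that("ZINB count adjustment recovers coefficients and reports retention", {
  set.seed(55)
  n <- 200; n_otu <- 8
  b_true <- c(0.7, -0.4)
  layout <- tibble::tibble(
    plot_id = sprintf("p%03d", 1:n), row = 0:(n - 1), col = 0,
    block = rep(1:8, length.out = n), treatment = "WW", genotype = "g1")
  pcs <- tibble::tibble(plot_id = layout$plot_id,
                        PC1_krig = rnorm(n), PC2_krig = rnorm(n))
  X <- as.matrix(pcs[, -1])
  counts <- vapply(seq_len(n_otu), function(j) {
    mu <- exp(log(80) + as.numeric(X %*% b_true))
    y <- rnbinom(n, mu = mu, size = 1)
    y[runif(n) < 0.2] <- 0
    y
  }, numeric(n))
  otus <- make_otus(counts, plot_ids = layout$plot_id)
  adj <- pcr_adjust_counts(otus, pcs, layout)
  ret <- attr(adj, "retention")
  expect_equal(ret$attempted, n_otu)
  expect_gt(ret$retained_frac, 0.5)
  cf <- attr(adj, "coefficients")
  b1 <- median(cf$estimate[cf$term == "PC1_krig"])
  b2 <- median(cf$estimate[cf$term == "PC2_krig"])
  expect_lt(abs(b1 - 0.7), 0.2)
  expect_lt(abs(b2 + 0.4), 0.2)
  # zeros preserved, positives positive, bookkeeping consistent
  expect_identical(adj$adjusted == 0, adj$observed == 0)
  expect_true(all(adj$adjusted >= 0))
  # adjusted = observed / exp(per-sample linear predictor), per OTU
  one <- adj[adj$otu == adj$otu[1], ]
  b_one <- cf$estimate[cf$otu == adj$otu[1]][-1]
  lp <- as.numeric(X[match(one$plot_id, layout$plot_id), ] %*% b_one)
  expect_equal(one$adjusted, one$observed / exp(lp), tolerance = 1e-10)
})

test_that("the literal constant-divisor form rescales all samples identically", {
  set.seed(56)
  n <- 60
  layout <- tibble::tibble(
    plot_id = sprintf("p%03d", 1:n), row = 0:(n - 1), col = 0,
    block = rep(1:4, length.out = n), treatment = "WW", genotype = "g1")
  pcs <- tibble::tibble(plot_id = layout$plot_id, PC1_krig = rnorm(n))
  counts <- matrix(rnbinom(n * 2, mu = 50, size = 2), n, 2)
  otus <- make_otus(counts, plot_ids = layout$plot_id)
  adj <- pcr_adjust_counts(otus, pcs, layout, literal_constant = TRUE)
  ratio <- adj$adjusted[adj$observed > 0] / adj$observed[adj$observed > 0]
  for (o in unique(adj$otu)) {
    r <- ratio[adj$otu[adj$observed > 0] == o]
    expect_lt(diff(range(r)), 1e-10)
  }
})
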