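test_that("Canberra distance matches hand evaluation and its symmetries", {
  expect_equal(canberra_distance(rbind(1, 3))[1, 2], 0.5)
  set.seed(41)
  m <- matrix(rpois(5 * 8, 3), 5, 8)
  d <- canberra_distance(m)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 5))
  # 0/0 features are skipped: adding an all-zero feature changes nothing
  expect_equal(canberra_distance(cbind(m, 0)), d)
  expect_error(canberra_distance(rbind(-1, 2)),
               class = "fieldkrige_domain_error")
  # agreement with base dist (no zero pairs involved here)
  mpos <- m + 1
  expect_equal(canberra_distance(mpos),
               as.matrix(dist(mpos, method = "canberra")),
               ignore_attr = TRUE, tolerance = 1e-12)
})

perm_fixture <- function(n = 24, seed = 8, effect = 0) {
  set.seed(seed)
  dat <- data.frame(
    g = factor(rep(c("a", "b"), each = n / 2)),
    x = rnorm(n)
  )
  m <- matrix(rpois(n * 15, 20), n, 15)
  m <- m + outer(dat$x, rep(1, 15)) * effect
  m <- pmax(m, 0)
  list(d = canberra_distance(m), dat = dat)
}

test_that("constrained PERMANOVA is scale-invariant and seed-reproducible", {
  fx <- perm_fixture()
  r1 <- suppressWarnings(
    constrained_permanova(fx$d, fx$dat, "x", "g", n_perm = 99, seed = 5))
  r2 <- suppressWarnings(
    constrained_permanova(fx$d * 7.3, fx$dat, "x", "g", n_perm = 99,
                          seed = 5))
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
  expect_identical(r1$p_value, r2$p_value)
  r3 <- suppressWarnings(
    constrained_permanova(fx$d, fx$dat, "x", "g", n_perm = 99, seed = 5))
  expect_identical(as.data.frame(r1), as.data.frame(r3))
  expect_error(
    suppressWarnings(constrained_permanova(fx$d, fx$dat, "g", "g")),
    class = "fieldkrige_collinear_error")
})

test_that("constrained pseudo-F matches vegan::capscale on the same embedding", {
  skip_if_not_installed("vegan")
  fx <- perm_fixture(seed = 12, effect = 3)
  r <- suppressWarnings(
    constrained_permanova(fx$d, fx$dat, "x", "g", n_perm = 99, seed = 2))
  cs <- vegan::capscale(stats::as.dist(fx$d) ~ x + Condition(g),
                        data = fx$dat)
  av <- suppressWarnings(stats::anova(cs, permutations = 99))
  expect_equal(r$statistic, av$F[1], tolerance = 1e-6)
})

test_that("a strong effect hits the permutation floor 1/(n_perm+1)", {
  fx <- perm_fixture(n = 30, seed = 3, effect = 25)
  r <- suppressWarnings(
    constrained_permanova(fx$d, fx$dat, "x", "g", n_perm = 999, seed = 1))
  expect_equal(r$p_value, 0.001)
})

test_that("permutation p agrees with exhaustive enumeration at n = 6", {
  set.seed(19)
  dat <- data.frame(x = rnorm(6))
  m <- matrix(rpois(6 * 6, 12), 6, 6)
  d <- canberra_distance(m)
  r <- suppressWarnings(
    constrained_permanova(d, dat, "x", character(), n_perm = 999, seed = 4))
  # exhaustive oracle over all 720 relabelings of the response rows
  Y <- fieldkrige:::pcoa_embed(d, warn_negative = FALSE)
  X <- cbind(1, dat$x)
  H <- fieldkrige:::hat_matrix(X)
  n <- 6
  Yc <- sweep(Y, 2, colMeans(Y))
  fstat <- function(Yp) {
    ss_t <- sum(((H - matrix(1 / n, n, n)) %*% Yp)^2)
    ss_r <- sum(((diag(n) - H) %*% Yp)^2)
    (ss_t / 1) / (ss_r / (n - 2))
  }
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  f_obs <- fstat(Yc)
  f_all <- apply(perms, 1, function(p) fstat(Yc[p, , drop = FALSE]))
  p_exact <- mean(f_all >= f_obs - 1e-12)
  expect_lt(abs(r$p_value - p_exact), 0.06)
})

test_that("type-III property test detects a perfect signal and is a 1-df chi-square", {
  sim <- small_study(seed = 4)
  prop <- fake_pcs(sim$layout, k = 1, seed = 8)$PC1_krig
  gi <- as.integer(sim$layout$genotype)
  y <- 10 + 0.5 * gi + 3 * prop
  r <- suppressWarnings(type3_property_test(y, prop, sim$layout))
  expect_lt(r$p_value, 1e-6)
  expect_equal(r$df, 1)
  # chi-square consistent with its own tail probability
  expect_equal(r$p_value, pchisq(r$statistic, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("type-III p-values are approximately uniform under the null", {
  sim <- small_study(seed = 4)
  prop <- fake_pcs(sim$layout, k = 1, seed = 8)$PC1_krig
  ps <- numeric(60)
  for (r in seq_len(60)) {
    set.seed(2000 + r)
    y <- rnorm(nrow(sim$layout))
    ps[r] <- suppressWarnings(
      type3_property_test(y, prop, sim$layout))$p_value
  }
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.005)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.08)
})

test_that("design partial R2 matches a hand ANOVA and its bounds", {
  # pure genotype signal
  sim <- small_study(seed = 7)
  dd <- as.data.frame(sim$layout)
  y <- as.integer(sim$layout$genotype) * 2
  r2 <- design_partial_r2(y, dd)
  expect_gt(r2$partial_r2[r2$term == "genotype"], 0.99)
  expect_lt(sum(r2$partial_r2), 1 + 1e-8)

  # univariate oracle on a balanced 2x3 toy: marginal SS via explicit lm
  set.seed(9)
  toy <- expand.grid(treatment = c("WW", "WS"), genotype = c("g1", "g2", "g3"),
                     rep = 1:4)
  toy$y <- rnorm(24, mean = as.integer(factor(toy$genotype)))
  r2t <- design_partial_r2(toy$y, toy)
  sst <- sum((toy$y - mean(toy$y))^2)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  a3 <- car::Anova(lm(y ~ treatment * genotype, data = toy), type = 3)
  for (tm in c("treatment", "genotype", "treatment:genotype")) {
    expect_equal(r2t$partial_r2[r2t$term == tm],
                 a3[tm, "Sum Sq"] / sst, tolerance = 1e-10)
  }
})
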