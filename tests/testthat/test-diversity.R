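test_that("heterozygosity estimators match counting arithmetic", {
  gm <- make_gm(cbind(c(1, 1, 1, 1, 1), c(0, 0, 2, 2, 0),
                      c(1, 1, 1, 0, 2), c(0, 0, 0, 0, 1)))
  expect_equal(unname(obs_het(gm)$per_locus),
               c(1, 0, 0.6, 0.2))
  # He for p = 0.5 (uncorrected) is 0.5; monomorphic is 0
  gm2 <- make_gm(cbind(c(0, 2, 0, 2), c(0, 0, 0, 0), c(0, 0, 0, 1)))
  he <- exp_het(gm2)$per_locus
  expect_equal(unname(he[1]), 0.5)
  expect_equal(unname(he[2]), 0)
  expect_equal(unname(he[3]), 2 * 0.125 * 0.875)
  # p = 0.1 gives 0.18
  gm3 <- make_gm(matrix(c(rep(0, 8), 1, 1), 10, 1))
  expect_equal(unname(exp_het(gm3)$per_locus), 0.18)
  # corrected factor 2n/(2n-1)
  expect_equal(unname(exp_het(gm3, corrected = TRUE)$per_locus),
               0.18 * 20 / 19)
})

test_that("FIS hits the inbred limit, bootstraps reproducibly, covers zero under HW", {
  # fully inbred polymorphic group: no heterozygotes, FIS = 1
  gm <- make_gm(cbind(c(0, 0, 2, 2), c(0, 2, 2, 2), c(2, 0, 0, 0)))
  f <- fis(gm, n_boot = 50, seed = 1)
  expect_equal(f$fis, 1)
  f2 <- fis(gm, n_boot = 50, seed = 1)
  expect_identical(f, f2)
  # all monomorphic: flagged
  gm0 <- make_gm(cbind(rep(0, 4), rep(2, 4)))
  expect_true(fis(gm0, n_boot = 10, seed = 1)$degenerate)
  # Hardy-Weinberg coverage of zero (scaled-down check)
  set.seed(30)
  cover <- vapply(1:60, function(s) {
    p <- runif(120, 0.15, 0.85)
    dos <- vapply(p, function(pp) rbinom(40, 2, pp), numeric(40))
    ff <- fis(make_gm(dos), n_boot = 200, seed = s)
    ff$ci[1] <= 0 && 0 <= ff$ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.85)
  expect_lte(mean(cover), 1.0)
})

test_that("rarefied allelic richness obeys its identities", {
  # g = N recovers the observed allele count
  gm <- make_gm(cbind(c(0, 1, 2, 1), c(0, 0, 0, 0)))
  ar <- allelic_richness(gm, g = 8)
  expect_equal(unname(ar$per_locus), c(2, 1))
  # counts (9, 1) at g = 2: 1 + (1 - 36/45) = 1.2
  gm2 <- make_gm(matrix(c(2, 2, 2, 2, 1), 5, 1))
  expect_equal(allelic_richness(gm2, g = 2)$mean, 1.2)
  # monomorphic locus is 1 at any g
  gm3 <- make_gm(matrix(0, 6, 1))
  for (g in c(2, 5, 12)) expect_equal(allelic_richness(gm3, g = g)$mean, 1)
  expect_error(allelic_richness(gm, g = 1), "g must be")
})

test_that("Weir-Cockerham theta matches a brute-force oracle and its limits", {
  # fixed difference: theta = 1
  gm <- make_gm(rbind(matrix(0, 5, 3), matrix(2, 5, 3)))
  expect_equal(wc_fst(gm, rep(1:2, each = 5))$theta_overall, 1)
  # random small fixtures against the independent loop implementation
  set.seed(31)
  for (i in 1:12) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1); L <- sample(3:10, 1)
    dos <- matrix(sample(c(0L, 1L, 2L, NA), (n1 + n2) * L, replace = TRUE,
                         prob = c(0.35, 0.3, 0.3, 0.05)), n1 + n2, L)
    gm_i <- make_gm(dos)
    pops <- rep(1:2, c(n1, n2))
    ours <- wc_fst(gm_i, pops)$theta_overall
    oracle <- oracle_wc_theta(dos, pops)
    if (is.finite(oracle)) expect_equal(ours, oracle, tolerance = 1e-12)
  }
  # one population split under two labels: theta near zero
  set.seed(32)
  dos <- vapply(runif(800, 0.1, 0.9), function(p) rbinom(100, 2, p),
                numeric(100))
  th <- wc_fst(make_gm(dos), rep(1:2, 50))$theta_overall
  expect_lt(abs(th), 0.02)
})

test_that("relatedness hits pedigree expectations and handles small groups", {
  p <- simulate_sources(2, 1500, 1e-6, seed = 33)
  coh <- simulate_cohort(p, design = list(
    n_reefs = 1, n_blocks = 1, n_per_reef_c1 = 60,
    mixing_matrix = matrix(c(1, 0), 1), n_families_per_source = NULL,
    family_size = NULL), seed = 34)
  gm <- coh$genotypes
  # self-comparison
  expect_equal(wang_relatedness(gm, c(1, 1))$r, 1, tolerance = 0.05)
  # unrelated pairs
  rs <- vapply(1:25, function(i)
    wang_relatedness(gm, c(2 * i - 1, 2 * i))$r, numeric(1))
  expect_equal(mean(rs), 0, tolerance = 0.05)
  # insufficient shared loci flagged
  few <- gm_subset(gm, loci = 1:50)
  expect_true(wang_relatedness(few, c(1, 2))$insufficient)
  expect_false(wang_relatedness(few, c(1, 2), min_loci = 10)$insufficient)
})

test_that("bootstrap mean relatedness degenerates and converges correctly", {
  p <- simulate_sources(2, 800, 1e-6, seed = 35)
  coh <- simulate_cohort(p, design = list(
    n_reefs = 1, n_blocks = 1, n_per_reef_c1 = 40,
    mixing_matrix = matrix(c(1, 0), 1), n_families_per_source = NULL,
    family_size = NULL), seed = 36)
  gm <- coh$genotypes
  # group of 1: no estimate
  expect_true(is.na(bootstrap_mean_relatedness(gm, 1, n_boot = 10)$mean))
  # group of 2: the single pair's value, flagged unbootstrapped
  b2 <- bootstrap_mean_relatedness(gm, 1:2, n_boot = 10, seed = 1)
  expect_true(b2$single_value)
  expect_equal(b2$mean, wang_relatedness(gm_subset(gm, individuals = 1:2),
                                         c(1, 2))$r)
  # larger groups: bootstrap mean approaches the plain mean of all pairs
  M <- relatedness_matrix(gm, 1:30)
  plain <- mean(M[upper.tri(M)])
  b <- bootstrap_mean_relatedness(gm, 1:30, n_boot = 400, seed = 2)
  expect_equal(b$mean, plain, tolerance = 0.01)
  b_again <- bootstrap_mean_relatedness(gm, 1:30, n_boot = 400, seed = 2)
  expect_equal(b$mean, b_again$mean)
})

test_that("squeeze transform and beta-regression trajectories behave", {
  x <- c(-3, 0, 2, 7)
  sx <- squeeze_unit(x)
  expect_true(all(sx > 0 & sx < 1))
  expect_true(all(diff(sx) > 0))
  # beta-regression MLE recovers simulated (mu, phi) (scaled-down check)
  set.seed(37)
  ok <- 0
  for (s in 1:20) {
    x <- rnorm(150)
    mu <- stats::plogis(0.3 + 0.6 * x)
    y <- rbeta(150, mu * 12, (1 - mu) * 12)
    fit <- beta_regression(y ~ x, data.frame(y = y, x = x))
    se <- sqrt(fit$vcov[2, 2])
    if (abs(fit$coefficients[2] - 0.6) < 3 * se) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.85)
  # constant metric: permutation p-values are non-extreme
  set.seed(38)
  dd <- expand.grid(cluster = 1:3, reef = 1:8, census = 1:2)
  dd$block <- (dd$reef - 1) %/% 2 + 1
  dd$metric <- 0.4 + rnorm(nrow(dd), 0, 0.03)
  dt <- diversity_trajectory(dd, n_perm = 49, seed = 39)
  expect_gt(dt$tests$cluster$p_value, 0.05)
  expect_gt(dt$tests$`cluster:census`$p_value, 0.05)
})
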