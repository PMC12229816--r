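test_that("count tables tally assignments with explicit zeros and mixed-reef flags", {
  a <- default_assigned()
  rec <- a$sim$rec
  samples <- rec[rec$sample_id %in% a$asg$sample_ids,
                 c("sample_id", "reef", "block", "census")]
  ct <- build_count_table(a$asg, samples)
  # totals per reef-census equal the number of assigned records
  for (r in unique(ct$reef)) for (cn in unique(ct$census)) {
    expect_equal(sum(ct$count[ct$reef == r & ct$census == cn]),
                 sum(samples$reef == r & samples$census == cn))
  }
  expect_equal(length(attr(ct, "mixed_reefs")), 12)
  # every reef-census carries a row for every cluster (zeros explicit)
  expect_true(all(table(ct$reef, ct$census) %in% c(0, 4)))
  expect_equal(sum(abs(tapply(ct$freq, paste(ct$reef, ct$census), sum) - 1) >
                     1e-9), 0)
})

test_that("exact shift test agrees with enumeration and fisher.test", {
  ct <- data.frame(reef = 1, block = 1,
                   census = rep(1:2, each = 2), cluster = rep(1:2, 2),
                   count = c(3, 1, 1, 3), total = 4, freq = 0.5)
  res <- fisher_shift(ct, reef = 1, cluster = 1)
  expect_equal(res$p_value, 34 / 70, tolerance = 1e-12)
  ct2 <- ct; ct2$count <- c(10, 0, 0, 10)
  res2 <- fisher_shift(ct2, 1, 1)
  expect_equal(res2$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  # identical compositions: p = 1
  ct3 <- ct; ct3$count <- c(5, 5, 5, 5)
  expect_equal(fisher_shift(ct3, 1, 1)$p_value, 1)
  # zero margin flagged degenerate
  ct4 <- ct; ct4$count <- c(0, 4, 0, 4)
  r4 <- fisher_shift(ct4, 1, 1)
  expect_true(r4$degenerate)
  expect_equal(r4$p_value, 1)
  # random tables match stats::fisher.test
  set.seed(20)
  for (i in 1:40) {
    tb <- matrix(rpois(4, 6), 2)
    expect_equal(reefshift:::fisher_p_2x2(tb[1, 1], tb[1, 2],
                                          tb[2, 1], tb[2, 2]),
                 stats::fisher.test(tb)$p.value, tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the hand example and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(21)
  p <- runif(30)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("permutation reef count honours the +1 convention and the null", {
  # a dataset with no shift at all: observed count 0, p = 1
  rec <- data.frame(reef = rep(1:3, each = 20),
                    census = rep(rep(1:2, each = 10), 3),
                    cluster = rep(rep(1:2, 5), 6))
  res <- permutation_reef_count(rec, n_perm = 50, seed = 1)
  expect_equal(res$cluster_1$statistic, 0)
  expect_equal(res$cluster_1$p_value, 1)
  expect_error(permutation_reef_count(rec, n_perm = 0), "n_perm")
  # reproducible under seed
  res2 <- permutation_reef_count(rec, n_perm = 50, seed = 1)
  expect_identical(results_table(res), results_table(res2))
})

test_that("beta-binomial ML matches the binomial limit and glmmTMB", {
  set.seed(22)
  d <- data.frame(cluster = rep(1:2, each = 16),
                  census = rep(rep(1:2, each = 8), 2),
                  block = rep(1:2, 16), total = 40)
  mu <- stats::plogis(-0.4 + 0.5 * (d$cluster == 2) - 0.7 * (d$census == 2))
  # pure binomial data: BB log-likelihood approaches the binomial GLM's
  d$count <- rbinom(32, d$total, mu)
  fit <- betabinom_glm(d)
  glmfit <- stats::glm(cbind(count, total - count) ~
                         factor(cluster) * factor(census) + factor(block),
                       stats::binomial(), d)
  expect_lt(abs(fit$loglik - as.numeric(stats::logLik(glmfit))), 0.5)
  # overdispersed data: agreement with glmmTMB's fixed-effects fit
  skip_if_not_installed("glmmTMB")
  rho <- 0.1
  d$count <- rbinom(32, d$total,
                    rbeta(32, mu * (1 - rho) / rho, (1 - mu) * (1 - rho) / rho))
  fit2 <- betabinom_glm(d)
  tmb <- glmmTMB::glmmTMB(cbind(count, total - count) ~
                            factor(cluster) * factor(census) + factor(block),
                          family = glmmTMB::betabinomial(), data = d)
  expect_equal(fit2$loglik, as.numeric(stats::logLik(tmb)), tolerance = 1e-4)
  expect_equal(unname(fit2$coefficients),
               unname(glmmTMB::fixef(tmb)$cond), tolerance = 1e-3)
  expect_equal(unname(fit2$rho), unname(1 / (1 + glmmTMB::sigma(tmb))),
               tolerance = 1e-3)
  expect_true(fit2$rho > 0 && fit2$rho < 1)
})

test_that("beta-binomial ML recovers simulated parameters", {
  set.seed(23)
  ok <- 0
  for (s in 1:20) {
    d <- data.frame(cluster = 1, census = 1, block = 1, total = 30)
    d <- d[rep(1, 100), ]
    rho <- 0.1; mu <- 0.3
    d$count <- rbinom(100, 30, rbeta(100, mu * (1 - rho) / rho,
                                     (1 - mu) * (1 - rho) / rho))
    fit <- betabinom_glm(d, formula = ~ 1)
    se <- sqrt(fit$vcov[1, 1])
    if (abs(fit$coefficients[1] - stats::qlogis(mu)) < 3 * se) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.85)
})

test_that("year contrasts carry the right structure and adjustment", {
  a <- default_assigned()
  rec <- a$sim$rec
  samples <- rec[rec$sample_id %in% a$asg$sample_ids,
                 c("sample_id", "reef", "block", "census")]
  ct <- build_count_table(a$asg, samples)
  cm <- ct[ct$reef %in% attr(ct, "mixed_reefs"), ]
  fit <- betabinom_glm(cm)
  yc <- year_contrasts(fit)
  expect_length(yc, 4)
  tab <- results_table(yc)
  # Bonferroni: adjusted = min(1, 4 p)
  expect_equal(tab$adjusted_p, pmin(1, 4 * tab$p_value))
  # no-interaction fit: all cluster contrasts identical
  fit0 <- betabinom_glm(cm, formula = ~ factor(cluster) + factor(census) +
                          factor(block))
  yc0 <- year_contrasts(fit0)
  expect_equal(length(unique(round(results_table(yc0)$estimate, 10))), 1)
})

test_that("permutation inference flags the shifted clusters, not the stable ones", {
  s <- default_sim()
  rec <- s$rec
  c1 <- rec[rec$census == 1, ]
  mixed <- names(which(tapply(c1$source, c1$reef,
                              function(x) length(unique(x)) > 1)))
  recs <- data.frame(reef = rec$reef, census = rec$census,
                     cluster = rec$source)
  recs <- recs[recs$reef %in% as.integer(mixed), ]
  pt <- year_contrast_permtest(recs, n_perm = 399, seed = 5)
  expect_lt(pt$cluster_4$estimate, 0)   # survival 0.25: declines
  expect_lte(pt$cluster_4$p_value, 0.05)
  expect_gt(pt$cluster_3$estimate, 0)   # survival 0.75: increases
  expect_gt(pt$cluster_1$p_value, 0.05) # neutral
})

test_that("clr transform matches hand computation and sums to zero", {
  out <- clr_transform(matrix(c(0.5, 0.25, 0.25), 1))
  expect_equal(as.vector(out), c(0.4621, -0.2310, -0.2310), tolerance = 1e-3)
  expect_equal(as.vector(clr_transform(matrix(1 / 3, 1, 3))), rep(0, 3))
  set.seed(24)
  comp <- matrix(rgamma(60, 1), 10, 6)
  comp[sample(60, 8)] <- 0
  comp <- comp / rowSums(comp)
  cl <- clr_transform(comp, pseudocount = 0.01)
  expect_true(all(abs(rowSums(cl)) < 1e-9))
})

test_that("PERMANOVA matches exhaustive enumeration and behaves under the null", {
  set.seed(25)
  X <- matrix(rnorm(12), 6, 2)
  g <- rep(c("a", "b"), each = 3)
  exact <- oracle_permanova_exact(X, g)
  mc <- permanova(X, data.frame(g = g), ~ g, n_perm = 4999, seed = 2)
  tol <- 3 * sqrt(exact * (1 - exact) / 4999) + 1 / 5000
  expect_lt(abs(mc$g$p_value - exact), tol)
  # identical groups: pseudo-F near 1 on average under exchangeability
  set.seed(26)
  fs <- replicate(60, {
    X0 <- matrix(rnorm(40), 20, 2)
    permanova(X0, data.frame(g = rep(1:2, 10)), ~ factor(g),
              n_perm = 1, seed = 1)[[1]]$statistic
  })
  expect_equal(mean(fs), 1, tolerance = 0.25)
  # cross-check statistic against vegan::adonis2
  skip_if_not_installed("vegan")
  X2 <- matrix(rnorm(40), 10, 4)
  meta <- data.frame(y = factor(rep(1:2, 5)), b = factor(rep(1:5, 2)))
  ours <- permanova(X2, meta, ~ y + b, n_perm = 9, seed = 3)
  veg <- vegan::adonis2(stats::dist(X2) ~ y + b, data = meta,
                        permutations = 9, by = "terms")
  expect_equal(ours$y$statistic, veg$F[1], tolerance = 1e-9)
  expect_equal(ours$b$statistic, veg$F[2], tolerance = 1e-9)
  expect_equal(ours$y$R2, veg$R2[1], tolerance = 1e-9)
})

test_that("dispersion test separates scale differences, not translations", {
  set.seed(27)
  A <- matrix(rnorm(40), 20, 2)
  # duplicated group: no dispersion difference
  res0 <- dispersion_test(rbind(A, A), rep(1:2, each = 20), n_perm = 199,
                          seed = 1)
  expect_gt(res0$p_value, 0.2)
  # one group scaled x3
  res1 <- dispersion_test(rbind(A, 3 * A), rep(1:2, each = 20),
                          n_perm = 199, seed = 2)
  expect_lte(res1$p_value, 0.05)
  # translation invariance
  res2 <- dispersion_test(rbind(A, 3 * A) + 100, rep(1:2, each = 20),
                          n_perm = 199, seed = 2)
  expect_equal(res1$statistic, res2$statistic, tolerance = 1e-9)
})

test_that("SIMPER contributions decompose the mean Bray-Curtis dissimilarity", {
  X <- rbind(matrix(c(1, 0, 1, 0), 2, 4), matrix(c(0, 1, 0, 1), 2, 4))
  X[, 2:4] <- 0.5  # identical in all but variable 1
  g <- rep(1:2, each = 2)
  sp <- simper(X, g, n_perm = 99, seed = 1)
  expect_equal(sp$contribution_pct[1], 100)
  set.seed(28)
  X2 <- matrix(rgamma(48, 2), 12, 4)
  g2 <- rep(1:2, each = 6)
  sp2 <- simper(X2, g2, n_perm = 99, seed = 2)
  # contributions sum to the mean between-group dissimilarity
  bc <- function(a, b) sum(abs(a - b)) / sum(a + b)
  pairs <- expand.grid(i = 1:6, j = 7:12)
  mean_bc <- mean(mapply(function(i, j) bc(X2[i, ], X2[j, ]),
                         pairs$i, pairs$j))
  expect_equal(sum(sp2$contribution), mean_bc, tolerance = 1e-12)
  skip_if_not_installed("vegan")
  vs <- summary(vegan::simper(X2, g2, permutations = 9))[[1]]
  expect_equal(sort(sp2$contribution, decreasing = TRUE),
               unname(vs$average), tolerance = 1e-9)
})
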