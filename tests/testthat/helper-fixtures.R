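# Shared fixtures and independent oracles. Expensive simulations are
# cached per session so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

make_gm <- function(dosage, chrom = "chr1", pos = NULL) {
  dosage <- as.matrix(dosage)
  L <- ncol(dosage)
  genotype_matrix(dosage, sprintf("s%02d", seq_len(nrow(dosage))),
                  data.frame(chrom = rep(chrom, length.out = L),
                             pos = if (is.null(pos)) seq_len(L) * 100 else pos,
                             ref = "A", alt = "T"))
}

# Default-scenario simulation at reduced locus count (shared across files).
default_sim <- function(n_loci = 1200, seed = 42) {
  cached(paste0("sim", n_loci, "_", seed), {
    panel <- simulate_sources(4, n_loci, 0.08, seed = seed)
    coh <- simulate_cohort(panel, seed = seed + 1)
    rec <- apply_mortality(coh$truth, c(0.5, 0.5, 0.75, 0.25),
                           seed = seed + 2)
    gm <- gm_subset(coh$genotypes,
                    individuals = coh$genotypes$sample_ids %in%
                      rec$sample_id)
    batch <- ifelse(gm$sample_ids %in%
                      rec$sample_id[rec$census == 2], "fall2020", "fall2018")
    gm <- apply_missingness(gm, batch,
                            c(fall2018 = 0.02, fall2020 = 0.08),
                            seed = seed + 3)
    list(panel = panel, coh = coh, rec = rec, gm = gm,
         batch = stats::setNames(batch, gm$sample_ids))
  })
}

# A filtered + assigned version of the default simulation.
default_assigned <- function() {
  cached("assigned", {
    s <- default_sim()
    filt <- iterative_filter(s$gm, default_cascade())
    asg <- suppressWarnings(
      assign_individuals(filt$gm, K = 4, n_iter = 10, seed = 7))
    truth <- s$coh$truth$source[match(filt$gm$sample_ids,
                                      s$coh$truth$sample_id)]
    list(sim = s, filt = filt, asg = asg, truth = truth)
  })
}

# Condition-index-driven mortality scenario: condition index is cluster-
# structured (through dry tissue mass), the other size traits are not, and
# survival is logistic in -z(condition index). The coupling strength gives
# a standardized regression effect with |t| near 3, the scale of the
# field-reported estimate.
ci_mortality_sim <- function(panel, seed) {
  cfg <- default_trait_config(4, cluster_effect = 0)
  cfg$dry_tissue_mass$mean <- 2.0 * (1 + 0.35 * seq(-1, 1, length.out = 4))
  coh <- simulate_cohort(panel, seed = seed)
  pop <- coh$truth
  pop$census <- 1L
  tr <- simulate_traits(pop, cfg, seed = seed + 1)
  zci <- as.vector(scale(tr$condition_index))
  rec <- apply_mortality(pop, stats::plogis(0.7 - 3 * zci), seed = seed + 2)
  dat <- cluster_reef_shift_data(
    rec, tr, trait_cols = c("condition_index", "shell_height",
                            "shell_length"))
  shift_regression(dat[setdiff(names(dat), c("cluster", "reef"))])
}

# --- independent oracles -------------------------------------------------

# Weir & Cockerham (1984) variance components, written plainly from the
# published per-locus formulas with explicit loops (oracle for wc_fst).
oracle_wc_theta <- function(dosage, pops) {
  pops <- as.integer(factor(pops))
  r <- max(pops)
  num <- den <- 0
  for (l in seq_len(ncol(dosage))) {
    n_i <- p_i <- h_i <- numeric(r)
    ok <- TRUE
    for (i in seq_len(r)) {
      g <- dosage[pops == i, l]
      g <- g[!is.na(g)]
      if (length(g) < 1) { ok <- FALSE; break }
      n_i[i] <- length(g)
      p_i[i] <- sum(g) / (2 * length(g))
      h_i[i] <- mean(g == 1)
    }
    if (!ok) next
    nbar <- mean(n_i)
    if (nbar <= 1) next
    pbar <- sum(n_i * p_i) / sum(n_i)
    if (pbar <= 0 || pbar >= 1) next
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / sum(n_i)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Leave-one-out dfbetas oracle: (b_j - b_j(-i)) / (s_(-i) * sqrt((X'X)^-1_jj)).
oracle_dfbetas <- function(fit) {
  X <- stats::model.matrix(fit)
  y <- stats::model.response(stats::model.frame(fit))
  xtx_inv_d <- sqrt(diag(solve(crossprod(X))))
  b <- stats::coef(fit)
  out <- matrix(0, nrow(X), length(b), dimnames = list(NULL, names(b)))
  for (i in seq_len(nrow(X))) {
    f <- stats::lm.fit(X[-i, , drop = FALSE], y[-i])
    s <- sqrt(sum(f$residuals^2) / f$df.residual)
    out[i, ] <- (b - f$coefficients) / (s * xtx_inv_d)
  }
  out
}

# Exhaustive-permutation PERMANOVA p for a single factor on small n.
oracle_permanova_exact <- function(X, g) {
  n <- nrow(X)
  perms <- gtools_permutations(n)
  f_of <- function(idx) {
    res <- permanova(X[idx, , drop = FALSE], data.frame(g = g), ~ g,
                     n_perm = 1, seed = 1)
    res$g$statistic
  }
  f_obs <- f_of(seq_len(n))
  fs <- apply(perms, 1, f_of)
  mean(fs >= f_obs - 1e-12)
}

# All permutations of 1..n (n small), base R.
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}
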