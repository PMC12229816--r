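test_that("source panel draws are reproducible and respect the F limit", {
  p1 <- simulate_sources(4, 200, 0.08, seed = 1)
  p2 <- simulate_sources(4, 200, 0.08, seed = 1)
  expect_identical(p1, p2)
  expect_true(all(p1$allele_freqs >= 0 & p1$allele_freqs <= 1))
  expect_error(simulate_sources(4, 100, 1.2), "fst_target")
  expect_error(simulate_sources(1, 100, 0.1), "n_sources")
  # zero-divergence limit: per-source freqs collapse onto the ancestral
  p0 <- simulate_sources(3, 400, 1e-6, seed = 2)
  expect_lt(max(abs(sweep(p0$allele_freqs, 2, p0$ancestral_freqs))), 0.01)
})

test_that("realized FST tracks fst_target monotonically", {
  theta_at <- function(f) {
    mean(vapply(1:4, function(s) {
      p <- simulate_sources(2, 600, f, seed = 100 * s)
      coh <- simulate_cohort(p, design = list(
        n_reefs = 2, n_blocks = 2, n_per_reef_c1 = 60,
        mixing_matrix = diag(2), n_families_per_source = NULL,
        family_size = NULL), seed = 100 * s + 1)
      wc_fst(coh$genotypes, coh$truth$source)$theta_overall
    }, numeric(1)))
  }
  th <- vapply(c(0.01, 0.05, 0.10), theta_at, numeric(1))
  expect_true(all(diff(th) > 0))
  expect_equal(th[2], 0.05, tolerance = 0.4)
})

test_that("cohort simulation reproduces the experimental design", {
  s <- default_sim()
  truth <- s$coh$truth
  expect_true(all(table(truth$reef) == 96))  # reef population
  expect_equal(length(unique(truth$reef)), 16)
  expect_equal(length(unique(truth$block)), 4)
  # census-1 sample: 512 records, 32 per reef, disjoint from census 2
  c1 <- s$rec[s$rec$census == 1, ]
  expect_equal(nrow(c1), 512)
  expect_true(all(table(c1$reef) == 32))
  expect_length(intersect(c1$sample_id,
                          s$rec$sample_id[s$rec$census == 2]), 0)
  # identity-like mixing: one source per reef
  p <- simulate_sources(2, 50, 0.05, seed = 5)
  coh <- simulate_cohort(p, design = list(
    n_reefs = 2, n_blocks = 1, n_per_reef_c1 = 10,
    mixing_matrix = diag(2), n_families_per_source = 3,
    family_size = NULL), seed = 6)
  expect_true(all(tapply(coh$truth$source, coh$truth$reef,
                         function(x) length(unique(x))) == 1))
  # invalid mixing row
  expect_error(simulate_cohort(p, design = list(
    n_reefs = 2, n_blocks = 1, n_per_reef_c1 = 10,
    mixing_matrix = matrix(c(0.5, 0.4, 0.4, 0.6), 2, byrow = TRUE),
    n_families_per_source = 3, family_size = NULL), seed = 1),
    "sum to 1")
})

test_that("full-sib families carry pedigree-level relatedness", {
  p <- simulate_sources(2, 1500, 1e-6, seed = 31)
  coh <- simulate_cohort(p, design = list(
    n_reefs = 1, n_blocks = 1, n_per_reef_c1 = 60,
    mixing_matrix = matrix(c(1, 0), 1), n_families_per_source = 30,
    family_size = 2), seed = 32)
  fam <- coh$truth$family_id
  rs <- vapply(seq(1, 40, 2), function(i) {
    j <- setdiff(which(fam == fam[i]), i)[1]
    wang_relatedness(coh$genotypes, c(i, j))$r
  }, numeric(1))
  expect_equal(mean(rs, na.rm = TRUE), 0.5, tolerance = 0.05)
})

test_that("mortality keeps survivors, truncates censuses and shifts the frail cluster", {
  s <- default_sim()
  truth <- s$coh$truth
  # full survival, no truncation: every non-collected oyster is sampled at
  # census 2, and the census samples are disjoint
  rec1 <- apply_mortality(truth, rep(1, 4), min_per_reef = 1,
                          max_per_reef = Inf, seed = 1)
  c1 <- rec1[rec1$census == 1, ]
  c2 <- rec1[rec1$census == 2, ]
  expect_equal(nrow(c1) + nrow(c2), nrow(truth))
  expect_length(intersect(c1$sample_id, c2$sample_id), 0)
  # extinction
  rec0 <- apply_mortality(truth, rep(0, 4), seed = 1)
  expect_equal(sum(rec0$census == 2), 0)
  # census-2 per-reef sizes within [min, max] (or all survivors if fewer)
  rec <- s$rec
  sizes <- table(rec$reef[rec$census == 2])
  expect_true(all(sizes <= 32))
  # frail cluster declines on mixed reefs in most replicates
  declines <- vapply(1:20, function(sd) {
    r <- apply_mortality(truth, c(0.5, 0.5, 0.75, 0.25), seed = 400 + sd)
    mix <- names(which(tapply(truth$source, truth$reef,
                              function(x) length(unique(x)) > 1)))
    f1 <- mean(r$source[r$census == 1 & r$reef %in% mix] == 4)
    f2 <- mean(r$source[r$census == 2 & r$reef %in% mix] == 4)
    f2 < f1
  }, logical(1))
  expect_gte(mean(declines), 0.95)
})

test_that("simulated traits honour the configured prevalence and structure", {
  s <- default_sim()
  cfg <- default_trait_config(4, cluster_effect = 0)
  cfg$prevalence["pm", ] <- 0.8467
  tr <- simulate_traits(s$rec, cfg, seed = 21)
  c1 <- tr$census == 1
  expect_equal(mean(tr$pm_presence[c1]), 0.8467, tolerance = 0.05)
  # condition index consistent with the masses it is derived from
  expect_equal(tr$condition_index,
               100 * tr$dry_tissue_mass / tr$dry_shell_mass)
  # zero prevalence leaves no infections and no intensities
  cfg0 <- default_trait_config(4)
  cfg0$prevalence["blister", ] <- 0
  tr0 <- simulate_traits(s$rec, cfg0, seed = 22)
  expect_equal(sum(tr0$blister_presence[tr0$census == 1]), 0)
  expect_true(all(is.na(tr0$blister_intensity)))
  # intensities only for infected individuals
  expect_true(all(is.na(tr$pm_intensity[c1][!tr$pm_presence[c1]])))
})

test_that("batch missingness is applied at the configured rates, reproducibly", {
  p <- simulate_sources(2, 4000, 0.05, seed = 41)
  coh <- simulate_cohort(p, design = list(
    n_reefs = 2, n_blocks = 1, n_per_reef_c1 = 20,
    mixing_matrix = diag(2), n_families_per_source = NULL,
    family_size = NULL), seed = 42)
  batch <- rep(c("a", "b"), each = 20)
  gm0 <- apply_missingness(coh$genotypes, batch, c(a = 0, b = 0), seed = 1)
  expect_identical(gm0$dosage, coh$genotypes$dosage)
  gm <- apply_missingness(coh$genotypes, batch, c(a = 0, b = 0.15), seed = 2)
  miss_b <- rowMeans(is.na(gm$dosage[batch == "b", ]))
  expect_true(all(miss_b > 0.13 & miss_b < 0.17))
  expect_equal(sum(is.na(gm$dosage[batch == "a", ])), 0)
  gm2 <- apply_missingness(coh$genotypes, batch, c(a = 0, b = 0.15), seed = 2)
  expect_identical(gm$dosage, gm2$dosage)
})

test_that("written datasets round-trip losslessly through the VCF", {
  s <- default_sim()
  sub <- gm_subset(s$gm, individuals = 1:12, loci = 1:80)
  rec <- s$rec[s$rec$sample_id %in% sub$sample_ids, ]
  dir <- withr::local_tempdir()
  paths <- write_dataset(sub, rec, traits = NULL, out_dir = dir)
  gm2 <- read_vcf(paths[["vcf"]])
  ord <- order(sub$loci$chrom, sub$loci$pos)
  expect_identical(unname(sub$dosage[, ord]), unname(gm2$dosage))
  expect_identical(sub$sample_ids, gm2$sample_ids)
  # loci strictly sorted, one record per locus
  expect_false(is.unsorted(gm2$loci$pos[gm2$loci$chrom == gm2$loci$chrom[1]],
                           strictly = TRUE))
  expect_equal(nrow(gm2$loci), 80)
  truth <- utils::read.delim(paths[["truth"]])
  expect_equal(nrow(truth), nrow(rec))
  expect_error(write_dataset(sub, s$rec, NULL, dir), "absent")
})
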