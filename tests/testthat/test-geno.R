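test_that("read_vcf keeps biallelic SNPs, maps GT to dosage, counts drops", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t./.",
    "chr1\t200\t.\tG\tA,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t300\t.\tG\tGA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t400\t.\tC\tG\t.\tPASS\t.\tGT\t1/1\t1|0\t0/0")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_message(gm <- read_vcf(f), "2 non-biallelic")
  expect_equal(attr(gm, "dropped"), 2)
  expect_equal(dim(gm$dosage), c(3L, 2L))
  expect_equal(sum(is.na(gm$dosage)), 1)
  expect_equal(unname(gm$dosage[, 1]), c(0L, 1L, NA))
  expect_equal(unname(gm$dosage[, 2]), c(2L, 1L, 0L))  # phased het handled
  expect_error(read_vcf(file.path(tempdir(), "nope.vcf")), "not found")
})

test_that("locus filters enforce MAC, MAF, call-rate and group missingness", {
  # six designed loci: (1) MAC=1, (2) fine, (3) low call rate,
  # (4) MAF at boundary 0.01 fails strict >, (5) fine, (6) monomorphic
  dos <- cbind(c(0, 0, 0, 0, 1, rep(0, 45)),        # MAC 1
               c(rep(0, 40), rep(1, 10)),           # MAC 10, MAF 0.1
               c(rep(NA, 20), rep(1, 30)),          # call rate 0.6
               c(rep(0, 49), 1),                    # MAF 0.01 exactly
               c(rep(2, 40), rep(1, 10)),           # fine (MAF 0.1)
               rep(0, 50))                          # monomorphic
  gm <- make_gm(dos)
  res <- filter_loci(gm, min_mac = 3, min_maf = 0.01, min_call_rate = 0.9)
  expect_equal(ncol(res$gm$dosage), 2)
  expect_equal(res$gm$loci$pos, c(200, 500))
  expect_equal(res$report$loci_before, 6)
  expect_equal(res$report$loci_after, 2)
  # MAF 0.02 > 0.01 is retained
  dos2 <- cbind(c(rep(0, 48), 1, 1))
  expect_equal(ncol(filter_loci(make_gm(dos2), min_mac = 2,
                                min_maf = 0.01,
                                min_call_rate = 0.5)$gm$dosage), 1)
  # group-wise missingness screen
  grp <- rep(c("x", "y"), each = 25)
  dos3 <- cbind(c(rep(NA, 10), rep(1, 15), rep(0, 20), rep(1, 5)),
                c(rep(1, 25), rep(0, 20), rep(1, 5)))
  res3 <- filter_loci(make_gm(dos3), min_mac = 1, min_maf = 0,
                      min_call_rate = 0.5,
                      max_geno_missing_by_group =
                        list(groups = grp, thresholds = c(x = 0.2, y = 0.2)))
  expect_equal(ncol(res3$gm$dosage), 1)  # locus 1 has 40% missing in x
})

test_that("individual filter and report chains reconcile", {
  dos <- rbind(rep(0:1, 25), c(rep(NA, 10), rep(1, 40)),
               c(rep(NA, 25), rep(0, 25)))
  gm <- make_gm(dos)
  res <- filter_individuals(gm, max_missing = 0.16)
  expect_equal(nrow(res$gm$dosage), 1)  # 0% kept; 20% and 50% removed
  expect_equal(res$report$ind_before - res$report$ind_after, 2)
  expect_error(filter_individuals(gm, 1.2), "max_missing")

  s <- default_sim()
  run <- iterative_filter(s$gm, default_cascade())
  rep_ <- run$report
  expect_true(all(rep_$loci_after <= rep_$loci_before))
  expect_true(all(rep_$ind_after <= rep_$ind_before))
  n <- nrow(rep_)
  expect_equal(rep_$loci_before[-1], rep_$loci_after[-n])
  expect_equal(rep_$ind_before[-1], rep_$ind_after[-n])
  # empty cascade is the identity
  id <- iterative_filter(s$gm, list())
  expect_identical(id$gm$dosage, s$gm$dosage)
  expect_error(iterative_filter(s$gm, list(list(step = "nope", args = list()))),
               "unknown cascade step")
  # idempotence: re-running the cascade on its output changes nothing
  run2 <- iterative_filter(run$gm, default_cascade())
  expect_identical(run2$gm$dosage, run$gm$dosage)
})

test_that("MAF and MAC agree with a brute-force recount under missingness", {
  set.seed(77)
  dos <- matrix(sample(c(0L, 1L, 2L, NA), 300, replace = TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)), 20, 15)
  gm <- make_gm(dos)
  for (j in 1:15) {
    g <- dos[, j][!is.na(dos[, j])]
    alt <- sum(g)
    maf_bf <- min(alt, 2 * length(g) - alt) / (2 * length(g))
    expect_equal(unname(reefshift:::minor_allele_freq(gm)[j]), maf_bf)
    expect_equal(unname(reefshift:::minor_allele_count(gm)[j]),
                 min(alt, 2 * length(g) - alt))
  }
})

test_that("pairwise r2 matches its definition and edge cases", {
  dos <- cbind(c(0, 1, 2, 0), c(2, 1, 0, 2), c(0, 1, 2, 0), c(1, 1, 1, 1))
  gm <- make_gm(dos)
  expect_equal(ld_r2(gm, 1, 3), 1)
  expect_equal(ld_r2(gm, 1, 2), 1)   # perfect negative correlation squared
  expect_true(is.na(ld_r2(gm, 1, 4)))  # monomorphic partner
  # independent loci have low r2 on average
  set.seed(3)
  big <- make_gm(matrix(rbinom(500 * 20, 2, 0.4), 500, 20))
  r2s <- vapply(2:20, function(j) ld_r2(big, 1, j), numeric(1))
  expect_lt(mean(r2s), 0.01)
})

test_that("LD pruning removes duplicates and leaves no violating pair", {
  set.seed(99)
  base <- c(0, 1, 2, 0, 1, 2, 0, 1, 2, 1)
  dos <- cbind(base, base, c(2, 1, 0, 2, 1, 0, 2, 1, 0, 1),
               rbinom(10, 2, 0.5))
  gm <- make_gm(dos)
  pr <- ld_prune(gm, window = 4, step = 1, r2_max = 0.5)
  # the three perfectly correlated copies collapse to one
  kept_correlated <- sum(colnames(pr$gm$dosage) %in%
                           paste0("chr1:", c(100, 200, 300)))
  expect_equal(kept_correlated, 1)
  # all-independent loci: nothing removed
  set.seed(11)
  ind <- make_gm(matrix(rbinom(200 * 60, 2, 0.45), 200, 60))
  expect_length(ld_prune(ind, window = 50, step = 5, r2_max = 0.5)$removed, 0)
  # post-hoc property on structured data
  set.seed(12)
  block <- matrix(rbinom(80 * 6, 2, 0.5), 80, 6)
  noisy <- cbind(block, block + matrix(sample(c(0, 0, 0, 1), 480,
                                              replace = TRUE), 80, 6))
  noisy <- pmin(pmax(noisy, 0), 2)
  gm2 <- make_gm(noisy)
  pruned <- ld_prune(gm2, window = 12, step = 2, r2_max = 0.5)$gm
  L <- ncol(pruned$dosage)
  for (i in seq_len(max(0, L - 1))) {
    for (j in (i + 1):min(L, i + 11)) {
      r2 <- ld_r2(pruned, i, j)
      if (!is.na(r2)) expect_lte(r2, 0.5 + 1e-9)
    }
  }
})
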