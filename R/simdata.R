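#' Simulate diverged source populations (Balding-Nichols model)
#'
#' Draws per-source allele frequencies around a shared ancestral frequency
#' under the Balding-Nichols model: for ancestral frequency p and divergence
#' F, each source's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F), so the
#' among-source variance is F p (1-p) and realized multilocus Weir-Cockerham
#' FST between sources is close to F. This emulates a set of hatchery
#' lineages with moderate pairwise differentiation (FST of roughly
#' 0.05-0.08) without demographic simulation.
#'
#' @param n_sources number of source lineages (>= 2).
#' @param n_loci number of biallelic loci.
#' @param fst_target divergence parameter F, strictly in (0, 1).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param ancestral_range range of the uniform distribution from which
#'   ancestral frequencies are drawn (default `c(0.1, 0.9)`).
#' @return An object of class `source_panel`: a list with `n_sources`,
#'   `allele_freqs` (sources x loci matrix), `ancestral_freqs`, `fst_target`.
#' @export
simulate_sources <- function(n_sources, n_loci, fst_target, seed = NULL,
                             ancestral_range = c(0.1, 0.9)) {
  if (n_sources < 2) stop_param("n_sources must be >= 2")
  if (n_loci < 1) stop_param("n_loci must be >= 1")
  if (!is.finite(fst_target) || fst_target <= 0 || fst_target >= 1)
    stop_param("fst_target must be strictly between 0 and 1")
  with_seed(seed, {
    anc <- stats::runif(n_loci, ancestral_range[1], ancestral_range[2])
    scale <- (1 - fst_target) / fst_target
    freqs <- matrix(stats::rbeta(n_sources * n_loci,
                                 rep(anc, each = n_sources) * scale,
                                 rep(1 - anc, each = n_sources) * scale),
                    nrow = n_sources, ncol = n_loci)
    # rbeta can return exact 0/1 for tiny shape parameters; keep loci usable
    freqs <- pmin(pmax(freqs, 1e-12), 1 - 1e-12)
    structure(list(n_sources = n_sources, allele_freqs = freqs,
                   ancestral_freqs = anc, fst_target = fst_target),
              class = "source_panel")
  })
}

#' Default experimental design for the synthetic restoration cohort
#'
#' Sixteen reefs in four spatial blocks with 32 individuals per reef at the
#' first census (512 total). One reef per block is seeded from a single
#' source (a different source per block); the remaining twelve reefs are
#' even mixtures of all four sources, so exactly twelve reefs are mixed.
#'
#' @param n_sources number of sources (default 4).
#' @param n_reefs,n_blocks,n_per_reef_c1 design constants.
#' @param pop_per_reef oysters living on each reef (default 3 x the
#'   census-1 sample size); censuses sample destructively from this
#'   population, so the two census samples are disjoint individuals as in
#'   the field protocol.
#' @param n_families_per_source,family_size family structure within each
#'   source; `family_size = NULL` assigns individuals to families uniformly
#'   at random, a fixed `family_size` fills families sequentially.
#' @return A design list consumed by [simulate_cohort()].
#' @export
default_design <- function(n_sources = 4, n_reefs = 16, n_blocks = 4,
                           n_per_reef_c1 = 32,
                           pop_per_reef = 3 * n_per_reef_c1,
                           n_families_per_source = 20,
                           family_size = NULL) {
  mix <- matrix(1 / n_sources, n_reefs, n_sources)
  # first reef of each block is single-source (source index = block index)
  reefs_per_block <- n_reefs / n_blocks
  for (b in seq_len(n_blocks)) {
    r <- (b - 1) * reefs_per_block + 1
    mix[r, ] <- 0
    mix[r, 1 + (b - 1) %% n_sources] <- 1
  }
  list(n_reefs = n_reefs, n_blocks = n_blocks, n_per_reef_c1 = n_per_reef_c1,
       pop_per_reef = pop_per_reef, mixing_matrix = mix,
       n_families_per_source = n_families_per_source,
       family_size = family_size)
}

# Draw one offspring dosage row per (maternal, paternal) dosage row pair.
mendelian_offspring <- function(dm, df) {
  n <- length(dm)
  stats::rbinom(n, 1, dm / 2) + stats::rbinom(n, 1, df / 2)
}

#' Simulate a restoration reef population with known truth
#'
#' Places oysters on reefs by multinomial draw from each reef's mixing
#' row (`pop_per_reef` individuals per reef), draws genotypes per source
#' with family structure (full-sib families share one parent pair,
#' producing elevated within-family relatedness), and returns the genotype
#' matrix together with a population truth table. Census samples are drawn
#' from this population by [apply_mortality()].
#'
#' @param panel a `source_panel` from [simulate_sources()].
#' @param design a design list as from [default_design()]; `mixing_matrix`
#'   rows (one per reef) must be nonnegative and sum to 1 over sources.
#'   A missing `pop_per_reef` falls back to `n_per_reef_c1`.
#' @param seed integer seed.
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `truth` (data.frame: sample_id, source, reef, block, family_id), one
#'   row per living oyster.
#' @export
simulate_cohort <- function(panel, design = default_design(panel$n_sources),
                            seed = NULL) {
  mix <- design$mixing_matrix
  if (nrow(mix) != design$n_reefs || ncol(mix) != panel$n_sources)
    stop_param("mixing_matrix must be n_reefs x n_sources")
  if (any(mix < 0) || any(abs(rowSums(mix) - 1) > 1e-9))
    stop_param("each mixing_matrix row must be nonnegative and sum to 1")
  n_pop <- design$pop_per_reef
  if (is.null(n_pop)) n_pop <- design$n_per_reef_c1
  with_seed(seed, {
    n_loci <- ncol(panel$allele_freqs)
    reefs_per_block <- design$n_reefs / design$n_blocks
    # reef membership: multinomial per reef
    src <- integer(0); reef <- integer(0)
    for (r in seq_len(design$n_reefs)) {
      counts <- stats::rmultinom(1, n_pop, mix[r, ])[, 1]
      src <- c(src, rep(seq_len(panel$n_sources), counts))
      reef <- c(reef, rep(r, n_pop))
    }
    n <- length(src)
    block <- (reef - 1) %/% reefs_per_block + 1
    # family assignment within source
    fam <- integer(n)
    for (s in seq_len(panel$n_sources)) {
      idx <- which(src == s)
      if (is.null(design$n_families_per_source)) {
        fam[idx] <- seq_along(idx)  # every individual its own family
      } else if (is.null(design$family_size)) {
        fam[idx] <- sample.int(design$n_families_per_source,
                               length(idx), replace = TRUE)
      } else {
        fam[idx] <- ceiling(seq_along(idx) / design$family_size)
      }
    }
    # parent pool per (source, family), then Mendelian transmission
    dosage <- matrix(NA_integer_, n, n_loci)
    for (s in seq_len(panel$n_sources)) {
      idx <- which(src == s)
      if (!length(idx)) next
      p <- panel$allele_freqs[s, ]
      fams <- sort(unique(fam[idx]))
      parents <- array(stats::rbinom(2L * length(fams) * n_loci, 2,
                                     rep(p, each = 2L * length(fams))),
                       dim = c(2L * length(fams), n_loci))
      for (k in seq_along(fams)) {
        members <- idx[fam[idx] == fams[k]]
        dm <- parents[2 * k - 1, ]; df <- parents[2 * k, ]
        for (m in members) dosage[m, ] <- mendelian_offspring(dm, df)
      }
    }
    ids <- sprintf("ind_%04d", seq_len(n))
    loci <- data.frame(chrom = paste0("chr", 1 + (seq_len(n_loci) - 1) %/% 1000),
                       pos = 1000L + ((seq_len(n_loci) - 1L) %% 1000L) * 250L,
                       ref = "A", alt = "T", stringsAsFactors = FALSE)
    gm <- genotype_matrix(dosage, ids, loci)
    truth <- data.frame(sample_id = ids,
                        source = src,
                        reef = reef,
                        block = block,
                        family_id = paste0("s", src, "_f", fam),
                        stringsAsFactors = FALSE)
    list(genotypes = gm, truth = truth)
  })
}

#' Impose cluster- or individual-specific mortality and two census samples
#'
#' Emulates the field protocol: a census-1 sample of `n_census1` oysters
#' per reef is collected destructively from the reef population; each
#' remaining individual then survives a Bernoulli trial with probability
#' given either per source cluster (length-K vector indexed by
#' `truth$source`) or per individual (length = nrow(truth)); the census-2
#' sample on each reef is a uniform subsample (without replacement) of
#' that reef's remaining survivors, truncated into
#' `[min_per_reef, max_per_reef]` (reefs with fewer survivors than
#' `min_per_reef` keep all survivors). The two census samples are
#' therefore disjoint individuals, so census labels are exchangeable
#' within reefs under equal survival. Survivors keep their genotypes and
#' identities.
#'
#' @param truth population truth table from [simulate_cohort()].
#' @param survival_probs survival probability per cluster (length = number
#'   of sources) or per individual (length = nrow(truth)).
#' @param min_per_reef,max_per_reef census-2 per-reef sample-size bounds.
#' @param n_census1 census-1 sample size per reef (default 32, capped at
#'   the reef population).
#' @param seed integer seed.
#' @return A long records table: one census-1 row per collected oyster
#'   and one census-2 row per sampled survivor (`survived = TRUE`).
#' @export
apply_mortality <- function(truth, survival_probs, min_per_reef = 8,
                            max_per_reef = 32, n_census1 = 32, seed = NULL) {
  check_prob(survival_probs, "survival_probs")
  if (min_per_reef > max_per_reef) stop_param("min_per_reef > max_per_reef")
  n <- nrow(truth)
  p <- if (length(survival_probs) == n) survival_probs
       else survival_probs[truth$source]
  if (anyNA(p)) stop_param("survival_probs does not cover all clusters")
  with_seed(seed, {
    rows1 <- integer(0)
    for (r in sort(unique(truth$reef))) {
      pool <- which(truth$reef == r)
      k <- min(n_census1, length(pool))
      rows1 <- c(rows1, sort(sample(pool, k)))
    }
    survived <- stats::runif(n) < p
    rows2 <- integer(0)
    for (r in sort(unique(truth$reef))) {
      surv_r <- setdiff(which(truth$reef == r & survived), rows1)
      k <- min(length(surv_r), max_per_reef)
      if (length(surv_r) > k) surv_r <- sort(sample(surv_r, k))
      rows2 <- c(rows2, surv_r)
    }
    c1 <- truth[rows1, , drop = FALSE]
    c1$census <- 1L
    c1$survived <- survived[rows1]
    c2 <- truth[rows2, , drop = FALSE]
    c2$census <- if (nrow(c2)) 2L else integer(0)
    c2$survived <- if (nrow(c2)) TRUE else logical(0)
    out <- rbind(c1, c2)
    rownames(out) <- NULL
    out
  })
}

#' Default per-cluster trait and parasite configuration
#'
#' Cluster-specific lognormal size/mass traits, Bernoulli parasite
#' prevalence and intensity distributions. Parasite prevalence defaults are
#' anchored to field-scale values for Perkinsus marinus (0.8467) and mud
#' blister worm (0.4498); size traits default to realistic juvenile-oyster
#' scales with modest cluster offsets so that cluster effects are present
#' but not dominant.
#'
#' @param n_clusters number of clusters.
#' @param cluster_effect multiplier applied to the default between-cluster
#'   offsets; 0 gives an all-cluster-equal configuration.
#' @return A `trait_config` list.
#' @export
default_trait_config <- function(n_clusters = 4, cluster_effect = 1) {
  off <- cluster_effect * seq(-0.15, 0.15, length.out = n_clusters)
  list(
    n_clusters = n_clusters,
    # mean and coefficient of variation of lognormal traits, per cluster
    shell_height  = list(mean = 60 * (1 + off), cv = 0.18),
    shell_length  = list(mean = 45 * (1 + off), cv = 0.18),
    dry_shell_mass  = list(mean = 40 * (1 + off), cv = 0.25),
    dry_tissue_mass = list(mean = 2.0 * (1 + rev(off)), cv = 0.30),
    total_mass_water_factor = 1.15,  # total = (shell + tissue) * factor
    prevalence = rbind(pm      = rep(0.8467, n_clusters) * (1 + 0.05 * off),
                       sso     = rep(0.30, n_clusters) * (1 + off),
                       sponge  = rep(0.25, n_clusters) * (1 + off),
                       blister = rep(0.4498, n_clusters) * (1 + 0.5 * off)),
    pm_intensity = list(meanlog = 2 + off, sdlog = 0.8),    # log-scale load
    blister_intensity = list(mean = stats::plogis(stats::qlogis(0.25) + off), phi = 10)
  )
}

rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

#' Simulate per-record oyster traits and parasite states
#'
#' Draws size and mass traits per record (individual x census) with
#' cluster-specific lognormal distributions, computes condition index from
#' the simulated masses (100 x dry tissue / dry shell), and draws parasite
#' presence (Bernoulli at the cluster prevalence) with intensities only for
#' infected individuals. Parasites are assessed at census 1 only, matching
#' the study design the generator emulates.
#'
#' @param records long records table from [apply_mortality()] (or a
#'   census-1 truth table).
#' @param config a `trait_config` from [default_trait_config()].
#' @param seed integer seed.
#' @return A trait table with one row per record.
#' @export
simulate_traits <- function(records, config = default_trait_config(),
                            seed = NULL) {
  check_prob(config$prevalence, "prevalence")
  cl <- records$source
  n <- nrow(records)
  with_seed(seed, {
    tab <- data.frame(sample_id = records$sample_id,
                      census = records$census,
                      stringsAsFactors = FALSE)
    tab$shell_height <- rlnorm_mean_cv(n, config$shell_height$mean[cl],
                                       config$shell_height$cv)
    tab$shell_length <- rlnorm_mean_cv(n, config$shell_length$mean[cl],
                                       config$shell_length$cv)
    tab$dry_shell_mass <- rlnorm_mean_cv(n, config$dry_shell_mass$mean[cl],
                                         config$dry_shell_mass$cv)
    tab$dry_tissue_mass <- rlnorm_mean_cv(n, config$dry_tissue_mass$mean[cl],
                                          config$dry_tissue_mass$cv)
    tab$total_mass <- (tab$dry_shell_mass + tab$dry_tissue_mass) *
      config$total_mass_water_factor
    tab$condition_index <- condition_index(tab$dry_tissue_mass,
                                           tab$dry_shell_mass)
    c1 <- records$census == 1L
    for (par in rownames(config$prevalence)) {
      pres <- rep(NA, n)
      pres[c1] <- stats::runif(sum(c1)) < config$prevalence[par, cl[c1]]
      tab[[paste0(par, "_presence")]] <- pres
    }
    pm_inf <- which(c1 & tab$pm_presence)
    tab$pm_intensity <- NA_real_
    tab$pm_intensity[pm_inf] <- stats::rnorm(length(pm_inf),
                                             config$pm_intensity$meanlog[cl[pm_inf]],
                                             config$pm_intensity$sdlog)
    bl_inf <- which(c1 & tab$blister_presence)
    tab$blister_intensity <- NA_real_
    mu <- config$blister_intensity$mean[cl[bl_inf]]
    phi <- config$blister_intensity$phi
    tab$blister_intensity[bl_inf] <- stats::rbeta(length(bl_inf),
                                                  mu * phi, (1 - mu) * phi)
    tab
  })
}

#' Mask genotype calls with batch-structured missingness
#'
#' Each call is masked independently with a batch-specific rate plus an
#' optional per-locus Gaussian jitter on the rate (clipped to `[0, 0.95]`),
#' emulating sequencing batches of unequal coverage.
#'
#' @param gm a [genotype_matrix()].
#' @param batch character/factor vector, one batch label per individual.
#' @param per_batch_rate named vector of missingness rates in `[0, 1)`,
#'   names covering the batch labels.
#' @param per_locus_jitter standard deviation of the per-locus rate jitter.
#' @param seed integer seed.
#' @return A `genotype_matrix` with masked calls.
#' @export
apply_missingness <- function(gm, batch, per_batch_rate,
                              per_locus_jitter = 0, seed = NULL) {
  if (any(per_batch_rate < 0 | per_batch_rate >= 1))
    stop_param("per_batch_rate must be in [0, 1)")
  if (length(batch) != nrow(gm$dosage))
    stop_param("batch must have one label per individual")
  if (!all(unique(batch) %in% names(per_batch_rate)))
    stop_param("per_batch_rate must name every batch")
  with_seed(seed, {
    n <- nrow(gm$dosage); L <- ncol(gm$dosage)
    jit <- if (per_locus_jitter > 0)
      stats::rnorm(L, 0, per_locus_jitter) else numeric(L)
    rate <- pmin(pmax(outer(per_batch_rate[batch], jit, `+`), 0), 0.95)
    mask <- matrix(stats::runif(n * L), n, L) < rate
    dos <- gm$dosage
    dos[mask] <- NA_integer_
    genotype_matrix(dos, gm$sample_ids, gm$loci, depth = gm$depth)
  })
}

#' Write a simulated dataset to disk
#'
#' Emits a VCF 4.2 with GT calls (one biallelic record per locus, sorted by
#' chrom/pos), a samples TSV (per-record metadata), a traits TSV and a
#' truth TSV. [read_vcf()] round-trips the dosage matrix losslessly.
#'
#' @param gm a [genotype_matrix()].
#' @param records long records table ([apply_mortality()] output).
#' @param traits trait table ([simulate_traits()] output), or `NULL`.
#' @param out_dir output directory, created if absent.
#' @return Invisibly, the vector of file paths written.
#' @export
write_dataset <- function(gm, records, traits = NULL, out_dir) {
  if (!all(records$sample_id %in% gm$sample_ids))
    stop("records reference samples absent from the genotype matrix",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             samples = file.path(out_dir, "samples.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_vcf(gm, paths["vcf"])
  samples <- records[, intersect(c("sample_id", "reef", "block", "census",
                                   "batch"), names(records))]
  if (is.null(samples$batch))
    samples$batch <- ifelse(samples$census == 2L, "fall2020", "fall2018")
  utils::write.table(samples, paths["samples"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(records, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(traits)) {
    paths <- c(paths, traits = file.path(out_dir, "traits.tsv"))
    utils::write.table(traits, paths["traits"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
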