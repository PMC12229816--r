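#' Build and validate a pipeline run configuration
#'
#' Exactly one of a simulation scenario or a set of input paths (VCF +
#' samples TSV, optional traits TSV) must be supplied. The single global
#' seed is fanned out deterministically per stage.
#'
#' @param scenario optional list of simulation settings: `n_sources`,
#'   `n_loci`, `fst_target`, `survival`, `design`, `trait_config`,
#'   `missingness` (named per-batch rates).
#' @param vcf,samples,traits optional input file paths.
#' @param K number of clusters or "auto".
#' @param alpha,n_perm,n_boot test parameters.
#' @param seed global integer seed (required).
#' @param out_dir output directory, or `NULL` for no file output.
#' @return A validated `run_config` list.
#' @export
run_config <- function(scenario = NULL, vcf = NULL, samples = NULL,
                       traits = NULL, K = "auto", alpha = 0.05,
                       n_perm = 1000, n_boot = 1000, seed, out_dir = NULL) {
  has_sim <- !is.null(scenario)
  has_files <- !is.null(vcf) || !is.null(samples)
  if (has_sim == has_files)
    stop_param("exactly one of scenario or input paths must be set")
  if (has_files && (is.null(vcf) || is.null(samples)))
    stop_param("file input requires both vcf and samples")
  if (missing(seed)) stop_param("seed is required")
  structure(list(scenario = scenario, vcf = vcf, samples = samples,
                 traits = traits, K = K, alpha = alpha,
                 n_perm = n_perm, n_boot = n_boot,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Default simulation scenario
#'
#' Four sources at Balding-Nichols divergence 0.08 over 4000 loci, the
#' 16-reef / 4-block / 32-per-reef design with twelve mixed reefs,
#' cluster survival probabilities (0.5, 0.5, 0.75, 0.25), census-2
#' truncation to 8-32 per reef, default cluster-structured traits, and a
#' higher missing-call rate for the census-2 sequencing batch.
#'
#' @param n_loci number of loci (default 4000).
#' @param fst_target divergence (default 0.08).
#' @param survival per-cluster survival probabilities.
#' @param cluster_effect trait cluster-effect multiplier.
#' @return Scenario list for [run_config()].
#' @export
default_scenario <- function(n_loci = 4000, fst_target = 0.08,
                             survival = c(0.5, 0.5, 0.75, 0.25),
                             cluster_effect = 1) {
  list(n_sources = 4, n_loci = n_loci, fst_target = fst_target,
       survival = survival, design = default_design(4),
       trait_config = default_trait_config(4, cluster_effect),
       missingness = c(fall2018 = 0.02, fall2020 = 0.08),
       min_per_reef = 8, max_per_reef = 32)
}

# Simulate one full dataset from a scenario (genotypes with missingness,
# long records, traits, truth).
simulate_scenario <- function(sc, seed) {
  panel <- simulate_sources(sc$n_sources, sc$n_loci, sc$fst_target,
                            seed = derive_seed(seed, 1))
  coh <- simulate_cohort(panel, sc$design, seed = derive_seed(seed, 2))
  records <- apply_mortality(coh$truth, sc$survival,
                             min_per_reef = sc$min_per_reef,
                             max_per_reef = sc$max_per_reef,
                             n_census1 = sc$design$n_per_reef_c1,
                             seed = derive_seed(seed, 3))
  traits <- simulate_traits(records, sc$trait_config,
                            seed = derive_seed(seed, 4))
  # only sampled oysters are genotyped; each belongs to one census batch
  gm <- gm_subset(coh$genotypes,
                  individuals = coh$genotypes$sample_ids %in%
                    records$sample_id)
  batch <- ifelse(gm$sample_ids %in%
                    records$sample_id[records$census == 2L],
                  "fall2020", "fall2018")
  gm <- apply_missingness(gm, batch, sc$missingness,
                          seed = derive_seed(seed, 5))
  list(panel = panel, genotypes = gm, records = records, traits = traits,
       truth = coh$truth,
       batch = stats::setNames(batch, gm$sample_ids))
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or ingest) -> filter -> assign -> shift tests
#' (exact/permutation, beta-binomial contrasts, CLR + PERMANOVA) ->
#' diversity -> traits. Returns a result bundle and, when `out_dir` is
#' set, writes per-stage TSV/JSON outputs plus a reproducibility manifest.
#'
#' @param config a [run_config()].
#' @return A named list of per-stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }
  # --- ingest / simulate ---
  if (!is.null(config$scenario)) {
    sim <- stage("simulate", simulate_scenario(config$scenario, seed))
    gm <- sim$genotypes
    samples <- sim$records[c("sample_id", "reef", "block", "census")]
    traits <- sim$traits
    truth <- sim$records
  } else {
    gm <- stage("ingest", read_vcf(config$vcf))
    samples <- stage("ingest", utils::read.delim(config$samples))
    traits <- if (!is.null(config$traits))
      stage("ingest", utils::read.delim(config$traits)) else NULL
    truth <- NULL
    sim <- NULL
  }
  # --- filter ---
  batch <- if (!is.null(sim)) sim$batch else NULL
  cascade <- default_cascade(batch_groups = if (!is.null(batch))
    list(groups = batch,
         thresholds = stats::setNames(rep(0.2, length(unique(batch))),
                                      unique(batch))) else NULL)
  filt <- stage("filter", iterative_filter(gm, cascade))
  # --- assign ---
  asg <- stage("assign",
               assign_individuals(filt$gm, K = config$K,
                                  seed = derive_seed(seed, 10)))
  # --- shifts ---
  samples_kept <- samples[samples$sample_id %in% asg$sample_ids, ]
  counts <- stage("shifts", build_count_table(asg, samples_kept))
  recs <- data.frame(reef = samples_kept$reef, block = samples_kept$block,
                     census = samples_kept$census,
                     cluster = asg$hard[match(samples_kept$sample_id,
                                              asg$sample_ids)])
  mixed <- attr(counts, "mixed_reefs")
  recs_mixed <- recs[recs$reef %in% mixed, ]
  counts_mixed <- counts[counts$reef %in% mixed, ]
  perm <- stage("shifts",
                permutation_reef_count(recs_mixed, alpha = config$alpha,
                                       n_perm = config$n_perm,
                                       seed = derive_seed(seed, 11)))
  bbfit <- stage("shifts", betabinom_glm(counts_mixed))
  contrasts <- stage("shifts", year_contrasts(bbfit))
  fm <- stats::reshape(
    counts_mixed[c("reef", "census", "cluster", "freq")],
    idvar = c("reef", "census"), timevar = "cluster", direction = "wide")
  comp <- as.matrix(fm[, -(1:2)])
  meta <- data.frame(census = factor(fm$census),
                     block = factor(counts_mixed$block[
                       match(paste(fm$reef, fm$census),
                             paste(counts_mixed$reef, counts_mixed$census))]))
  clr <- clr_transform(comp,
                       pseudocount = 0.5 / counts_mixed$total[
                         match(paste(fm$reef, fm$census),
                               paste(counts_mixed$reef, counts_mixed$census))])
  pmv <- stage("shifts", permanova(clr, meta, ~ census + block,
                                   n_perm = config$n_perm,
                                   seed = derive_seed(seed, 12)))
  # --- diversity ---
  div <- stage("diversity",
               diversity_records(filt$gm, asg, samples_kept))
  fst <- stage("diversity", wc_fst(filt$gm,
                                   asg$hard[match(filt$gm$sample_ids,
                                                  asg$sample_ids)]))
  # --- traits ---
  trait_res <- NULL
  if (!is.null(traits)) {
    trait_res <- stage("traits",
                       trait_mortality_analysis(traits, recs, samples_kept,
                                                asg, counts_mixed,
                                                seed = derive_seed(seed, 13),
                                                n_perm = min(config$n_perm,
                                                             499)))
  }
  bundle <- list(filter_report = filt$report, assignment = asg,
                 counts = counts, permutation = perm, betabinom = bbfit,
                 year_contrasts = contrasts, permanova = pmv,
                 diversity = div, fst = fst, traits = trait_res,
                 truth = truth,
                 manifest = list(seed = seed, K = asg$K,
                                 alpha = config$alpha,
                                 n_perm = config$n_perm,
                                 n_boot = config$n_boot,
                                 n_loci_final = ncol(filt$gm$dosage),
                                 n_individuals_final = nrow(filt$gm$dosage),
                                 package_version =
                                   as.character(utils::packageVersion("reefshift"))))
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# Per cluster x reef x census diversity records (Ho, He, FIS, Ar).
#' Per-group diversity records
#'
#' Computes Ho, He (corrected), FIS and rarefied allelic richness for each
#' cluster x reef x census group with at least `min_n` individuals; the
#' rarefaction size is the smallest gene-copy count across the compared
#' groups.
#'
#' @param gm filtered [genotype_matrix()].
#' @param assignment a `cluster_assignment`.
#' @param samples sample metadata (sample_id, reef, block, census).
#' @param min_n minimum group size (default 4).
#' @param n_boot FIS bootstrap replicates (default 200).
#' @param seed integer seed.
#' @return data.frame of diversity records.
#' @export
diversity_records <- function(gm, assignment, samples, min_n = 4,
                              n_boot = 200, seed = NULL) {
  cl <- assignment$hard[match(gm$sample_ids, assignment$sample_ids)]
  meta <- samples[match(gm$sample_ids, samples$sample_id), ]
  # samples may contain one row per record (census 1 and 2); map both
  out <- NULL
  key <- unique(data.frame(reef = samples$reef, census = samples$census))
  groups <- list()
  for (i in seq_len(nrow(key))) {
    ids <- samples$sample_id[samples$reef == key$reef[i] &
                               samples$census == key$census[i]]
    for (k in sort(unique(assignment$hard))) {
      idx <- which(gm$sample_ids %in% ids & cl == k)
      if (length(idx) >= min_n)
        groups[[length(groups) + 1]] <-
          list(reef = key$reef[i], census = key$census[i], cluster = k,
               idx = idx)
    }
  }
  if (!length(groups)) return(NULL)
  g <- min(vapply(groups, function(gr) 2 * length(gr$idx), numeric(1)))
  for (gi in seq_along(groups)) {
    gr <- groups[[gi]]
    f <- fis(gm, gr$idx, n_boot = n_boot,
             seed = if (is.null(seed)) NULL else derive_seed(seed, gi))
    out <- rbind(out, data.frame(
      reef = gr$reef, census = gr$census, cluster = gr$cluster,
      n = length(gr$idx),
      ho = obs_het(gm, gr$idx)$mean,
      he = exp_het(gm, gr$idx, corrected = TRUE)$mean,
      fis = f$fis, fis_lo = f$ci[1], fis_hi = f$ci[2],
      ar = allelic_richness(gm, gr$idx, g = g)$mean, g = g))
  }
  out
}

# Cluster-by-reef trait means, delta frequencies and the shift regression.
trait_mortality_analysis <- function(traits, recs, samples, assignment,
                                     counts, seed = NULL, n_perm = 199) {
  cl <- assignment$hard[match(traits$sample_id, assignment$sample_ids)]
  t1 <- traits[traits$census == 1L & !is.na(cl), ]
  cl1 <- cl[traits$census == 1L & !is.na(cl)]
  meta <- samples[match(t1$sample_id, samples$sample_id), ]
  trait_cols <- c("condition_index", "shell_height", "shell_length",
                  "dry_tissue_mass", "dry_shell_mass",
                  "pm_intensity", "blister_intensity")
  trait_cols <- intersect(trait_cols, names(t1))
  grain <- paste(cl1, meta$reef, sep = "_")
  means <- stats::aggregate(t1[trait_cols], by = list(key = grain), mean,
                            na.rm = TRUE)
  parts <- do.call(rbind, strsplit(means$key, "_"))
  means$cluster <- as.integer(parts[, 1]); means$reef <- as.integer(parts[, 2])
  # delta frequency per cluster x reef between censuses
  d1 <- counts[counts$census == 1, ]; d2 <- counts[counts$census == 2, ]
  kk <- paste(means$cluster, means$reef)
  means$delta_freq <- d2$freq[match(kk, paste(d2$cluster, d2$reef))] -
    d1$freq[match(kk, paste(d1$cluster, d1$reef))]
  dat <- means[stats::complete.cases(means[c("delta_freq", trait_cols)]), ]
  retained <- correlation_prune(dat[trait_cols])
  reg <- shift_regression(dat[c("delta_freq", retained)],
                          response = "delta_freq", traits = retained)
  ct <- cluster_trait_test(
    data.frame(condition_index = t1$condition_index, cluster = cl1,
               census = 1L, block = meta$block, reef = meta$reef),
    "condition_index", family = "gaussian", n_perm = n_perm, seed = seed)
  list(cluster_reef_means = means, retained_traits = retained,
       regression = reg, condition_index_test = ct)
}

# Write the pipeline bundle as TSV/JSON files.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(bundle$filter_report,
                     file.path(out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  asg <- bundle$assignment
  post <- as.data.frame(asg$posterior)
  names(post) <- paste0("posterior_", seq_len(ncol(post)))
  utils::write.table(cbind(data.frame(sample_id = asg$sample_ids,
                                      hard_label = asg$hard), post),
                     file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(bundle$counts),
                     file.path(out_dir, "count_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(results_table(bundle$permutation),
                     file.path(out_dir, "permutation_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(results_table(bundle$year_contrasts),
                     file.path(out_dir, "year_contrasts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(results_table(bundle$permanova),
                     file.path(out_dir, "permanova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$diversity))
    utils::write.table(bundle$diversity,
                       file.path(out_dir, "diversity_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
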