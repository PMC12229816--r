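#!/usr/bin/env Rscript
# Stage 6: trait analyses. Rosner outlier screen on condition index;
# cluster-effect tests with reef-respecting permutation inference;
# parasite community SIMPER + dispersion; correlation pruning and the
# trait-to-mortality multiple regression with dfbetas influence screen
# and added-variable data.
suppressPackageStartupMessages(library(reefshift))
seed <- 20177L
traits <- utils::read.delim("results/data/traits.tsv")
samples <- utils::read.delim("results/data/samples.tsv")
asg_tab <- utils::read.delim("results/assignments.tsv")
counts <- utils::read.delim("results/count_table.tsv")

cl <- asg_tab$hard_label[match(traits$sample_id, asg_tab$sample_id)]
t1 <- traits[traits$census == 1 & !is.na(cl), ]
cl1 <- cl[traits$census == 1 & !is.na(cl)]
meta <- samples[match(t1$sample_id, samples$sample_id), ]

out <- esd_outliers(t1$condition_index)
cat("condition-index outliers flagged:", length(out), "\n")
if (length(out)) t1$condition_index[out] <- NA

ct <- cluster_trait_test(
  data.frame(condition_index = t1$condition_index, cluster = cl1,
             census = 1L, block = meta$block, reef = meta$reef),
  "condition_index", n_perm = 199, seed = seed + 61)
cat("\ncondition index ~ cluster (+block), permutation p:\n")
print(results_table(ct$tests))
if (!is.null(ct$tukey)) {
  cat("\nTukey-Kramer pairwise cluster contrasts:\n")
  print(ct$tukey, digits = 3)
}

# parasite community composition by cluster (prevalence by cluster-reef)
pres <- c("pm_presence", "sso_presence", "sponge_presence",
          "blister_presence")
grp <- paste(cl1, meta$reef, sep = "_")
comm <- stats::aggregate(t1[pres], by = list(key = grp), mean, na.rm = TRUE)
comm_cl <- as.integer(sub("_.*", "", comm$key))
two <- comm_cl %in% sort(unique(comm_cl))[1:2]
sp <- simper(as.matrix(comm[two, pres]), comm_cl[two], n_perm = 999,
             seed = seed + 62)
cat("\nSIMPER decomposition (first two clusters):\n")
print(sp, digits = 3)
dt <- dispersion_test(as.matrix(comm[two, pres]), comm_cl[two],
                      n_perm = 999, seed = seed + 63)
cat(sprintf("\ndispersion test: F = %.3f, p = %.3f\n", dt$statistic,
            dt$p_value))

# trait-to-mortality regression at the cluster x reef grain
rec <- data.frame(sample_id = samples$sample_id, reef = samples$reef,
                  census = samples$census,
                  source = asg_tab$hard_label[match(samples$sample_id,
                                                    asg_tab$sample_id)])
dat <- cluster_reef_shift_data(rec, traits,
                               trait_cols = c("condition_index",
                                              "shell_height",
                                              "shell_length",
                                              "dry_tissue_mass",
                                              "dry_shell_mass",
                                              "pm_intensity",
                                              "blister_intensity"))
keep <- correlation_prune(dat[setdiff(names(dat),
                                      c("cluster", "reef", "delta_freq"))])
cat("\ntraits retained after correlation pruning:",
    paste(keep, collapse = ", "), "\n")
sr <- shift_regression(dat[c("delta_freq", keep)])
print(sr)
utils::write.table(sr$coefficients, "results/shift_regression.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
av <- do.call(rbind, lapply(names(sr$added_variable), function(tr)
  data.frame(trait = tr, sr$added_variable[[tr]])))
utils::write.table(av, "results/added_variable_data.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
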