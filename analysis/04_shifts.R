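#!/usr/bin/env Rscript
# Stage 4: the three frequency-shift inferences on mixed reefs:
# (i) per-reef exact tests with BH correction and the within-reef
# permutation null; (ii) fixed-effects beta-binomial regression with
# per-cluster year contrasts (Bonferroni) and their permutation test;
# (iii) CLR + PERMANOVA on reef compositions.
suppressPackageStartupMessages(library(reefshift))
seed <- 20177L
asg_tab <- utils::read.delim("results/assignments.tsv")
samples <- utils::read.delim("results/data/samples.tsv")
samples <- samples[samples$sample_id %in% asg_tab$sample_id, ]
asg <- data.frame(sample_id = asg_tab$sample_id,
                  cluster = asg_tab$hard_label)

counts <- build_count_table(asg, samples)
mixed <- attr(counts, "mixed_reefs")
cat("mixed reefs retained:", length(mixed), "of",
    length(unique(counts$reef)), "\n")
cm <- counts[counts$reef %in% mixed, ]
utils::write.table(as.data.frame(counts), "results/count_table.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

recs <- data.frame(reef = samples$reef, block = samples$block,
                   census = samples$census,
                   cluster = asg$cluster[match(samples$sample_id,
                                               asg$sample_id)])
recs <- recs[recs$reef %in% mixed, ]

pc <- permutation_reef_count(recs, n_perm = 1000, seed = seed + 41)
cat("\nsignificant-reef counts (BH-adjusted exact tests) and permutation p:\n")
print(results_table(pc))

fit <- betabinom_glm(cm)
yc <- year_contrasts(fit)
pt <- year_contrast_permtest(recs, n_perm = 1000, seed = seed + 42)
cat("\nper-cluster year contrasts (logit scale; Bonferroni p):\n")
print(results_table(yc))
cat("\npermutation p for the pooled logit-frequency contrast:\n")
print(results_table(pt))
utils::write.table(cbind(results_table(yc),
                         perm_p = results_table(pt)$p_value),
                   "results/year_contrasts.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

fm <- stats::reshape(cm[c("reef", "census", "cluster", "freq")],
                     idvar = c("reef", "census"), timevar = "cluster",
                     direction = "wide")
tot <- cm$total[match(paste(fm$reef, fm$census),
                      paste(cm$reef, cm$census))]
clr <- clr_transform(as.matrix(fm[, -(1:2)]), pseudocount = 0.5 / tot)
meta <- data.frame(census = factor(fm$census),
                   block = factor(cm$block[match(fm$reef, cm$reef)]))
pmv <- permanova(clr, meta, ~ census + block, n_perm = 1000,
                 seed = seed + 43)
cat("\nPERMANOVA on CLR compositions (census, then block):\n")
print(results_table(pmv))
utils::write.table(results_table(pmv), "results/permanova.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
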