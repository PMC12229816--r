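# A filter report is a data.frame with one row per cascade step:
# step, loci_before, loci_after, ind_before, ind_after, params.
new_report_step <- function(step, gm_before, gm_after, params = "") {
  data.frame(step = step,
             loci_before = ncol(gm_before$dosage),
             loci_after = ncol(gm_after$dosage),
             ind_before = nrow(gm_before$dosage),
             ind_after = nrow(gm_after$dosage),
             params = params, stringsAsFactors = FALSE)
}

#' Filter loci on allele count, frequency, call rate and group missingness
#'
#' A locus is retained iff its minor allele count is at least `min_mac`,
#' its minor allele frequency exceeds `min_maf` (strict), its call rate
#' exceeds `min_call_rate` (strict), and, for each named sample group, its
#' missing-genotype rate within the group is below that group's threshold.
#' Allele frequencies and counts are computed from non-missing calls only.
#' Upstream base-quality/depth filters belong to the variant-calling
#' pipeline and are recorded, not re-applied, here.
#'
#' @param gm a [genotype_matrix()].
#' @param min_mac minimum minor allele count (default 3).
#' @param min_maf strict lower bound on minor allele frequency (default 0.01).
#' @param min_call_rate strict lower bound on call rate (default 0.9).
#' @param max_geno_missing_by_group optional named list
#'   `list(groups = <vector of group labels per individual>, thresholds =
#'   <named vector of strict upper bounds on within-group missing rate>)`.
#' @return list(gm = filtered matrix, report = one-row report step).
#' @export
filter_loci <- function(gm, min_mac = 3, min_maf = 0.01, min_call_rate = 0.9,
                        max_geno_missing_by_group = NULL) {
  if (min_maf < 0 || min_maf >= 0.5) stop_param("min_maf out of range")
  if (min_call_rate < 0 || min_call_rate > 1)
    stop_param("min_call_rate out of range")
  call_rate <- colMeans(!is.na(gm$dosage))
  keep <- minor_allele_count(gm) >= min_mac &
    minor_allele_freq(gm) > min_maf &
    call_rate > min_call_rate
  if (!is.null(max_geno_missing_by_group)) {
    grp <- max_geno_missing_by_group$groups
    # a named group vector is matched to the current samples by id, so the
    # same spec can be reused after individual-filtering steps
    if (!is.null(names(grp))) grp <- grp[gm$sample_ids]
    for (g in names(max_geno_missing_by_group$thresholds)) {
      rows <- grp == g
      miss_g <- colMeans(is.na(gm$dosage[rows, , drop = FALSE]))
      keep <- keep & miss_g < max_geno_missing_by_group$thresholds[[g]]
    }
  }
  keep[is.na(keep)] <- FALSE
  out <- gm_subset(gm, loci = keep)
  if (ncol(out$dosage) == 0) warning("no loci survive the filter")
  list(gm = out,
       report = new_report_step("filter_loci", gm, out,
                                sprintf("mac>=%g, maf>%g, call_rate>%g",
                                        min_mac, min_maf, min_call_rate)))
}

#' Filter individuals on per-individual missingness
#'
#' Retains individuals whose fraction of missing calls is at most
#' `max_missing`.
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing maximum tolerated missing fraction, in (0, 1).
#' @return list(gm = filtered matrix, report = one-row report step).
#' @export
filter_individuals <- function(gm, max_missing) {
  if (max_missing <= 0 || max_missing >= 1)
    stop_param("max_missing must be in (0, 1)")
  miss <- rowMeans(is.na(gm$dosage))
  keep <- miss <= max_missing
  out <- gm_subset(gm, individuals = keep)
  list(gm = out,
       report = new_report_step("filter_individuals", gm, out,
                                sprintf("max_missing<=%g", max_missing)))
}

#' Run an ordered filtering cascade
#'
#' Executes the named steps in order, each on the previous step's output,
#' and accumulates a full filter report whose before/after counts chain.
#' The default cascade mirrors an iterative SNP-filtering protocol: a base
#' locus screen, a permissive individual missingness screen (0.815), a
#' strict locus set (call rate > 0.9, MAF > 0.01, per-batch missingness
#' < 0.2), a strict individual screen (0.16), and sliding-window LD
#' pruning.
#'
#' @param gm a [genotype_matrix()].
#' @param cascade list of steps; each step is
#'   `list(step = "filter_loci"|"filter_individuals"|"ld_prune",
#'   args = list(...))`.
#' @return list(gm = final matrix, report = data.frame of all steps).
#' @export
iterative_filter <- function(gm, cascade) {
  report <- NULL
  for (st in cascade) {
    res <- switch(st$step,
      filter_loci = do.call(filter_loci, c(list(gm), st$args)),
      filter_individuals = do.call(filter_individuals, c(list(gm), st$args)),
      ld_prune = {
        pr <- do.call(ld_prune, c(list(gm), st$args))
        list(gm = pr$gm,
             report = new_report_step("ld_prune", gm, pr$gm,
                                      sprintf("removed %d", length(pr$removed))))
      },
      stop_param("unknown cascade step: ", st$step))
    report <- rbind(report, res$report)
    gm <- res$gm
  }
  list(gm = gm, report = report)
}

#' Default filtering cascade parameters
#'
#' @param batch_groups optional group spec forwarded to [filter_loci()] for
#'   batch-wise missingness screening.
#' @param ld logical; append an LD-pruning step (50-variant window, step 5,
#'   r2 > 0.5)?
#' @return A cascade list for [iterative_filter()].
#' @export
default_cascade <- function(batch_groups = NULL, ld = TRUE) {
  cas <- list(
    list(step = "filter_loci",
         args = list(min_mac = 3, min_maf = 0, min_call_rate = 0.5)),
    list(step = "filter_individuals", args = list(max_missing = 0.815)),
    list(step = "filter_loci",
         args = list(min_mac = 3, min_maf = 0.01, min_call_rate = 0.9,
                     max_geno_missing_by_group = batch_groups)),
    list(step = "filter_individuals", args = list(max_missing = 0.16)))
  if (ld)
    cas <- c(cas, list(list(step = "ld_prune",
                            args = list(window = 50, step = 5, r2_max = 0.5))))
  cas
}
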