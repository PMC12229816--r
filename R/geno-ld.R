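#' Pairwise linkage-disequilibrium r-squared between two loci
#'
#' Squared Pearson correlation of the dosage vectors over individuals with
#' non-missing calls at both loci. Returns `NA` when fewer than two
#' pairwise-complete individuals remain or when either locus is
#' monomorphic in the pairwise-complete subset.
#'
#' @param gm a [genotype_matrix()].
#' @param locus_i,locus_j column indices.
#' @return r-squared in \[0, 1\], or `NA`.
#' @export
ld_r2 <- function(gm, locus_i, locus_j) {
  x <- gm$dosage[, locus_i]; y <- gm$dosage[, locus_j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# r2 matrix among a block of loci (pairwise-complete), NA on monomorphic.
ld_r2_block <- function(dos) {
  suppressWarnings(stats::cor(dos, use = "pairwise.complete.obs")^2)
}

#' Sliding-window LD pruning
#'
#' Scans windows of `window` loci, sliding by `step`, over loci sorted by
#' (chrom, pos). Within a window, while any retained pair has r2 above
#' `r2_max`, one member of the most correlated pair is removed. The removal
#' tie-break (the external tools that perform this step do not document a
#' single rule) is: drop the locus with the lower call rate; on ties the
#' lower minor allele frequency; on ties the later genomic position.
#' Removed loci are never reconsidered.
#'
#' @param gm a [genotype_matrix()] with loci sorted by (chrom, pos).
#' @param window window size in variants (default 50).
#' @param step slide in variants (default 5).
#' @param r2_max retention threshold (default 0.5).
#' @return list(gm = pruned matrix, removed = integer indices into the
#'   input loci).
#' @export
ld_prune <- function(gm, window = 50, step = 5, r2_max = 0.5) {
  L <- ncol(gm$dosage)
  if (any(order(gm$loci$chrom, gm$loci$pos) != seq_len(L)))
    stop_param("loci must be sorted by (chrom, pos)")
  call_rate <- colMeans(!is.na(gm$dosage))
  maf <- minor_allele_freq(gm)
  removed <- logical(L)
  # windows never span chromosomes
  for (chr in unique(gm$loci$chrom)) {
    idx <- which(gm$loci$chrom == chr)
    starts <- seq(1L, max(1L, length(idx) - 1L), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, length(idx))]
      win <- win[!removed[win]]
      if (length(win) < 2) next
      r2 <- ld_r2_block(gm$dosage[, win, drop = FALSE])
      diag(r2) <- 0
      r2[is.na(r2)] <- 0
      while (max(r2) > r2_max) {
        hit <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        pair <- win[c(hit[1], hit[2])]
        # removal rule: lower call rate, then lower MAF, then later position
        o <- order(call_rate[pair], maf[pair], -gm$loci$pos[pair])
        drop <- pair[o[1]]
        removed[drop] <- TRUE
        k <- which(win == drop)
        win <- win[-k]
        r2 <- r2[-k, -k, drop = FALSE]
        if (length(win) < 2) break
      }
    }
  }
  list(gm = gm_subset(gm, loci = !removed), removed = which(removed))
}
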