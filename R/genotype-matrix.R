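#' Construct a genotype matrix
#'
#' The central genotype container: an individuals x loci integer dosage
#' matrix (count of ALT alleles, `NA` = missing call) together with a locus
#' registry (chrom, pos, ref, alt) and unique sample identifiers.
#'
#' @param dosage integer matrix, individuals in rows, loci in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row of `dosage`.
#' @param loci data.frame with columns `chrom`, `pos`, `ref`, `alt`, one row
#'   per column of `dosage`; `(chrom, pos)` must be unique.
#' @param depth optional matrix of per-call read depths, same shape as
#'   `dosage`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sample_ids, loci, depth = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (length(sample_ids) != nrow(dosage))
    stop_param("sample_ids length must equal nrow(dosage)")
  if (anyDuplicated(sample_ids)) stop_param("sample_ids must be unique")
  if (nrow(loci) != ncol(dosage))
    stop_param("loci must have one row per dosage column")
  if (anyDuplicated(paste(loci$chrom, loci$pos)))
    stop_param("(chrom, pos) must be unique")
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 2L))
    stop_param("dosage entries must be in {0, 1, 2, NA}")
  rownames(dosage) <- sample_ids
  colnames(dosage) <- paste(loci$chrom, loci$pos, sep = ":")
  structure(list(dosage = dosage, sample_ids = as.character(sample_ids),
                 loci = as.data.frame(loci), depth = depth),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by explicit indices
#' @param gm a `genotype_matrix`.
#' @param individuals,loci index vectors (logical or integer); `NULL` keeps all.
#' @return A `genotype_matrix`.
#' @export
gm_subset <- function(gm, individuals = NULL, loci = NULL) {
  i <- if (is.null(individuals)) seq_len(nrow(gm$dosage)) else individuals
  j <- if (is.null(loci)) seq_len(ncol(gm$dosage)) else loci
  genotype_matrix(gm$dosage[i, j, drop = FALSE],
                  gm$sample_ids[i],
                  gm$loci[j, , drop = FALSE],
                  depth = if (!is.null(gm$depth)) gm$depth[i, j, drop = FALSE])
}

# Per-locus ALT allele frequency from non-missing calls.
allele_freq <- function(gm) {
  colMeans(gm$dosage, na.rm = TRUE) / 2
}

# Per-locus minor allele frequency / count from non-missing calls.
minor_allele_freq <- function(gm) {
  p <- allele_freq(gm)
  pmin(p, 1 - p)
}

minor_allele_count <- function(gm) {
  alt <- colSums(gm$dosage, na.rm = TRUE)
  tot <- 2L * colSums(!is.na(gm$dosage))
  pmin(alt, tot - alt)
}
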