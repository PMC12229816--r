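#' Read a VCF into a genotype matrix
#'
#' Parses a VCF (4.x) via \pkg{vcfR}, keeps biallelic SNP records only
#' (multi-allelic records and indels are dropped and counted), and converts
#' GT calls to ALT-allele dosages; `./.` becomes a missing call. Records
#' are sorted by (chrom, pos).
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @return A [genotype_matrix()] with attribute `dropped` giving the number
#'   of non-biallelic-SNP records removed.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_param("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ref <- fix$REF; alt <- fix$ALT
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  dropped <- sum(!keep)
  if (dropped) message(dropped, " non-biallelic-SNP record(s) dropped")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  gt_core <- sub(":.*", "", gt)
  alleles <- gsub("[|]", "/", gt_core)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[alleles == "0/0"] <- 0L
  dos[alleles %in% c("0/1", "1/0")] <- 1L
  dos[alleles == "1/1"] <- 2L
  loci <- data.frame(chrom = fix$CHROM[keep],
                     pos = as.integer(fix$POS[keep]),
                     ref = ref[keep], alt = alt[keep],
                     stringsAsFactors = FALSE)
  ord <- order(loci$chrom, loci$pos)
  gm <- genotype_matrix(t(dos)[, ord, drop = FALSE], colnames(gt),
                        loci[ord, , drop = FALSE])
  attr(gm, "dropped") <- dropped
  gm
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits one biallelic SNP record per locus with a GT field, loci sorted by
#' (chrom, pos). A minimal text emitter is used so fixtures stay plain text.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  ord <- order(gm$loci$chrom, gm$loci$pos)
  loci <- gm$loci[ord, , drop = FALSE]
  dos <- gm$dosage[, ord, drop = FALSE]
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")),
             con)
  body <- vapply(seq_len(nrow(loci)), function(j) {
    g <- dos[, j]
    calls <- ifelse(is.na(g), "./.", gt_map[as.character(g)])
    paste(c(loci$chrom[j], loci$pos[j], ".", loci$ref[j], loci$alt[j],
            ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}
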