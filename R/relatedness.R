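# Unbiased estimators of sum_i p_i^m (m = 2, 3, 4) from reference allele
# counts via falling factorials: E[n(n-1)...(n-m+1)] = S(S-1)...(S-m+1) p^m
# for counts n out of S gene copies. Used to debias the moment equations
# for reference-sample allele-frequency error.
unbiased_allele_moments <- function(n_alt, S) {
  counts <- rbind(n_alt, S - n_alt)  # biallelic: ALT and REF counts
  ff <- function(x, m) {
    out <- x
    for (k in seq_len(m - 1)) out <- out * (x - k)
    out
  }
  list(a2 = colSums(ff(counts, 2)) / ff(S, 2),
       a3 = colSums(ff(counts, 3)) / ff(S, 3),
       a4 = colSums(ff(counts, 4)) / ff(S, 4))
}

#' Wang (2002) moment estimator of pairwise relatedness
#'
#' Moment estimator based on the identity-by-state similarity categories
#' of the dyad's genotypes. At a biallelic locus the four published
#' categories reduce to three observable ones (identical genotypes;
#' homozygote-heterozygote sharing an allele; opposite homozygotes), so
#' the two-gene (phi) and four-gene (delta) identity coefficients solve a
#' 2x2 linear system of category-frequency moment equations, with locus
#' weights 1/(2 a2 - a3) and allele-frequency moments debiased for
#' reference-sample size via falling-factorial estimators. Relatedness is
#' r = phi/2 + delta.
#'
#' @param gm a [genotype_matrix()].
#' @param pair length-2 vector of individual indices (or sample ids).
#' @param ref_freqs reference ALT allele frequencies per locus with an
#'   attached reference size; either a numeric vector (frequencies, with
#'   `ref_n` giving diploid reference size) or `NULL` to estimate from all
#'   individuals in `gm`.
#' @param ref_n diploid size of the reference sample used for the
#'   frequency-bias correction (default `nrow(gm$dosage)` when `ref_freqs`
#'   is `NULL`).
#' @param min_loci minimum number of loci called in both individuals
#'   (default 100); fewer yields `NA` with a flag.
#' @return list(r, phi, delta, n_loci, insufficient).
#' @export
wang_relatedness <- function(gm, pair, ref_freqs = NULL, ref_n = NULL,
                             min_loci = 100) {
  if (is.character(pair)) pair <- match(pair, gm$sample_ids)
  if (length(pair) != 2 || anyNA(pair)) stop_param("pair must index 2 samples")
  g1 <- gm$dosage[pair[1], ]; g2 <- gm$dosage[pair[2], ]
  if (is.null(ref_freqs)) {
    ref_n <- nrow(gm$dosage)
    n_called <- colSums(!is.na(gm$dosage))
    S <- 2 * n_called
    n_alt <- colSums(gm$dosage, na.rm = TRUE)
  } else {
    if (is.null(ref_n)) stop_param("ref_n required with explicit ref_freqs")
    S <- rep(2 * ref_n, length(ref_freqs))
    n_alt <- round(ref_freqs * S)
  }
  ok <- !is.na(g1) & !is.na(g2) & S >= 4 & n_alt > 0 & n_alt < S
  if (sum(ok) < min_loci)
    return(list(r = NA_real_, phi = NA_real_, delta = NA_real_,
                n_loci = sum(ok), insufficient = TRUE))
  g1 <- g1[ok]; g2 <- g2[ok]
  am <- unbiased_allele_moments(n_alt[ok], S[ok])
  a2 <- pmin(pmax(am$a2, 1e-12), 1)
  a3 <- pmin(pmax(am$a3, 1e-12), 1)
  a4 <- pmin(pmax(am$a4, 1e-12), 1)
  # observable IBS categories at a biallelic locus
  cat1 <- g1 == g2                                   # identical genotypes
  cat2 <- (g1 == 1) != (g2 == 1) & abs(g1 - g2) == 1 # homo vs het, shared
  # expected category probabilities: unrelated (w) and one-pair-IBD (v)
  w1 <- 2 * a2^2 - a4
  w2 <- 4 * (a3 - a4)
  v1 <- a2
  v2 <- 2 * (a2 - a3)
  wt <- 1 / (2 * a2 - a3)
  wt <- wt / sum(wt)
  P1 <- sum(wt * cat1); P2 <- sum(wt * cat2)
  W1 <- sum(wt * w1); W2 <- sum(wt * w2)
  V1 <- sum(wt * v1); V2 <- sum(wt * v2)
  # P1 = delta + phi V1 + (1 - phi - delta) W1
  # P2 =         phi V2 + (1 - phi - delta) W2
  A <- rbind(c(1 - W1, V1 - W1),
             c(-W2, V2 - W2))
  sol <- solve(A, c(P1 - W1, P2 - W2))
  delta <- sol[1]; phi <- sol[2]
  list(r = phi / 2 + delta, phi = phi, delta = delta,
       n_loci = length(g1), insufficient = FALSE)
}

#' Pairwise relatedness matrix within a group
#'
#' @param gm a [genotype_matrix()].
#' @param group individual indices (>= 2).
#' @param ref_freqs,ref_n,min_loci passed to [wang_relatedness()]; by
#'   default reference frequencies come from the group itself.
#' @return Symmetric matrix of pairwise r (NA diagonal).
#' @export
relatedness_matrix <- function(gm, group, ref_freqs = NULL, ref_n = NULL,
                               min_loci = 100) {
  sub <- gm_subset(gm, individuals = group)
  n <- nrow(sub$dosage)
  if (n < 2) stop_param("group must contain >= 2 individuals")
  M <- matrix(NA_real_, n, n, dimnames = list(sub$sample_ids, sub$sample_ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    M[i, j] <- M[j, i] <- wang_relatedness(sub, c(i, j), ref_freqs = ref_freqs,
                                           ref_n = ref_n,
                                           min_loci = min_loci)$r
  }
  M
}

#' Bootstrap mean pairwise relatedness within a group
#'
#' Per iteration, individuals are resampled with replacement; all pairwise
#' relatedness values among the distinct resampled individuals are
#' extracted (self-pairs from duplicate draws excluded) and their mean
#' recorded. Iterations yielding no pair (a single distinct individual)
#' are skipped and counted. The point estimate is the mean of bootstrap
#' means with a percentile confidence interval. Groups with a single pair
#' carry that pair's value flagged as unbootstrapped; groups of size 1
#' yield no estimate.
#'
#' @param gm a [genotype_matrix()].
#' @param group individual indices.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @param ... passed to [relatedness_matrix()].
#' @return list(mean, ci, n_pairs, n_empty, single_value, boot_means).
#' @export
bootstrap_mean_relatedness <- function(gm, group, n_boot = 1000, seed = NULL,
                                       conf = 0.95, ...) {
  n <- length(group)
  if (n < 2)
    return(list(mean = NA_real_, ci = c(NA_real_, NA_real_), n_pairs = 0,
                n_empty = NA_integer_, single_value = FALSE))
  M <- relatedness_matrix(gm, group, ...)
  pairs <- which(upper.tri(M), arr.ind = TRUE)
  if (nrow(pairs) == 1)
    return(list(mean = M[1, 2], ci = c(M[1, 2], M[1, 2]), n_pairs = 1,
                n_empty = NA_integer_, single_value = TRUE))
  n_empty <- 0L
  boots <- with_seed(seed, {
    out <- numeric(0)
    for (b in seq_len(n_boot)) {
      idx <- unique(sample.int(n, n, replace = TRUE))
      if (length(idx) < 2) { n_empty <- n_empty + 1L; next }
      sub <- M[idx, idx]
      out <- c(out, mean(sub[upper.tri(sub)], na.rm = TRUE))
    }
    out
  })
  alpha <- (1 - conf) / 2
  list(mean = mean(boots),
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       n_pairs = nrow(pairs), n_empty = n_empty,
       single_value = FALSE, boot_means = boots)
}
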