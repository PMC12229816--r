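#' Observed heterozygosity
#'
#' Fraction of heterozygous calls among non-missing calls per locus, and
#' the mean over loci.
#'
#' @param gm a [genotype_matrix()].
#' @param group optional individual index (logical or integer); default all.
#' @return list(per_locus, mean).
#' @export
obs_het <- function(gm, group = NULL) {
  dos <- if (is.null(group)) gm$dosage else gm$dosage[group, , drop = FALSE]
  ho <- colMeans(dos == 1L, na.rm = TRUE)
  list(per_locus = ho, mean = mean(ho, na.rm = TRUE))
}

#' Expected heterozygosity (Nei gene diversity)
#'
#' Per biallelic locus, 2p(1-p) from the group allele frequencies;
#' `corrected = TRUE` applies the small-sample factor 2n/(2n-1).
#'
#' @param gm a [genotype_matrix()].
#' @param group optional individual index; default all.
#' @param corrected apply the unbiased small-sample correction?
#' @return list(per_locus, mean).
#' @export
exp_het <- function(gm, group = NULL, corrected = FALSE) {
  dos <- if (is.null(group)) gm$dosage else gm$dosage[group, , drop = FALSE]
  p <- colMeans(dos, na.rm = TRUE) / 2
  he <- 2 * p * (1 - p)
  if (corrected) {
    n2 <- 2 * colSums(!is.na(dos))
    he <- he * n2 / pmax(n2 - 1, 1)
  }
  list(per_locus = he, mean = mean(he, na.rm = TRUE))
}

#' Inbreeding coefficient with locus-bootstrap confidence interval
#'
#' FIS = 1 - mean(Ho)/mean(Hs) as an aggregate ratio over polymorphic
#' loci, with Hs the small-sample-corrected gene diversity. The percentile
#' confidence interval resamples loci with replacement.
#'
#' @param gm a [genotype_matrix()].
#' @param group optional individual index; default all.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return list(fis, ci = c(lower, upper), n_loci); all-monomorphic input
#'   yields `fis = NA` with `degenerate = TRUE`.
#' @export
fis <- function(gm, group = NULL, n_boot = 1000, seed = NULL, conf = 0.95) {
  ho <- obs_het(gm, group)$per_locus
  hs <- exp_het(gm, group, corrected = TRUE)$per_locus
  poly <- !is.na(hs) & hs > 0
  if (sum(poly) < 2)
    return(list(fis = NA_real_, ci = c(NA_real_, NA_real_),
                n_loci = sum(poly), degenerate = TRUE))
  ho <- ho[poly]; hs <- hs[poly]
  point <- 1 - mean(ho) / mean(hs)
  L <- length(ho)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    i <- sample.int(L, L, replace = TRUE)
    1 - mean(ho[i]) / mean(hs[i])
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  list(fis = point,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       n_loci = L, degenerate = FALSE)
}

#' Rarefied allelic richness
#'
#' Per locus, the expected number of distinct alleles in a random
#' subsample of `g` gene copies: Ar = sum_i \[1 - C(N - N_i, g)/C(N, g)\]
#' over alleles with counts N_i out of N non-missing gene copies. Loci
#' with fewer than `g` copies are excluded from the mean.
#'
#' @param gm a [genotype_matrix()].
#' @param group optional individual index; default all.
#' @param g rarefaction size in gene copies (>= 2).
#' @return list(per_locus, mean, g).
#' @export
allelic_richness <- function(gm, group = NULL, g) {
  if (g < 2) stop_param("g must be >= 2")
  dos <- if (is.null(group)) gm$dosage else gm$dosage[group, , drop = FALSE]
  n_called <- colSums(!is.na(dos))
  N <- 2 * n_called
  n_alt <- colSums(dos, na.rm = TRUE)
  n_ref <- N - n_alt
  ar <- rep(NA_real_, ncol(dos))
  ok <- N >= g
  miss_term <- function(Ni, Ntot)
    exp(lchoose(Ntot - Ni, g) - lchoose(Ntot, g))
  ar[ok] <- (1 - miss_term(n_ref[ok], N[ok])) +
    (1 - miss_term(n_alt[ok], N[ok]))
  list(per_locus = ar, mean = mean(ar, na.rm = TRUE), g = g)
}

# Weir-Cockerham (1984) per-locus variance components for 2+ populations
# at one biallelic locus. n_i, p_i, h_i: sample sizes, ALT frequencies and
# observed heterozygote proportions per population.
wc_components <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  c(a = a, b = b, c = c_)
}

#' Weir-Cockerham FST (theta) with pairwise matrix
#'
#' Per-locus variance components a (among populations), b (among
#' individuals within populations) and c (within individuals), combined as
#' the ratio-of-sums multilocus estimator theta = sum(a) / sum(a + b + c).
#' Loci monomorphic across a population pair (or with a population lacking
#' calls) are excluded from that pair's sums.
#'
#' @param gm a [genotype_matrix()].
#' @param pop_labels population label per individual.
#' @return list(theta_pairwise = symmetric matrix, theta_overall,
#'   components = per-locus a/b/c for the all-population estimate).
#' @export
wc_fst <- function(gm, pop_labels) {
  pop_labels <- factor(pop_labels)
  pops <- levels(pop_labels)
  if (length(pops) < 2) stop_param("need >= 2 populations")
  # per-pop, per-locus n, p, h
  stat_pop <- lapply(pops, function(pp) {
    dos <- gm$dosage[pop_labels == pp, , drop = FALSE]
    n <- colSums(!is.na(dos))
    list(n = n, p = colSums(dos, na.rm = TRUE) / (2 * pmax(n, 1)),
         h = colSums(dos == 1L, na.rm = TRUE) / pmax(n, 1))
  })
  names(stat_pop) <- pops
  theta_of <- function(sub) {
    L <- ncol(gm$dosage)
    comp <- matrix(NA_real_, L, 3)
    for (l in seq_len(L)) {
      n_i <- vapply(sub, function(s) s$n[l], numeric(1))
      if (any(n_i < 1) || mean(n_i) <= 1) next
      p_i <- vapply(sub, function(s) s$p[l], numeric(1))
      h_i <- vapply(sub, function(s) s$h[l], numeric(1))
      pbar <- sum(n_i * p_i) / sum(n_i)
      if (pbar <= 0 || pbar >= 1) next  # monomorphic across the set
      comp[l, ] <- wc_components(n_i, p_i, h_i)
    }
    list(theta = sum(comp[, 1], na.rm = TRUE) /
           sum(comp, na.rm = TRUE),
         components = comp)
  }
  K <- length(pops)
  M <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    M[i, j] <- M[j, i] <- theta_of(stat_pop[c(i, j)])$theta
  }
  overall <- theta_of(stat_pop)
  list(theta_pairwise = M, theta_overall = overall$theta,
       components = overall$components)
}
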