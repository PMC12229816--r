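#' Build a reef x census x cluster count table
#'
#' Tabulates assigned individuals into live-oyster counts per reef, census
#' and genetic cluster (explicit zero rows included) and derives per
#' reef-census relative frequencies. Reefs whose census-1 sample contains a
#' single cluster are flagged for exclusion from shift analyses.
#'
#' @param assignment a `cluster_assignment`, or a data.frame with columns
#'   `sample_id` and `cluster`.
#' @param samples data.frame with columns `sample_id`, `reef`, `block`,
#'   `census` (one row per sampled record).
#' @return An object of class `count_table`: data.frame (reef, block,
#'   census, cluster, count, total, freq) with attribute `mixed_reefs`.
#' @export
build_count_table <- function(assignment, samples) {
  if (inherits(assignment, "cluster_assignment"))
    assignment <- data.frame(sample_id = assignment$sample_ids,
                             cluster = assignment$hard,
                             stringsAsFactors = FALSE)
  cl <- assignment$cluster[match(samples$sample_id, assignment$sample_id)]
  if (anyNA(cl)) stop_param("samples without cluster assignment")
  clusters <- sort(unique(assignment$cluster))
  out <- NULL
  for (r in sort(unique(samples$reef))) {
    for (cen in sort(unique(samples$census))) {
      rows <- samples$reef == r & samples$census == cen
      if (!any(rows)) next
      cnt <- as.vector(table(factor(cl[rows], levels = clusters)))
      out <- rbind(out, data.frame(reef = r,
                                   block = samples$block[rows][1],
                                   census = cen, cluster = clusters,
                                   count = cnt, total = sum(cnt),
                                   freq = cnt / sum(cnt)))
    }
  }
  c1 <- out[out$census == min(out$census), ]
  mixed <- vapply(split(c1, c1$reef), function(d) sum(d$count > 0) > 1,
                  logical(1))
  structure(out, class = c("count_table", "data.frame"),
            mixed_reefs = as.integer(names(mixed))[mixed])
}

# Exact two-sided Fisher p for a 2x2 table [[a, b], [c, d]] by the
# probability-mass rule: sum of hypergeometric outcomes whose probability
# does not exceed that of the observed table.
fisher_p_2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  min(1, sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)]))
}

#' Exact test for a cluster-frequency shift on one reef
#'
#' Two-sided exact hypergeometric (Fisher) test of independence between
#' census and membership in the focal cluster, on the 2x2 table of the
#' focal cluster's count versus the pooled remainder at each census.
#'
#' @param counts a `count_table`.
#' @param reef,cluster the focal reef and cluster.
#' @return A [test_result()] (`statistic` is the sample odds ratio); a zero
#'   margin yields p = 1 with `degenerate = TRUE`.
#' @export
fisher_shift <- function(counts, reef, cluster) {
  d <- counts[counts$reef == reef, ]
  cens <- sort(unique(d$census))
  if (length(cens) != 2) stop_param("reef must have exactly two censuses")
  foc <- vapply(cens, function(cn)
    sum(d$count[d$census == cn & d$cluster == cluster]), numeric(1))
  oth <- vapply(cens, function(cn)
    sum(d$count[d$census == cn & d$cluster != cluster]), numeric(1))
  p <- fisher_p_2x2(foc[1], oth[1], foc[2], oth[2])
  or <- (foc[1] * oth[2]) / (oth[1] * foc[2])
  degenerate <- (foc[1] + oth[1] == 0) || (foc[2] + oth[2] == 0) ||
    (foc[1] + foc[2] == 0) || (oth[1] + oth[2] == 0)
  test_result("fisher_exact", statistic = or, p_value = p,
              degenerate = degenerate,
              table = matrix(c(foc, oth), 2, 2,
                             dimnames = list(paste0("census", cens),
                                             c("focal", "others"))))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @return Adjusted p-values (elementwise no smaller than the input).
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_param("p-values outside [0,1]")
  stats::p.adjust(p_values, method = "BH")
}

# For one reef: census-1 focal counts for every cluster given an index
# permutation, plus lookup tables of Fisher p as a function of the focal
# census-1 count (all margins are fixed under within-reef permutation).
reef_fisher_lookup <- function(cl_vec, n1, clusters) {
  n <- length(cl_vec)
  tot_focal <- vapply(clusters, function(cc) sum(cl_vec == cc), numeric(1))
  lapply(seq_along(clusters), function(ci) {
    K <- tot_focal[ci]
    a_vals <- max(0, K - (n - n1)):min(K, n1)
    p <- vapply(a_vals, function(a)
      fisher_p_2x2(a, n1 - a, K - a, (n - n1) - (K - a)), numeric(1))
    stats::setNames(p, a_vals)
  })
}

#' Permutation test for the number of reefs with significant shifts
#'
#' The observed statistic for each cluster is the number of reefs on which
#' the cluster's BH-adjusted (optionally raw) exact p falls below `alpha`.
#' The null reassigns census labels to individuals within each reef
#' (preserving per-census totals), recomputes every reef x cluster exact
#' test, re-applies the BH adjustment across the whole family, and
#' recounts. p = (#\{perm >= obs\} + 1) / (n_perm + 1).
#'
#' @param records individual-level records: data.frame with `reef`,
#'   `census` (two values) and `cluster`.
#' @param alpha significance threshold for counting a reef (default 0.05).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param adjust count reefs on BH-adjusted (TRUE, default) or raw p.
#' @param exclude_single_cluster drop reefs monomorphic at census 1
#'   (default TRUE).
#' @return Named list of [test_result()] per cluster (`statistic` =
#'   observed number of significant reefs).
#' @export
permutation_reef_count <- function(records, alpha = 0.05, n_perm = 1000,
                                   seed = NULL, adjust = TRUE,
                                   exclude_single_cluster = TRUE) {
  if (n_perm < 1) stop_param("n_perm must be >= 1")
  cens <- sort(unique(records$census))
  if (length(cens) != 2) stop_param("records must span exactly two censuses")
  if (exclude_single_cluster) {
    keep <- vapply(split(records, records$reef), function(d)
      length(unique(d$cluster[d$census == cens[1]])) > 1, logical(1))
    records <- records[records$reef %in%
                         as.integer(names(keep))[keep], , drop = FALSE]
  }
  reefs <- sort(unique(records$reef))
  clusters <- sort(unique(records$cluster))
  by_reef <- lapply(reefs, function(r) {
    d <- records[records$reef == r, ]
    list(cl = d$cluster, n1 = sum(d$census == cens[1]),
         lookup = reef_fisher_lookup(d$cluster, sum(d$census == cens[1]),
                                     clusters))
  })
  nR <- length(reefs); nC <- length(clusters)
  count_sig <- function(a_mat) {
    # a_mat: nR x nC matrix of focal census-1 counts
    p <- matrix(NA_real_, nR, nC)
    for (i in seq_len(nR)) for (j in seq_len(nC))
      p[i, j] <- by_reef[[i]]$lookup[[j]][[as.character(a_mat[i, j])]]
    if (adjust) p <- matrix(bh_adjust(as.vector(p)), nR, nC)
    colSums(p < alpha)
  }
  obs_a <- matrix(0, nR, nC)
  for (i in seq_len(nR)) {
    d <- records[records$reef == reefs[i], ]
    for (j in seq_len(nC))
      obs_a[i, j] <- sum(d$cluster == clusters[j] & d$census == cens[1])
  }
  obs <- count_sig(obs_a)
  perm_ge <- rep(0L, nC)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      a_mat <- matrix(0, nR, nC)
      for (i in seq_len(nR)) {
        br <- by_reef[[i]]
        idx <- sample.int(length(br$cl), br$n1)
        tab <- table(factor(br$cl[idx], levels = clusters))
        a_mat[i, ] <- as.vector(tab)
      }
      perm_ge <- perm_ge + as.integer(count_sig(a_mat) >= obs)
    }
  })
  out <- lapply(seq_len(nC), function(j)
    test_result("permutation_reef_count", statistic = obs[j],
                p_value = (perm_ge[j] + 1) / (n_perm + 1),
                n_permutations = as.integer(n_perm),
                alpha = alpha, adjusted_counts = adjust))
  names(out) <- paste0("cluster_", clusters)
  out
}
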