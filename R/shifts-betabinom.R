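# Beta-binomial log-likelihood in the (mu, rho) parametrization:
# k ~ BetaBin(n, a = mu(1-rho)/rho, b = (1-mu)(1-rho)/rho), so rho is the
# intra-class (overdispersion) correlation and rho -> 0 recovers the
# binomial.
bb_loglik <- function(k, n, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

#' Fixed-effects beta-binomial regression with logit link
#'
#' Maximum-likelihood fit of cluster-count data: for each reef x census x
#' cluster row, count ~ BetaBinomial(total, pi, rho) with logit(pi) = X
#' beta, a common overdispersion rho in (0, 1), and design terms given by
#' `formula` (default cluster x census interaction plus block). Numerical
#' optimization starts from a binomial GLM warm start. Reef
#' non-independence is handled downstream by within-reef permutation
#' inference rather than a random intercept.
#'
#' @param counts a `count_table` (or data.frame with `count`, `total`,
#'   `cluster`, `census`, `block`).
#' @param formula right-hand-side model formula (default
#'   `~ factor(cluster) * factor(census) + factor(block)`).
#' @return An object of class `betabinom_fit`: coefficients, `rho`,
#'   `loglik`, `vcov` (observed-information, coefficients only),
#'   `converged`, plus the design and data.
#' @export
betabinom_glm <- function(counts,
                          formula = ~ factor(cluster) * factor(census) +
                            factor(block)) {
  d <- as.data.frame(counts)
  X <- stats::model.matrix(formula, d)
  k <- d$count; n <- d$total
  warm <- suppressWarnings(
    stats::glm.fit(X, cbind(k, n - k), family = stats::binomial()))
  start <- c(warm$coefficients, stats::qlogis(0.05))
  start[!is.finite(start)] <- 0
  negll <- function(theta) {
    beta <- theta[-length(theta)]
    rho <- stats::plogis(theta[length(theta)])
    rho <- min(max(rho, 1e-8), 1 - 1e-8)
    mu <- stats::plogis(drop(X %*% beta))
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    -bb_loglik(k, n, mu, rho)
  }
  opt <- stats::optim(start, negll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  p <- ncol(X)
  vcov_all <- tryCatch(solve(opt$hessian), error = function(e)
    matrix(NA_real_, p + 1, p + 1))
  coefs <- stats::setNames(opt$par[seq_len(p)], colnames(X))
  structure(list(coefficients = coefs,
                 rho = stats::plogis(opt$par[p + 1]),
                 loglik = -opt$value,
                 vcov = vcov_all[seq_len(p), seq_len(p), drop = FALSE],
                 vcov_all = vcov_all,
                 converged = opt$convergence == 0,
                 formula = formula, X = X, data = d),
            class = "betabinom_fit")
}

#' @export
print.betabinom_fit <- function(x, ...) {
  cat(sprintf("betabinom_fit: logLik = %.3f, rho = %.4f (%s)\n",
              x$loglik, x$rho,
              if (x$converged) "converged" else "NOT CONVERGED"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Likelihood-ratio test between nested beta-binomial fits
#'
#' @param full,reduced `betabinom_fit` objects on the same data.
#' @return A [test_result()] with a chi-square LRT statistic.
#' @export
bb_lrt <- function(full, reduced) {
  stat <- 2 * (full$loglik - reduced$loglik)
  df <- ncol(full$X) - ncol(reduced$X)
  test_result("lrt_betabinom", statistic = max(stat, 0), df = df,
              p_value = stats::pchisq(max(stat, 0), df, lower.tail = FALSE))
}

#' Permutation LRT for the cluster x census interaction
#'
#' Observed statistic: LRT of the full model against the no-interaction
#' model. Null distribution: census labels permuted across individuals
#' within each reef (preserving per-census sample sizes), counts rebuilt
#' and both models refit. p = (#\{perm >= obs\} + 1)/(n_perm + 1).
#'
#' @param records individual-level records (`reef`, `block`, `census`,
#'   `cluster`).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return A [test_result()].
#' @export
bb_interaction_permtest <- function(records, n_perm = 1000, seed = NULL) {
  full_f <- ~ factor(cluster) * factor(census) + factor(block)
  red_f <- ~ factor(cluster) + factor(census) + factor(block)
  make_counts <- function(rec) {
    samples <- data.frame(sample_id = seq_len(nrow(rec)), reef = rec$reef,
                          block = rec$block, census = rec$census)
    asg <- data.frame(sample_id = seq_len(nrow(rec)), cluster = rec$cluster)
    build_count_table(asg, samples)
  }
  stat_of <- function(rec) {
    ct <- make_counts(rec)
    bb_lrt(betabinom_glm(ct, full_f), betabinom_glm(ct, red_f))$statistic
  }
  obs <- stat_of(records)
  ge <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      rec <- records
      for (r in unique(rec$reef)) {
        i <- which(rec$reef == r)
        rec$census[i] <- rec$census[i][sample.int(length(i))]
      }
      if (stat_of(rec) >= obs) ge <- ge + 1L
    }
  })
  test_result("bb_interaction_permutation", statistic = obs,
              p_value = (ge + 1) / (n_perm + 1),
              n_permutations = as.integer(n_perm))
}

#' Within-reef permutation test of per-cluster year contrasts
#'
#' Direct permutation inference for the census effect on each cluster's
#' frequency: the observed statistic is the pooled (across reefs) logit
#' frequency at census 2 minus census 1 for the focal cluster, with a 0.5
#' continuity correction; the null permutes census labels across
#' individuals within each reef, preserving per-census sample sizes.
#' Two-sided p = (#\{|perm| >= |obs|\} + 1)/(n_perm + 1).
#'
#' @param records individual-level records (`reef`, `census`, `cluster`).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return Named list of [test_result()] per cluster (`estimate` = pooled
#'   logit-frequency difference).
#' @export
year_contrast_permtest <- function(records, n_perm = 1000, seed = NULL) {
  cens <- sort(unique(records$census))
  if (length(cens) != 2) stop_param("records must span exactly two censuses")
  clusters <- sort(unique(records$cluster))
  reefs <- sort(unique(records$reef))
  by_reef <- lapply(reefs, function(r) {
    d <- records[records$reef == r, ]
    list(cl = d$cluster, n1 = sum(d$census == cens[1]))
  })
  n1_tot <- sum(vapply(by_reef, `[[`, numeric(1), "n1"))
  n_tot <- nrow(records)
  stat_of <- function(counts1) {
    # counts1: focal census-1 count per cluster; totals fixed by design
    tot <- vapply(clusters, function(cc)
      sum(records$cluster == cc), numeric(1))
    k1 <- counts1; k2 <- tot - counts1
    lo <- function(k, n) log((k + 0.5) / (n - k + 0.5))
    lo(k2, n_tot - n1_tot) - lo(k1, n1_tot)
  }
  obs_counts <- vapply(clusters, function(cc)
    sum(records$cluster == cc & records$census == cens[1]), numeric(1))
  obs <- stat_of(obs_counts)
  ge <- rep(0L, length(clusters))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      c1 <- numeric(length(clusters))
      for (br in by_reef) {
        idx <- sample.int(length(br$cl), br$n1)
        c1 <- c1 + as.vector(table(factor(br$cl[idx], levels = clusters)))
      }
      ge <- ge + as.integer(abs(stat_of(c1)) >= abs(obs))
    }
  })
  out <- lapply(seq_along(clusters), function(j)
    test_result("year_contrast_permutation", statistic = obs[j],
                estimate = obs[j],
                p_value = (ge[j] + 1) / (n_perm + 1),
                n_permutations = as.integer(n_perm)))
  names(out) <- paste0("cluster_", clusters)
  out
}

#' Per-cluster census contrasts from a beta-binomial fit
#'
#' Computes, for each cluster, the census-2 minus census-1 contrast of the
#' linear predictor (logit scale) as a linear combination of coefficients,
#' its delta-method standard error from the observed-information
#' covariance, a z-ratio, and Bonferroni-adjusted p-values across clusters.
#'
#' @param fit a converged `betabinom_fit` containing the
#'   cluster x census interaction.
#' @return Named list of [test_result()] per cluster (`estimate` is the
#'   logit-scale contrast).
#' @export
year_contrasts <- function(fit) {
  if (!fit$converged) warning("contrasts from a non-converged fit")
  d <- fit$data
  clusters <- sort(unique(d$cluster))
  cens <- sort(unique(d$census))
  if (length(cens) != 2) stop_param("need exactly two censuses")
  cn <- colnames(fit$X)
  out <- vector("list", length(clusters))
  zs <- es <- ses <- numeric(length(clusters))
  for (i in seq_along(clusters)) {
    # contrast vector: predictor difference census2 - census1 for cluster i
    row2 <- row1 <- d[1, , drop = FALSE]
    row1$cluster <- clusters[i]; row2$cluster <- clusters[i]
    row1$census <- cens[1]; row2$census <- cens[2]
    mm <- stats::model.matrix(fit$formula,
                              rbind(row1, row2,
                                    d[, , drop = FALSE]))[1:2, , drop = FALSE]
    l <- mm[2, ] - mm[1, ]
    es[i] <- sum(l * fit$coefficients)
    ses[i] <- sqrt(drop(t(l) %*% fit$vcov %*% l))
    zs[i] <- es[i] / ses[i]
  }
  praw <- 2 * stats::pnorm(-abs(zs))
  padj <- pmin(1, praw * length(clusters))
  for (i in seq_along(clusters))
    out[[i]] <- test_result("year_contrast", statistic = zs[i],
                            p_value = praw[i], adjusted_p = padj[i],
                            estimate = es[i], se = ses[i])
  names(out) <- paste0("cluster_", clusters)
  out
}
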