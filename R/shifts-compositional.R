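#' Centered log-ratio transform of compositional rows
#'
#' Zeros are replaced by a pseudocount (multiplicative replacement) and
#' rows renormalized before taking clr(x) = ln(x / geometric row mean), so
#' each output row sums to zero.
#'
#' @param freq_matrix rows are compositions (nonnegative, summing to 1).
#' @param pseudocount zero replacement: a scalar, a per-row vector, or the
#'   default `NULL` which uses 0.5 / total when a `total` attribute/column
#'   context is unavailable, falling back to 0.5 / (2 x number of parts).
#' @return Matrix of clr coordinates, same shape.
#' @export
clr_transform <- function(freq_matrix, pseudocount = NULL) {
  X <- as.matrix(freq_matrix)
  if (any(X < 0)) stop_param("compositions must be nonnegative")
  if (is.null(pseudocount)) pseudocount <- 0.5 / (2 * ncol(X))
  pc <- rep(pseudocount, length.out = nrow(X))
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    x[x == 0] <- pc[i]
    X[i, ] <- x / sum(x)
  }
  log(X) - rowMeans(log(X))
}

# Hat (projection) matrix of a design matrix via QR.
hat_matrix <- function(X) {
  q <- qr.Q(qr(X))
  tcrossprod(q)
}

#' Permutational multivariate analysis of variance (Euclidean distances)
#'
#' Pseudo-F statistics from partitioned sums of squared Euclidean
#' distances on the rows of `X` (for clr-transformed compositions this is
#' the Aitchison geometry). Terms are assessed sequentially in formula
#' order; significance is by unrestricted row permutation with
#' p = (#\{F_perm >= F_obs\} + 1)/(n_perm + 1).
#'
#' @param X numeric matrix (rows = observations).
#' @param data data.frame of explanatory variables.
#' @param formula right-hand-side formula over `data`, e.g. `~ year + block`.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return Named list of [test_result()] per term, with `R2` fields; a
#'   constant `X` yields a flagged degenerate result.
#' @export
permanova <- function(X, data, formula, n_perm = 1000, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ss_total <- sum(Xc^2)
  trms <- stats::terms(formula, data = data)
  labs <- attr(trms, "term.labels")
  if (ss_total == 0) {
    res <- lapply(labs, function(l)
      test_result("permanova", statistic = NA_real_, p_value = NA_real_,
                  degenerate = TRUE))
    names(res) <- labs
    return(res)
  }
  # cumulative hat matrices for sequential (type I) partitioning
  hats <- vector("list", length(labs) + 1)
  hats[[1]] <- matrix(1 / n, n, n)  # intercept
  dfs <- numeric(length(labs))
  for (i in seq_along(labs)) {
    f <- stats::reformulate(labs[seq_len(i)])
    M <- stats::model.matrix(f, data)
    hats[[i + 1]] <- hat_matrix(M)
    dfs[i] <- qr(M)$rank - qr(stats::model.matrix(
      if (i == 1) ~1 else stats::reformulate(labs[seq_len(i - 1)]),
      data))$rank
  }
  df_resid <- n - qr(stats::model.matrix(formula, data))$rank
  stat_fun <- function(Y) {
    ss_terms <- vapply(seq_along(labs), function(i)
      sum(((hats[[i + 1]] - hats[[i]]) %*% Y) * Y), numeric(1))
    ss_res <- sum(((diag(n) - hats[[length(hats)]]) %*% Y) * Y)
    (ss_terms / dfs) / (ss_res / df_resid)
  }
  f_obs <- stat_fun(Xc)
  ss_terms_obs <- vapply(seq_along(labs), function(i)
    sum(((hats[[i + 1]] - hats[[i]]) %*% Xc) * Xc), numeric(1))
  ge <- rep(0L, length(labs))
  # relative tolerance so numerically tied permutation statistics (common
  # with few distinct group splits) count as >= the observed value
  eps <- sqrt(.Machine$double.eps) * pmax(abs(f_obs), 1)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      f_p <- stat_fun(Xc[sample.int(n), , drop = FALSE])
      ge <- ge + as.integer(f_p >= f_obs - eps)
    }
  })
  res <- lapply(seq_along(labs), function(i)
    test_result("permanova", statistic = f_obs[i], df = dfs[i],
                p_value = (ge[i] + 1) / (n_perm + 1),
                n_permutations = as.integer(n_perm),
                R2 = ss_terms_obs[i] / ss_total, degenerate = FALSE))
  names(res) <- labs
  res
}

#' Permutation test for homogeneity of multivariate dispersion
#'
#' Computes each row's Euclidean distance to its group centroid and tests
#' the group effect on these dispersions with an ANOVA F statistic whose
#' null distribution comes from permuting group labels.
#'
#' @param X numeric matrix (rows = observations).
#' @param groups group labels.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return A [test_result()] with per-group mean dispersions attached.
#' @export
dispersion_test <- function(X, groups, n_perm = 999, seed = NULL) {
  X <- as.matrix(X)
  groups <- factor(groups)
  disp_of <- function(g) {
    cent <- rowsum(X, g) / as.vector(table(g))
    sqrt(rowSums((X - cent[as.integer(g), , drop = FALSE])^2))
  }
  f_of <- function(g) {
    d <- disp_of(g)
    m <- tapply(d, g, mean)
    ssb <- sum(table(g) * (m - mean(d))^2)
    ssw <- sum((d - m[as.integer(g)])^2)
    dfb <- nlevels(g) - 1; dfw <- length(d) - nlevels(g)
    (ssb / dfb) / (ssw / dfw)
  }
  f_obs <- f_of(groups)
  eps <- sqrt(.Machine$double.eps) * max(abs(f_obs), 1)
  ge <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      if (f_of(groups[sample.int(length(groups))]) >= f_obs - eps)
        ge <- ge + 1L
    }
  })
  test_result("dispersion_permutation", statistic = f_obs,
              df = nlevels(groups) - 1,
              p_value = (ge + 1) / (n_perm + 1),
              n_permutations = as.integer(n_perm),
              group_dispersion = tapply(disp_of(groups), groups, mean))
}

# Per-variable mean Bray-Curtis contribution between two groups.
simper_contrib <- function(X, ia, ib) {
  contrib <- matrix(0, length(ia) * length(ib), ncol(X))
  k <- 0
  for (i in ia) for (j in ib) {
    k <- k + 1
    denom <- sum(X[i, ] + X[j, ])
    contrib[k, ] <- if (denom > 0) abs(X[i, ] - X[j, ]) / denom else 0
  }
  colMeans(contrib)
}

#' Similarity percentage (SIMPER) decomposition
#'
#' Decomposes the average Bray-Curtis dissimilarity between two groups
#' into per-variable contributions (which sum to the mean dissimilarity)
#' and attaches a per-variable permutation p-value: the probability, under
#' shuffled group labels, that a variable's contribution is at least as
#' large as observed.
#'
#' @param X nonnegative community matrix (rows = observations).
#' @param groups vector with exactly two group labels.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return data.frame (variable, contribution, contribution_pct, p_value)
#'   with attribute `mean_dissimilarity`.
#' @export
simper <- function(X, groups, n_perm = 999, seed = NULL) {
  X <- as.matrix(X)
  if (any(X < 0)) stop_param("community matrix must be nonnegative")
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop_param("simper requires exactly two groups")
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  obs <- simper_contrib(X, ia, ib)
  ge <- rep(0L, ncol(X))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      g <- groups[sample.int(length(groups))]
      pa <- which(g == levels(groups)[1]); pb <- which(g == levels(groups)[2])
      ge <- ge + as.integer(simper_contrib(X, pa, pb) >=
                              obs - sqrt(.Machine$double.eps))
    }
  })
  out <- data.frame(variable = colnames(X) %||% paste0("V", seq_len(ncol(X))),
                    contribution = obs,
                    contribution_pct = 100 * obs / sum(obs),
                    p_value = (ge + 1) / (n_perm + 1),
                    stringsAsFactors = FALSE)
  attr(out, "mean_dissimilarity") <- sum(obs)
  attr(out, "n_permutations") <- as.integer(n_perm)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
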