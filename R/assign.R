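#' Principal-component scores of a genotype matrix
#'
#' Missing dosages are mean-imputed per locus (twice the ALT allele
#' frequency), loci are centred (and optionally scaled), monomorphic loci
#' are excluded with a warning, and scores on the top `n_axes` principal
#' axes are returned. Axes are oriented so that the loading of largest
#' magnitude on each axis is positive, removing the sign indeterminacy.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param n_axes number of axes to retain (default 100, capped at the
#'   matrix rank bound `min(n - 1, n_loci)`).
#' @param scale logical; scale loci to unit variance?
#' @return A list with `scores` (n x n_axes), `sdev` (singular values /
#'   sqrt(n-1)) and `var_explained`.
#' @export
pca_scores <- function(gm, n_axes = 100, scale = FALSE) {
  X <- gm$dosage
  p2 <- colMeans(X, na.rm = TRUE)       # 2 * allele frequency
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- p2[j]
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " monomorphic locus/loci excluded from PCA")
    X <- X[, v > 0, drop = FALSE]
  }
  X <- scale(X, center = TRUE, scale = scale)
  n_axes <- min(n_axes, nrow(X) - 1L, ncol(X))
  sv <- svd(X, nu = n_axes, nv = n_axes)
  # orient: largest-|loading| entry of each axis positive
  for (a in seq_len(n_axes)) {
    ld <- sv$v[, a]
    if (ld[which.max(abs(ld))] < 0) {
      sv$v[, a] <- -sv$v[, a]; sv$u[, a] <- -sv$u[, a]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_axes)], n_axes)
  rownames(scores) <- gm$sample_ids
  sdev <- sv$d / sqrt(nrow(X) - 1)
  list(scores = scores, sdev = sdev[seq_len(n_axes)],
       var_explained = sv$d[seq_len(n_axes)]^2 / sum(sv$d^2))
}

# k-means BIC: n * ln(WSS/n) + K * ln(n).
kmeans_bic <- function(wss, n, K) n * log(wss / n) + K * log(n)

#' Successive k-means over a range of K with replicate BIC profile
#'
#' For each K in `k_range` and each of `n_iter` replicates, runs k-means
#' (multiple random starts, best within-cluster sum of squares kept) on
#' the PC scores and records BIC(K) = n ln(WSS/n) + K ln(n). Replicates
#' differ by derived seed streams; the best-WSS labelling per K is kept.
#'
#' @param scores PC score matrix.
#' @param k_range candidate numbers of clusters (default 1:10).
#' @param n_iter replicates per K (default 25).
#' @param seed integer seed.
#' @param nstart random starts per k-means run (default 10).
#' @return An object of class `bic_profile`: list with `k`, `bic` (n_iter x
#'   K matrix), `mean_bic`, `sd_bic`, `labels` (best labelling per K).
#' @export
find_clusters <- function(scores, k_range = 1:10, n_iter = 25, seed = NULL,
                          nstart = 10) {
  n <- nrow(scores)
  k_range <- k_range[k_range <= n]
  if (!length(k_range)) stop_param("k_range exceeds sample size")
  bic <- matrix(NA_real_, n_iter, length(k_range),
                dimnames = list(NULL, paste0("K", k_range)))
  labels <- vector("list", length(k_range))
  base_seed <- if (is.null(seed)) sample.int(2^30, 1) else seed
  for (ki in seq_along(k_range)) {
    K <- k_range[ki]
    best <- Inf
    for (it in seq_len(n_iter)) {
      fit <- with_seed(derive_seed(base_seed, 1000L * ki + it),
                       stats::kmeans(scores, centers = K, nstart = nstart,
                                     iter.max = 100))
      bic[it, ki] <- kmeans_bic(fit$tot.withinss, n, K)
      if (fit$tot.withinss < best) {
        best <- fit$tot.withinss
        labels[[ki]] <- fit$cluster
      }
    }
  }
  structure(list(k = k_range, bic = bic,
                 mean_bic = colMeans(bic),
                 sd_bic = apply(bic, 2, stats::sd),
                 labels = labels),
            class = "bic_profile")
}

#' Select the number of clusters by the Evanno-style delta statistic
#'
#' Computes, for interior K, delta(K) = |mean BIC(K+1) - 2 mean BIC(K) +
#' mean BIC(K-1)| / sd BIC(K) and returns the K maximizing it. Replicate
#' standard deviations that collapse to zero (every k-means run finding
#' the same optimum, as happens on cleanly separated data) are floored at
#' 1e-6 x the BIC range, with a warning, so the statistic degrades to raw
#' second-difference elbow detection; if every second difference is zero
#' (a linear BIC curve) the smallest interior K is returned with a
#' warning.
#'
#' @param profile a `bic_profile` from [find_clusters()].
#' @return Selected K (integer), with the delta curve as attribute `delta`.
#' @export
select_k <- function(profile) {
  k <- profile$k; m <- profile$mean_bic; s <- profile$sd_bic
  if (length(k) < 3) stop_param("need at least 3 K values")
  interior <- 2:(length(k) - 1)
  d2 <- abs(m[interior + 1] - 2 * m[interior] + m[interior - 1])
  # replicate sds can collapse to zero when every k-means run converges to
  # the same optimum (common on cleanly separated data); floor the scale so
  # the statistic degrades to raw second-difference elbow detection there
  floor_s <- 1e-6 * diff(range(m))
  delta <- d2 / pmax(s[interior], floor_s)
  if (any(s[interior] == 0))
    warning("zero BIC sd at some K; scale floored for those K")
  if (all(d2 == 0)) {
    warning("linear BIC curve: all second differences zero")
    kk <- k[interior][1]
  } else kk <- k[interior][which.max(delta)]
  structure(as.integer(kk), delta = stats::setNames(delta, k[interior]))
}

#' Fisher linear discriminant fit on PC scores with Gaussian posteriors
#'
#' Finds up to `n_da` discriminant axes maximizing between- over
#' within-class variance on the retained PCs, then assigns per-individual
#' posterior membership from Gaussian class densities with a shared
#' within-class covariance on the discriminant axes and equal priors. A
#' singular within-class scatter is ridge-regularized (logged epsilon).
#'
#' @param scores PC score matrix.
#' @param labels integer cluster labels (1..K).
#' @param n_pc number of PCs retained (default all columns).
#' @param n_da number of discriminant axes (default K - 1).
#' @return list with `axes` (loadings on PCs), `da_scores`, `posterior`
#'   (n x K, rows sum to 1), `hard` (argmax labels), `means`, `ridge`.
#' @export
dapc_fit <- function(scores, labels, n_pc = ncol(scores), n_da = NULL) {
  labels <- as.integer(factor(labels))
  K <- max(labels)
  if (K < 2) stop_param("need at least 2 clusters")
  X <- scores[, seq_len(min(n_pc, ncol(scores))), drop = FALSE]
  if (is.null(n_da)) n_da <- K - 1L
  n_da <- min(n_da, K - 1L)
  n <- nrow(X); p <- ncol(X)
  mu <- rowsum(X, labels) / as.vector(table(labels))
  Xc <- X - mu[labels, , drop = FALSE]
  W <- crossprod(Xc) / (n - K)
  Bm <- mu - rep(colMeans(X), each = K)
  B <- crossprod(Bm * sqrt(as.vector(table(labels)))) / (K - 1)
  ridge <- 0
  ok <- FALSE
  while (!ok) {
    Wr <- W + diag(ridge, p)
    ev <- tryCatch({
      R <- chol(Wr)
      M <- backsolve(R, forwardsolve(t(R), B), upper.tri = TRUE)
      eigen(M)
    }, error = function(e) NULL)
    if (!is.null(ev) && all(is.finite(Re(ev$values)))) ok <- TRUE
    else ridge <- if (ridge == 0) 1e-8 * mean(diag(W) + 1e-300) + 1e-12
                  else ridge * 100
  }
  A <- Re(ev$vectors[, seq_len(n_da), drop = FALSE])
  # scale axes to unit pooled within-class variance
  for (a in seq_len(n_da)) {
    wv <- drop(t(A[, a]) %*% (W + diag(ridge, p)) %*% A[, a])
    A[, a] <- A[, a] / sqrt(wv)
    if (A[which.max(abs(A[, a])), a] < 0) A[, a] <- -A[, a]
  }
  Z <- X %*% A
  muZ <- rowsum(Z, labels) / as.vector(table(labels))
  # shared covariance on DA axes (identity by construction up to ridge,
  # recomputed for the posterior model)
  Zc <- Z - muZ[labels, , drop = FALSE]
  S <- crossprod(Zc) / (n - K)
  S <- S + diag(max(1e-12, 1e-10 * mean(diag(S))), n_da)
  Si <- solve(S)
  loglik <- matrix(0, n, K)
  for (k in seq_len(K)) {
    D <- Z - rep(muZ[k, ], each = n)
    loglik[, k] <- -0.5 * rowSums((D %*% Si) * D)
  }
  post <- exp(loglik - apply(loglik, 1, max))
  post <- post / rowSums(post)
  list(axes = A, da_scores = Z, posterior = post,
       hard = max.col(post, ties.method = "first"),
       means = muZ, ridge = ridge)
}

#' End-to-end genetic cluster assignment
#'
#' Composition of [pca_scores()], [find_clusters()] (with [select_k()] when
#' `K` is `NULL`/"auto") and [dapc_fit()]. Returns per-individual posterior
#' membership and hard labels plus all hyperparameters used.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param K number of clusters, or `NULL`/"auto" to select via delta-BIC.
#' @param n_axes PCs computed (default 100).
#' @param n_pc PCs retained in the discriminant step (default `n_axes`).
#' @param n_da discriminant axes (default K - 1).
#' @param k_range,n_iter passed to [find_clusters()].
#' @param seed integer seed.
#' @return An object of class `cluster_assignment`: list with `sample_ids`,
#'   `hard`, `posterior`, `K`, `n_pc`, `n_da`, `bic_profile`.
#' @export
assign_individuals <- function(gm, K = NULL, n_axes = 100, n_pc = n_axes,
                               n_da = NULL, k_range = 1:10, n_iter = 25,
                               seed = NULL) {
  pc <- pca_scores(gm, n_axes = n_axes)
  auto <- is.null(K) || identical(K, "auto")
  prof <- find_clusters(pc$scores, k_range = k_range, n_iter = n_iter,
                        seed = seed)
  if (auto) K <- as.integer(select_k(prof))
  labels <- prof$labels[[match(K, prof$k)]]
  fit <- dapc_fit(pc$scores, labels, n_pc = n_pc, n_da = n_da)
  structure(list(sample_ids = gm$sample_ids, hard = fit$hard,
                 posterior = fit$posterior, K = K,
                 n_pc = min(n_pc, ncol(pc$scores)),
                 n_da = ncol(fit$axes),
                 bic_profile = prof, dapc = fit),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d individuals, K = %d (%d PCs, %d DAs)\n",
              length(x$sample_ids), x$K, x$n_pc, x$n_da))
  print(table(cluster = x$hard))
  invisible(x)
}
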