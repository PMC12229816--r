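#' Oyster condition index
#'
#' 100 x dry tissue mass / dry shell mass; non-positive shell mass yields
#' `NA` with a warning.
#'
#' @param dry_tissue,dry_shell masses in grams.
#' @return Numeric vector.
#' @export
condition_index <- function(dry_tissue, dry_shell) {
  out <- 100 * dry_tissue / dry_shell
  bad <- !is.na(dry_shell) & dry_shell <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive dry shell mass set NA")
    out[bad] <- NA_real_
  }
  out
}

#' Generalized extreme studentized deviate (Rosner) outlier screen
#'
#' Iteratively removes the point with the largest |x - mean|/sd and
#' compares each test statistic R_i to its t-distribution critical value
#' lambda_i; the confirmed outliers are all points up to the largest i
#' with R_i > lambda_i.
#'
#' @param values numeric vector (NAs ignored); `length >= 15` recommended
#'   for the approximation (`min_n` configurable).
#' @param max_outliers maximum number of outliers tested (default 5).
#' @param alpha significance level (default 0.05).
#' @param min_n validity floor on the sample size (default 15).
#' @return Integer indices (into `values`) of confirmed outliers.
#' @export
esd_outliers <- function(values, max_outliers = 5, alpha = 0.05,
                         min_n = 15) {
  idx_all <- which(!is.na(values))
  x <- values[idx_all]
  n <- length(x)
  if (n < min_n) stop_param("need at least ", min_n, " non-missing values")
  live <- seq_len(n)
  cand <- integer(0)
  R <- lambda <- numeric(max_outliers)
  for (i in seq_len(max_outliers)) {
    xi <- x[live]
    s <- stats::sd(xi)
    if (s == 0) { R[i] <- 0 } else {
      dev <- abs(xi - mean(xi))
      j <- which.max(dev)
      R[i] <- dev[j] / s
      cand <- c(cand, live[j])
      live <- live[-j]
    }
    ni <- n - i + 1
    p <- 1 - alpha / (2 * ni)
    t <- stats::qt(p, ni - 2)
    lambda[i] <- (ni - 1) * t / sqrt((ni - 2 + t^2) * ni)
  }
  k <- if (any(R > lambda)) max(which(R > lambda)) else 0
  if (k == 0) integer(0) else idx_all[cand[seq_len(k)]]
}

#' Fixed-effects trait model with restricted permutation inference
#'
#' Fits a cluster x census interaction plus block model for a continuous
#' (Gaussian least squares), binary (logit-binomial) or proportion
#' (logit-beta) response, tests each term with a likelihood-ratio (or F)
#' statistic against a reef-respecting permutation null (response shuffled
#' within reefs for within-reef terms; the reef-to-block map shuffled for
#' the block term), and, for significant cluster terms, reports
#' Tukey-Kramer pairwise contrasts via studentized-range quantiles.
#'
#' @param data data.frame with the response column plus `cluster`,
#'   `census`, `block`, `reef`.
#' @param response name of the response column.
#' @param family "gaussian", "binomial" or "beta".
#' @param n_perm permutations per term (default 199).
#' @param seed integer seed.
#' @param alpha threshold for running post hoc contrasts (default 0.05).
#' @return list(tests = per-term [test_result()], tukey = pairwise cluster
#'   contrasts or NULL, fit = the full-model fit).
#' @export
cluster_trait_test <- function(data, response,
                               family = c("gaussian", "binomial", "beta"),
                               n_perm = 199, seed = NULL, alpha = 0.05) {
  family <- match.arg(family)
  d <- as.data.frame(data)
  d <- d[!is.na(d[[response]]), , drop = FALSE]
  d$y <- d[[response]]
  one_census <- length(unique(d$census)) < 2
  full_f <- if (one_census) y ~ factor(cluster) + factor(block)
            else y ~ factor(cluster) * factor(census) + factor(block)
  main_f <- y ~ factor(cluster) + factor(census) + factor(block)
  reduced <- if (one_census)
    list(cluster = y ~ factor(block),
         block = y ~ factor(cluster))
  else
    list(`cluster:census` = main_f,
         cluster = y ~ factor(census) + factor(block),
         census = y ~ factor(cluster) + factor(block),
         block = y ~ factor(cluster) * factor(census))
  fit_fun <- switch(family,
    gaussian = function(f, dd) {
      m <- stats::lm(f, dd)
      list(loglik = as.numeric(stats::logLik(m)), k = m$rank, fit = m)
    },
    binomial = function(f, dd) {
      m <- suppressWarnings(stats::glm(f, stats::binomial(), dd))
      list(loglik = as.numeric(stats::logLik(m)), k = m$rank, fit = m)
    },
    beta = function(f, dd) {
      m <- beta_regression(f, dd)
      list(loglik = m$loglik, k = ncol(m$X), fit = m)
    })
  lrt_stat <- function(dd, term) {
    base_f <- if (term %in% c("cluster:census") || one_census) full_f
              else main_f
    f1 <- fit_fun(base_f, dd); f0 <- fit_fun(reduced[[term]], dd)
    max(0, 2 * (f1$loglik - f0$loglik))
  }
  terms <- names(reduced)
  tests <- vector("list", length(terms)); names(tests) <- terms
  base_seed <- if (is.null(seed)) sample.int(2^30, 1) else seed
  for (ti in seq_along(terms)) {
    term <- terms[ti]
    obs <- lrt_stat(d, term)
    ge <- 0L
    with_seed(derive_seed(base_seed, 100L + ti), {
      for (b in seq_len(n_perm)) {
        dd <- d
        if (term == "block") {
          map <- tapply(d$block, d$reef, `[`, 1)
          map <- stats::setNames(sample(map), names(map))
          dd$block <- map[as.character(dd$reef)]
        } else {
          for (r in unique(d$reef)) {
            i <- which(d$reef == r)
            dd$y[i] <- d$y[i][sample.int(length(i))]
          }
        }
        if (lrt_stat(dd, term) >= obs) ge <- ge + 1L
      }
    })
    tests[[ti]] <- test_result(paste0("perm_", family, "_", term),
                               statistic = obs,
                               p_value = (ge + 1) / (n_perm + 1),
                               n_permutations = as.integer(n_perm))
  }
  tukey <- NULL
  if (!is.null(tests$cluster) && !is.na(tests$cluster$p_value) &&
      tests$cluster$p_value <= alpha)
    tukey <- tukey_kramer(d$y, d$cluster)
  list(tests = tests, tukey = tukey, fit = fit_fun(full_f, d)$fit)
}

#' Tukey-Kramer pairwise contrasts
#'
#' All pairwise group-mean differences with studentized-range p-values
#' using the Kramer unequal-n standard error.
#'
#' @param y response vector.
#' @param group group labels.
#' @return data.frame of contrasts (estimate, se, q, p_value).
#' @export
tukey_kramer <- function(y, group) {
  group <- factor(group)
  K <- nlevels(group)
  ns <- as.vector(table(group))
  ms <- tapply(y, group, mean)
  df <- length(y) - K
  mse <- sum((y - ms[as.integer(group)])^2) / df
  out <- NULL
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(ms[i] - ms[j]) / se
    out <- rbind(out, data.frame(
      contrast = paste(levels(group)[i], "-", levels(group)[j]),
      estimate = unname(ms[i] - ms[j]), se = se, q = q,
      p_value = stats::ptukey(q, K, df, lower.tail = FALSE),
      stringsAsFactors = FALSE))
  }
  out
}

#' Correlation-based predictor pruning
#'
#' Iteratively removes one member of every trait pair whose rank (or
#' Pearson) correlation exceeds `rho_max` in magnitude and is significant
#' at `alpha`: the member with the larger mean absolute correlation to all
#' other traits is dropped (ties: the later column), until no violating
#' pair remains.
#'
#' @param trait_matrix numeric matrix/data.frame of candidate predictors.
#' @param rho_max threshold (default 0.7).
#' @param method "spearman" (default) or "pearson".
#' @param alpha significance level for the correlation test (default 0.05).
#' @return Character vector of retained column names.
#' @export
correlation_prune <- function(trait_matrix, rho_max = 0.7,
                              method = c("spearman", "pearson"),
                              alpha = 0.05) {
  method <- match.arg(method)
  X <- as.data.frame(trait_matrix)
  if (ncol(X) < 2) stop_param("need at least two traits")
  keep <- names(X)
  repeat {
    if (length(keep) < 2) break
    C <- suppressWarnings(
      stats::cor(X[keep], use = "pairwise.complete.obs", method = method))
    diag(C) <- 0
    viol <- which(abs(C) > rho_max, arr.ind = TRUE)
    viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
    if (nrow(viol)) {
      sig <- vapply(seq_len(nrow(viol)), function(k) {
        ct <- suppressWarnings(
          stats::cor.test(X[[keep[viol[k, 1]]]], X[[keep[viol[k, 2]]]],
                          method = method, exact = FALSE))
        ct$p.value < alpha
      }, logical(1))
      viol <- viol[sig, , drop = FALSE]
    }
    if (!nrow(viol)) break
    # worst pair first
    worst <- viol[which.max(abs(C[viol])), ]
    cand <- keep[c(worst[1], worst[2])]
    mean_abs <- colMeans(abs(C[, cand, drop = FALSE]))
    drop <- if (abs(diff(mean_abs)) > 1e-12) cand[which.max(mean_abs)]
            else cand[2]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Cluster-by-reef shift-regression table
#'
#' Builds the analysis grain of the trait-to-mortality regression: one row
#' per cluster x mixed reef with the change in the cluster's relative
#' frequency between the two censuses (`delta_freq`) and census-1 trait
#' means.
#'
#' @param records long records table with `reef`, `census`, a cluster
#'   column and `sample_id`.
#' @param traits trait table with `sample_id`, `census` and trait columns.
#' @param trait_cols trait columns to average (default: size, mass and
#'   condition traits present in the table).
#' @param cluster_col name of the cluster column in `records` (default
#'   "source", the generator's truth label; use "cluster" for inferred
#'   labels).
#' @param min_n minimum census-1 group size (default 2).
#' @return data.frame with `cluster`, `reef`, `delta_freq` and one column
#'   per trait mean.
#' @export
cluster_reef_shift_data <- function(records, traits,
                                    trait_cols = c("condition_index",
                                                   "shell_height",
                                                   "shell_length",
                                                   "dry_tissue_mass"),
                                    cluster_col = "source", min_n = 2) {
  rec <- as.data.frame(records)
  rec$cluster <- rec[[cluster_col]]
  c1 <- rec[rec$census == 1, ]
  c2 <- rec[rec$census == 2, ]
  mixed <- names(which(tapply(c1$cluster, c1$reef,
                              function(x) length(unique(x)) > 1)))
  trait_cols <- intersect(trait_cols, names(traits))
  t1 <- traits[traits$census == 1, ]
  out <- NULL
  for (r in mixed) {
    d1 <- c1[c1$reef == r, ]; d2 <- c2[c2$reef == r, ]
    for (k in sort(unique(d1$cluster))) {
      n1 <- sum(d1$cluster == k)
      if (n1 < min_n || nrow(d2) == 0) next
      delta <- mean(d2$cluster == k) - n1 / nrow(d1)
      ids <- d1$sample_id[d1$cluster == k]
      tm <- colMeans(t1[t1$sample_id %in% ids, trait_cols, drop = FALSE],
                     na.rm = TRUE)
      out <- rbind(out, data.frame(cluster = k, reef = r,
                                   delta_freq = delta, t(tm)))
    }
  }
  out
}

#' Trait-to-mortality multiple regression with influence diagnostics
#'
#' Ordinary least squares of the change in reef-level cluster frequency on
#' z-standardized cluster-by-reef trait means. Reports standardized
#' coefficients, dfbetas per observation and coefficient, observations
#' exceeding the influence rule (both the fit with and without them), and
#' added-variable (partial regression) data per trait.
#'
#' @param data data.frame: response column plus trait columns.
#' @param response name of the response column (default "delta_freq").
#' @param traits character vector of predictor columns (default all
#'   others).
#' @param dfbeta_rule "sd" (exclude observations with |dfbetas| beyond one
#'   standard deviation of that coefficient's dfbetas distribution,
#'   replica of the field protocol) or "2/sqrt(n)" (conventional size-
#'   adjusted cutoff).
#' @return Object of class `shift_regression`: list with `fit`,
#'   `coefficients` (data.frame), `dfbetas`, `excluded`, `refit`,
#'   `refit_coefficients`, `added_variable` (list of data.frames).
#' @export
shift_regression <- function(data, response = "delta_freq", traits = NULL,
                             dfbeta_rule = c("sd", "2/sqrt(n)")) {
  dfbeta_rule <- match.arg(dfbeta_rule)
  d <- as.data.frame(data)
  if (is.null(traits)) traits <- setdiff(names(d), response)
  d <- d[stats::complete.cases(d[c(response, traits)]), , drop = FALSE]
  n <- nrow(d); p <- length(traits)
  if (p >= n) stop_param("more predictors than observations")
  Z <- scale(as.matrix(d[traits]))
  dd <- data.frame(y = d[[response]], Z)
  fml <- stats::reformulate(traits, response = "y")
  fit <- stats::lm(fml, dd)
  coef_tab <- function(m) {
    s <- summary(m)$coefficients
    data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
               t = s[, 3], p_value = s[, 4], row.names = NULL,
               stringsAsFactors = FALSE)
  }
  dfb <- stats::dfbetas(fit)[, -1, drop = FALSE]  # drop intercept column
  cut <- switch(dfbeta_rule,
                "sd" = apply(dfb, 2, stats::sd),
                "2/sqrt(n)" = rep(2 / sqrt(n), p))
  excluded <- which(rowSums(abs(dfb) > rep(cut, each = n)) > 0)
  refit <- NULL; refit_tab <- NULL
  if (length(excluded) && length(excluded) < n - p - 1) {
    refit <- stats::lm(fml, dd[-excluded, , drop = FALSE])
    refit_tab <- coef_tab(refit)
  }
  av <- lapply(traits, function(tr) {
    others <- setdiff(traits, tr)
    f_y <- if (length(others)) stats::reformulate(others, "y") else y ~ 1
    f_x <- if (length(others)) stats::reformulate(others, tr)
           else stats::reformulate("1", tr)
    data.frame(x_resid = stats::resid(stats::lm(f_x, dd)),
               y_resid = stats::resid(stats::lm(f_y, dd)))
  })
  names(av) <- traits
  structure(list(fit = fit, coefficients = coef_tab(fit), dfbetas = dfb,
                 dfbeta_rule = dfbeta_rule, excluded = excluded,
                 refit = refit, refit_coefficients = refit_tab,
                 added_variable = av, n = n, traits = traits),
            class = "shift_regression")
}

#' @export
print.shift_regression <- function(x, ...) {
  cat(sprintf("shift_regression: n = %d, %d traits, %d excluded (%s rule)\n",
              x$n, length(x$traits), length(x$excluded), x$dfbeta_rule))
  print(x$coefficients, digits = 3)
  invisible(x)
}
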