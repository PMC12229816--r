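#' Min-max squeeze of a metric into (0, 1)
#'
#' x' = (x - min + eps) / (max - min + 2 eps) with eps = 0.5/n; strictly
#' monotone, maps the observed range into the open unit interval so that
#' unbounded metrics can enter a beta-regression likelihood.
#'
#' @param x numeric vector.
#' @param eps squeeze margin (default `0.5 / length(x)`).
#' @return Transformed vector.
#' @export
squeeze_unit <- function(x, eps = 0.5 / length(x)) {
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0) return(rep(0.5, length(x)))
  (x - rng[1] + eps) / (diff(rng) + 2 * eps)
}

# Beta log-likelihood, mean-precision parametrization.
beta_loglik <- function(y, mu, phi) {
  sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

#' Beta regression with logit link (maximum likelihood)
#'
#' y ~ Beta(mu phi, (1 - mu) phi) with logit(mu) = X beta and precision
#' phi > 0 (log-parametrized), fit by BFGS from a logit-least-squares warm
#' start.
#'
#' @param formula model formula; the response must lie strictly in (0, 1)
#'   (use [squeeze_unit()] first if needed).
#' @param data data.frame.
#' @return Object of class `beta_fit`: coefficients, `phi`, `loglik`,
#'   `vcov`, `converged`.
#' @export
beta_regression <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y <= 0 | y >= 1)) stop_param("response must be strictly in (0,1)")
  X <- stats::model.matrix(formula, mf)
  warm <- stats::lm.fit(X, stats::qlogis(y))$coefficients
  warm[!is.finite(warm)] <- 0
  start <- c(warm, log(5))
  negll <- function(theta) {
    beta <- theta[-length(theta)]
    phi <- exp(theta[length(theta)])
    mu <- stats::plogis(drop(X %*% beta))
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    -beta_loglik(y, mu, min(phi, 1e8))
  }
  opt <- stats::optim(start, negll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  p <- ncol(X)
  V <- tryCatch(solve(opt$hessian), error = function(e)
    matrix(NA_real_, p + 1, p + 1))
  structure(list(coefficients = stats::setNames(opt$par[seq_len(p)],
                                                colnames(X)),
                 phi = exp(opt$par[p + 1]), loglik = -opt$value,
                 vcov = V[seq_len(p), seq_len(p), drop = FALSE],
                 converged = opt$convergence == 0,
                 formula = formula, X = X, y = y),
            class = "beta_fit")
}

# LRT between nested beta fits.
beta_lrt <- function(full, reduced) {
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- ncol(full$X) - ncol(reduced$X)
  test_result("lrt_beta", statistic = stat, df = df,
              p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Diversity trajectories across censuses with permutation inference
#'
#' Fits a beta regression (logit link) of a per-group diversity metric on
#' cluster, census, their interaction and block, after squeezing the
#' metric into (0, 1). Each fixed term is tested by a likelihood-ratio
#' statistic whose null distribution permutes the metric within reefs
#' (cluster/census/interaction terms) or permutes whole reefs across
#' blocks (block term), respecting the grouping structure instead of a
#' random reef intercept.
#'
#' @param records data.frame with columns `metric`, `cluster`, `census`,
#'   `block`, `reef` (one row per cluster x reef x census group).
#' @param n_perm permutations per term (default 199).
#' @param seed integer seed.
#' @return list(fit, tests = named list of [test_result()] per term).
#' @export
diversity_trajectory <- function(records, n_perm = 199, seed = NULL) {
  d <- as.data.frame(records)
  if (length(unique(d$census)) < 2) stop_param("need records for >= 2 censuses")
  d$y <- squeeze_unit(d$metric)
  full_f <- y ~ factor(cluster) * factor(census) + factor(block)
  drop_f <- list(
    `cluster:census` = y ~ factor(cluster) + factor(census) + factor(block),
    cluster = y ~ factor(census) + factor(block),
    census = y ~ factor(cluster) + factor(block),
    block = y ~ factor(cluster) * factor(census))
  # reduced models for main effects exclude the interaction (marginality)
  main_f <- y ~ factor(cluster) + factor(census) + factor(block)
  fit_full <- beta_regression(full_f, d)
  obs_stat <- function(dd, term) {
    if (term == "cluster:census")
      beta_lrt(beta_regression(full_f, dd),
               beta_regression(drop_f[[term]], dd))$statistic
    else
      beta_lrt(beta_regression(main_f, dd),
               beta_regression(drop_f[[term]], dd))$statistic
  }
  terms <- names(drop_f)
  tests <- vector("list", length(terms))
  names(tests) <- terms
  base_seed <- if (is.null(seed)) sample.int(2^30, 1) else seed
  for (ti in seq_along(terms)) {
    term <- terms[ti]
    obs <- obs_stat(d, term)
    ge <- 0L
    with_seed(derive_seed(base_seed, ti), {
      for (b in seq_len(n_perm)) {
        dd <- d
        if (term == "block") {
          # permute the reef -> block assignment wholesale
          map <- tapply(d$block, d$reef, `[`, 1)
          map <- stats::setNames(sample(map), names(map))
          dd$block <- map[as.character(dd$reef)]
        } else {
          for (r in unique(d$reef)) {
            i <- which(d$reef == r)
            dd$y[i] <- d$y[i][sample.int(length(i))]
          }
        }
        if (obs_stat(dd, term) >= obs) ge <- ge + 1L
      }
    })
    tests[[ti]] <- test_result(paste0("perm_lrt_", term), statistic = obs,
                               p_value = (ge + 1) / (n_perm + 1),
                               n_permutations = as.integer(n_perm))
  }
  list(fit = fit_full, tests = tests)
}
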