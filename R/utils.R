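#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a deterministic RNG state, restoring the caller's
# stream afterwards so package functions never perturb user-level RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Fan a single global seed out into per-stage sub-seeds. Multiplier and
# modulus keep every derived seed a valid positive 32-bit integer.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(offset)) %% 2147483587) + 1L
}

stop_param <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  bad <- !is.finite(x) |
    (if (open_left) x <= 0 else x < 0) |
    (if (open_right) x >= 1 else x > 1)
  if (any(bad)) stop_param(name, " must lie in ", if (open_left) "(" else "[",
                           "0,1", if (open_right) ")" else "]")
  invisible(x)
}

#' Construct a shared hypothesis-test result record
#'
#' All inferential routines in the package return (lists of) this record so
#' that downstream tables carry a uniform contract: a method tag, the test
#' statistic, degrees of freedom where defined, the p-value, and optional
#' adjusted p-value, permutation count and estimate with standard error.
#'
#' @param method character tag identifying the procedure.
#' @param statistic numeric test statistic.
#' @param df degrees of freedom, or `NA` where undefined.
#' @param p_value p-value in \[0, 1\].
#' @param adjusted_p multiplicity-adjusted p-value (optional).
#' @param n_permutations number of permutations used (optional).
#' @param estimate,se point estimate and standard error (optional).
#' @param ... additional named fields carried through unchanged.
#' @return An object of class `test_result` (a named list).
#' @export
test_result <- function(method, statistic, df = NA_real_, p_value,
                        adjusted_p = NA_real_, n_permutations = NA_integer_,
                        estimate = NA_real_, se = NA_real_, ...) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop_param("p_value outside [0,1]")
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, adjusted_p = adjusted_p,
                 n_permutations = n_permutations,
                 estimate = estimate, se = se, ...),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> stat = %.4g", x$method, x$statistic))
  if (!is.na(x$df)) cat(sprintf(", df = %s", format(x$df)))
  cat(sprintf(", p = %.4g", x$p_value))
  if (!is.na(x$adjusted_p)) cat(sprintf(", p.adj = %.4g", x$adjusted_p))
  cat("\n")
  invisible(x)
}

# Convert a list of test_result records to a data.frame.
#' Tabulate a list of test results
#' @param results list of `test_result` objects.
#' @return data.frame with one row per result.
#' @export
results_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(method = r$method, statistic = r$statistic, df = r$df,
               p_value = r$p_value, adjusted_p = r$adjusted_p,
               estimate = r$estimate, se = r$se,
               stringsAsFactors = FALSE)
  }))
}
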