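# MCMC convergence diagnostics: Gelman-Rubin potential scale reduction and
# the acceptance gate used to reject unconverged model output.

#' Gelman-Rubin potential scale reduction factor
#'
#' Classical PSRF from between-chain (B) and within-chain (W) variances:
#' `Rhat = sqrt(((n-1)/n W + B/n) / W)` with `n` draws per chain. For two
#' identical chains B = 0 and `Rhat = sqrt((n-1)/n) <= 1`.
#'
#' @param draws numeric matrix (draws x parameters) or a `posterior_draws`
#'   object (all proportion components and residual SDs are monitored).
#' @param chain integer vector assigning each draw row to a chain (ignored
#'   for `posterior_draws` input, which carries its own).
#' @return named numeric vector of Rhat values.
#' @export
gelman_rubin <- function(draws, chain = NULL) {
  if (inherits(draws, "posterior_draws")) {
    chain <- draws$chain
    draws <- draws_matrix(draws)
  }
  draws <- as.matrix(draws)
  stopifnot(!is.null(chain), length(chain) == nrow(draws))
  chains <- unique(chain)
  m <- length(chains)
  if (m < 2) stop("Gelman-Rubin needs at least 2 chains", call. = FALSE)
  n <- min(table(chain))
  if (n < 2) stop("need at least 2 draws per chain", call. = FALSE)
  apply(draws, 2, function(x) {
    per <- lapply(chains, function(ch) head(x[chain == ch], n))
    means <- vapply(per, mean, 0)
    W <- mean(vapply(per, var, 0))
    B <- n * var(means)
    if (W == 0) return(if (B == 0) sqrt((n - 1) / n) else Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
}

#' Convergence gate on Gelman-Rubin diagnostics
#'
#' Model output is rejected if more than `max_frac` (default 5%) of the
#' monitored variables have `Rhat` above `limit` (default 1.05).
#'
#' @param rhat numeric vector of Rhat values.
#' @param limit Rhat threshold per variable.
#' @param max_frac maximum tolerated fraction of variables above `limit`.
#' @return list of class `convergence_report`: `pass`, `fraction`,
#'   `n_above`, `n_total`, `rhat`.
#' @export
check_convergence <- function(rhat, limit = 1.05, max_frac = 0.05) {
  stopifnot(length(rhat) >= 1)
  n_above <- sum(rhat > limit)
  fraction <- n_above / length(rhat)
  structure(list(pass = !(fraction > max_frac), fraction = fraction,
                 n_above = n_above, n_total = length(rhat),
                 limit = limit, max_frac = max_frac, rhat = rhat),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence: %s (%d/%d variables with Rhat > %.2f, max Rhat %.3f)\n",
              if (x$pass) "PASS" else "FAIL", x$n_above, x$n_total,
              x$limit, max(x$rhat)))
  invisible(x)
}
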