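# User-facing fitting interface: mixfit() fits one node's mixing model and
# packages draws, diagnostics and the spec into a classed object.

#' Fit a Bayesian mixing model for one node
#'
#' Unmixes a node's sediment-mixture tracer values against its source
#' groups: per factor level, a Dirichlet-prior proportion simplex; normal
#' likelihood around the concentration-weighted combination of source means;
#' residual (default) or process error; source mean/SD uncertainty
#' propagated by redrawing them each iteration from their closed-form
#' posteriors. Sampling is by adaptive random-walk Metropolis in isometric
#' log-ratio coordinates; convergence is gated on the Gelman-Rubin
#' diagnostic (fail if more than 5% of monitored variables exceed 1.05).
#'
#' @param mixtures a [tracer_table()].
#' @param sources a [source_set()] (>= 2 groups).
#' @param tracers tracer panel; default: tracers shared by mixtures and
#'   sources (after any screening).
#' @param alpha Dirichlet hyperparameters (scalar, vector, or named by
#'   group); all 1 is uninformative.
#' @param error `"residual"` or `"process"`.
#' @param concentration optional K x J concentration matrix.
#' @param mcmc an [mcmc_settings()].
#' @param seed master seed.
#' @param source_fit `"draw"` or `"plugin"`.
#' @param tau_max optional residual-SD prior upper bound (scalar or per
#'   tracer); default 10 x empirical mixture SD.
#' @return object of class `mixfit`: `draws` (a `posterior_draws`), `rhat`,
#'   `convergence` (a `convergence_report`), `spec`, `settings`, `seed`.
#' @examples
#' truth <- truth_spec(make_topology("simple"),
#'                     proportions = list(M = c(A = 0.6, B = 0.3, C = 0.1)),
#'                     seed = 7)
#' dat <- simulate_watershed(truth)
#' fit <- mixfit(dat$mixtures$M, dat$sources$M,
#'               mcmc = mcmc_settings(4000, 2000, 2, 3), seed = 7)
#' coef(fit)
#' @export
mixfit <- function(mixtures, sources, tracers = NULL, alpha = 1,
                   error = c("residual", "process"), concentration = NULL,
                   mcmc = mcmc_settings(), seed = 1,
                   source_fit = c("draw", "plugin"), tau_max = NULL) {
  stopifnot(inherits(mixtures, "tracer_table"), inherits(sources, "source_set"))
  if (is.null(tracers)) tracers <- intersect(mixtures$tracers, sources$tracers)
  spec <- node_model_spec(sources, tracers = tracers,
                          levels = mixtures$levels, alpha = alpha,
                          error = match.arg(error),
                          concentration = concentration, tau_max = tau_max,
                          source_fit = match.arg(source_fit),
                          node = mixtures$node)
  draws <- run_mcmc(spec, mixtures, settings = mcmc, seed = seed)
  rhat <- gelman_rubin(draws)
  conv <- check_convergence(rhat)
  if (!conv$pass) {
    warning("node ", spec$node, ": convergence gate failed (",
            conv$n_above, "/", conv$n_total, " variables with Rhat > ",
            conv$limit, ")", call. = FALSE)
  }
  structure(list(draws = draws, rhat = rhat, convergence = conv,
                 spec = spec, settings = mcmc, seed = seed,
                 mixtures = mixtures),
            class = "mixfit")
}

#' @export
print.mixfit <- function(x, ...) {
  cat("Bayesian mixing model fit - node", x$spec$node, "\n")
  cat(sprintf("  %d sources, %d tracers, %d level(s); error = %s; %d draws\n",
              length(x$spec$sources), length(x$spec$tracers),
              length(x$spec$levels), x$spec$error, dim(x$draws$p)[1]))
  print(x$convergence)
  cat("Posterior mean proportions:\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
summary.mixfit <- function(object, ...) {
  out <- summary(object$draws)
  attr(out, "convergence") <- object$convergence
  out
}

#' Posterior mean proportions
#' @param object a `mixfit`.
#' @param ... unused.
#' @return L x K matrix (levels x sources) of posterior means.
#' @export
coef.mixfit <- function(object, ...) {
  t(apply(object$draws$p, c(2, 3), mean))
}

#' Boxplot of posterior proportion draws
#' @param x a `mixfit`.
#' @param level factor level to plot (default: first).
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.mixfit <- function(x, level = x$draws$levels[1], ...) {
  l <- match(level, x$draws$levels)
  m <- x$draws$p[, , l, drop = FALSE]
  dim(m) <- dim(x$draws$p)[1:2]
  colnames(m) <- x$draws$sources
  graphics::boxplot(as.data.frame(m), ylab = "proportion",
                    main = paste("Node", x$spec$node, "-", level), ...)
  invisible(x)
}

#' Simulate mixture data from the fitted model
#'
#' Draws replicate mixture tables from the posterior predictive: for each
#' requested replicate a retained draw (p, tau) is picked and mixture values
#' are generated as normal around the implied mixture mean.
#'
#' @param object a `mixfit`.
#' @param nsim number of replicate tables.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of data.frames shaped like the observed mixture data.
#' @export
simulate.mixfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  spec <- object$spec
  md <- mix_data_matrix(spec, object$mixtures)
  K <- length(spec$sources); J <- length(spec$tracers)
  conc <- if (is.null(spec$concentration)) matrix(1, K, J)
          else spec$concentration
  T_n <- dim(object$draws$p)[1]
  reps <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    t <- sample.int(T_n, 1)
    Y <- md$Y
    for (i in seq_len(nrow(Y))) {
      l <- md$lev[i]
      pp <- apply_concentration(object$draws$p[t, , l], conc)
      m <- mixture_mean(pp, spec$summaries$mean)
      sdv <- if (spec$error == "residual") object$draws$tau[t, ]
             else sqrt(colSums(pp^2 * spec$summaries$sd^2))
      Y[i, ] <- rnorm(J, m, sdv)
    }
    reps[[r]] <- as.data.frame(Y)
  }
  reps
}

#' Residuals of the fitted mixing model
#'
#' Observed mixture values minus the posterior-mean predicted mixture
#' signature for the sample's factor level.
#'
#' @param object a `mixfit`.
#' @param ... unused.
#' @return N x J matrix of residuals.
#' @export
residuals.mixfit <- function(object, ...) {
  spec <- object$spec
  md <- mix_data_matrix(spec, object$mixtures)
  K <- length(spec$sources); J <- length(spec$tracers)
  conc <- if (is.null(spec$concentration)) matrix(1, K, J)
          else spec$concentration
  pbar <- coef(object)
  R <- md$Y
  for (i in seq_len(nrow(R))) {
    pp <- apply_concentration(pbar[md$lev[i], ], conc)
    R[i, ] <- md$Y[i, ] - mixture_mean(pp, spec$summaries$mean)
  }
  R
}
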