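# Per-node Bayesian mixing model: model spec, priors, log posterior
# (reference R implementation), MCMC driver around the C++ sampler.

#' Draw source parameters from their closed-form posterior
#'
#' Given a group's per-tracer summary (sample mean, SD, n), draws the source
#' SD from the scaled inverse-chi-squared posterior with `n - 1` degrees of
#' freedom and scale `s^2`, then the source mean from a normal with mean
#' `xbar` and variance `sigma^2 / n` (the standard noninformative prior
#' `p(mu, sigma^2) ~ 1/sigma^2`). With `plugin = TRUE` the empirical values
#' are returned deterministically. Tracers with `s = 0` always return the
#' plug-in values.
#'
#' @param mean,sd numeric vectors (per tracer): sample mean and SD.
#' @param n sample size (scalar, >= 2).
#' @param plugin if TRUE, return `(mean, sd)` exactly.
#' @return list with numeric vectors `mu` and `sigma`.
#' @export
source_param_draw <- function(mean, sd, n, plugin = FALSE) {
  stopifnot(length(mean) == length(sd), all(sd >= 0))
  if (n < 2) stop("source group needs n >= 2", call. = FALSE)
  if (plugin) return(list(mu = mean, sigma = sd))
  J <- length(mean)
  sig2 <- ifelse(sd > 0, (n - 1) * sd^2 / rchisq(J, df = n - 1), 0)
  mu <- ifelse(sd > 0, rnorm(J, mean, sqrt(sig2 / n)), mean)
  list(mu = mu, sigma = sqrt(sig2))
}

#' Concentration-dependent proportion adjustment
#'
#' Re-weights mass proportions by per-source tracer concentration:
#' `p'_kj = p_k c_kj / sum_l p_l c_lj`, so that for each tracer the adjusted
#' proportions again sum to one.
#'
#' @param p proportion vector on the simplex (length K).
#' @param conc K x J matrix of strictly positive concentrations (or a
#'   length-K vector for a single tracer).
#' @return K x J matrix of adjusted proportions.
#' @export
apply_concentration <- function(p, conc) {
  if (is.vector(conc)) conc <- matrix(conc, ncol = 1)
  stopifnot(length(p) == nrow(conc))
  if (any(conc <= 0)) stop("concentrations must be strictly positive",
                           call. = FALSE)
  w <- p * conc
  sweep(w, 2, colSums(w), "/")
}

#' Mixture mean per tracer
#'
#' `m_j = sum_k p'_kj mu_kj`: the expected mixture signature as the
#' concentration-weighted combination of source means.
#'
#' @param pprime K x J adjusted proportions (from [apply_concentration()]),
#'   or a length-K proportion vector (recycled across tracers).
#' @param mu K x J matrix of source means.
#' @return numeric vector of length J.
#' @export
mixture_mean <- function(pprime, mu) {
  if (is.vector(pprime)) pprime <- matrix(pprime, nrow = length(pprime),
                                          ncol = ncol(mu))
  stopifnot(all(dim(pprime) == dim(mu)))
  colSums(pprime * mu)
}

#' Build a node model specification
#'
#' Collects everything the sampler needs for one node: source summaries,
#' tracer panel, factor levels, Dirichlet prior, error model, concentration
#' table and residual-SD prior bound.
#'
#' @param sources a [source_set()] (>= 2 groups).
#' @param tracers tracer panel (default: the source panel).
#' @param levels factor levels (default `"all"`).
#' @param alpha Dirichlet hyperparameters: scalar (recycled) or vector of
#'   length K, optionally named by group. All 1 is the uninformative prior;
#'   a small value (e.g. 0.01 for channel banks) encodes prior belief in a
#'   minor contribution.
#' @param error `"residual"` (per-tracer residual SD tau_j) or `"process"`
#'   (SD propagated from source variances).
#' @param concentration K x J matrix, or NULL for concentration-independent.
#' @param tau_max upper bound of the uniform prior on tau_j; default is set
#'   from the mixture data at fit time (10 x the empirical SD per tracer).
#' @param source_fit `"draw"` (refresh source parameters from their posterior
#'   each iteration) or `"plugin"` (fix at empirical mean/SD).
#' @param node node label.
#' @return object of class `node_model_spec`.
#' @export
node_model_spec <- function(sources, tracers = NULL, levels = "all",
                            alpha = 1, error = c("residual", "process"),
                            concentration = NULL, tau_max = NULL,
                            source_fit = c("draw", "plugin"), node = NULL) {
  error <- match.arg(error)
  source_fit <- match.arg(source_fit)
  stopifnot(inherits(sources, "source_set"))
  K <- length(sources$groups)
  if (K < 2) stop("need at least 2 source groups to unmix", call. = FALSE)
  if (is.null(tracers)) tracers <- sources$tracers
  if (!all(tracers %in% sources$tracers)) {
    stop("tracer panel not covered by sources: ",
         paste(setdiff(tracers, sources$tracers), collapse = ", "),
         call. = FALSE)
  }
  gnames <- names(sources$groups)
  if (length(alpha) == 1) alpha <- rep(alpha, K)
  if (!is.null(names(alpha))) {
    full <- setNames(rep(1, K), gnames)
    full[intersect(names(alpha), gnames)] <-
      alpha[intersect(names(alpha), gnames)]
    alpha <- full
  }
  stopifnot(length(alpha) == K, all(alpha > 0))
  if (!is.null(concentration)) {
    if (is.null(rownames(concentration))) rownames(concentration) <- gnames
    concentration <- concentration[gnames, tracers, drop = FALSE]
    if (any(concentration <= 0)) {
      stop("concentrations must be strictly positive", call. = FALSE)
    }
  }
  ss <- source_summaries(sources, tracers)
  if (error == "process" && any(colSums(ss$sd > 0) == 0)) {
    stop("process error needs positive source variance in some group for ",
         "every tracer", call. = FALSE)
  }
  structure(list(node = if (is.null(node)) sources$node else node,
                 sources = gnames, classes = sources$classes,
                 tracers = tracers, levels = levels,
                 alpha = setNames(as.numeric(alpha), gnames),
                 error = error, concentration = concentration,
                 tau_max = tau_max, source_fit = source_fit,
                 summaries = ss),
            class = "node_model_spec")
}

# Mixture data matrix + level index for the sampler. data may be NULL
# (prior-only run).
mix_data_matrix <- function(spec, data) {
  if (is.null(data)) {
    Y <- matrix(numeric(0), 0, length(spec$tracers))
    lev <- integer(0)
  } else {
    stopifnot(inherits(data, "tracer_table"))
    miss <- setdiff(spec$tracers, data$tracers)
    if (length(miss) > 0) {
      stop("mixture table lacks panel tracer(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    Y <- as.matrix(data$data[spec$tracers])
    if (any(!is.finite(Y))) stop("non-finite mixture values", call. = FALSE)
    lev <- match(data$data$.level, spec$levels)
    if (anyNA(lev)) {
      stop("mixture has factor level(s) outside the spec: ",
           paste(unique(data$data$.level[is.na(lev)]), collapse = ", "),
           call. = FALSE)
    }
  }
  list(Y = Y, lev = lev)
}

# Default residual-SD prior bound: 10 x empirical SD per tracer, falling
# back to a scale-aware constant when fewer than 2 mixture samples exist.
default_tau_max <- function(Y) {
  if (nrow(Y) >= 2) {
    s <- apply(Y, 2, sd)
    s[s == 0] <- pmax(abs(colMeans(Y))[s == 0], 1)
    10 * s
  } else if (nrow(Y) == 1) {
    pmax(abs(Y[1, ]), 1)
  } else {
    rep(1, ncol(Y))
  }
}

#' Log posterior density of the mixing model (reference implementation)
#'
#' Direct R evaluation of the unnormalised log posterior used by the
#' sampler: normal likelihood of the mixture values around the
#' concentration-weighted combination of source means, with per-tracer
#' residual SD (`error = "residual"`) or source-variance-propagated SD
#' (`error = "process"`), plus the Dirichlet prior on each factor level's
#' proportions and a uniform prior on each tau. Densities are over (p, tau)
#' directly (no transform Jacobians), so it serves as an independent oracle
#' for grid integration.
#'
#' @param state list with `p` (L x K matrix of proportions, rows on the
#'   simplex; or a vector for one level) and `tau` (length-J vector,
#'   required for residual error).
#' @param data a [tracer_table()] or NULL.
#' @param spec a [node_model_spec()].
#' @param source_params list with `mu`, `sigma` (K x J), e.g. the plug-in
#'   summaries; default: plug-in empirical values.
#' @return scalar log density (can be `-Inf` outside the support).
#' @export
log_posterior <- function(state, data, spec, source_params = NULL) {
  stopifnot(inherits(spec, "node_model_spec"))
  K <- length(spec$sources)
  J <- length(spec$tracers)
  p <- state$p
  if (is.vector(p)) p <- matrix(p, 1)
  L <- nrow(p)
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-9)) return(-Inf)
  if (is.null(source_params)) {
    source_params <- list(mu = spec$summaries$mean, sigma = spec$summaries$sd)
  }
  md <- mix_data_matrix(spec, data)
  conc <- if (is.null(spec$concentration)) matrix(1, K, J)
          else spec$concentration
  tau_max <- spec$tau_max
  if (is.null(tau_max)) tau_max <- default_tau_max(md$Y)
  lp <- sum((rep(spec$alpha, each = L) - 1) * log(pmax(p, 1e-300)))
  if (spec$error == "residual") {
    tau <- state$tau
    stopifnot(length(tau) == J)
    if (any(tau <= 0) || any(tau >= tau_max)) return(-Inf)
  }
  m <- array(NA_real_, c(L, J))
  s2 <- array(0, c(L, J))
  for (l in seq_len(L)) {
    pp <- apply_concentration(p[l, ], conc)
    m[l, ] <- mixture_mean(pp, source_params$mu)
    s2[l, ] <- colSums(pp^2 * source_params$sigma^2)
  }
  if (nrow(md$Y) > 0) {
    for (i in seq_len(nrow(md$Y))) {
      l <- md$lev[i]
      sdv <- if (spec$error == "residual") state$tau else sqrt(s2[l, ])
      if (any(sdv <= 0)) return(-Inf)
      lp <- lp + sum(dnorm(md$Y[i, ], m[l, ], sdv, log = TRUE))
    }
  }
  lp
}

#' Run the MCMC sampler for a node model
#'
#' Adaptive random-walk Metropolis on ILR-transformed proportions (one
#' simplex per factor level) and log residual SDs, with source parameters
#' refreshed each iteration from their closed-form posteriors. Step size
#' adapts during burn-in only. Per-chain seeds are derived from the master
#' seed, so runs are reproducible.
#'
#' @param spec a [node_model_spec()].
#' @param data a [tracer_table()], or NULL for a prior-only run.
#' @param settings an [mcmc_settings()].
#' @param seed master seed (integer).
#' @return object of class `posterior_draws`: `p` (array draws x K sources x
#'   L levels), `tau` (draws x J), `chain` (chain index per draw), plus
#'   `sources`, `classes`, `levels`, `tracers`, `node`, `settings`,
#'   `accept_rate`.
#' @export
run_mcmc <- function(spec, data = NULL, settings = mcmc_settings(),
                     seed = 1) {
  stopifnot(inherits(spec, "node_model_spec"),
            inherits(settings, "mcmc_settings"))
  n_keep <- retained_draws(settings)
  if (n_keep < 1) stop("settings retain no draws", call. = FALSE)
  md <- mix_data_matrix(spec, data)
  K <- length(spec$sources)
  J <- length(spec$tracers)
  L <- length(spec$levels)
  conc <- if (is.null(spec$concentration)) matrix(1, K, J)
          else unname(spec$concentration)
  tau_max <- spec$tau_max
  if (is.null(tau_max)) tau_max <- default_tau_max(md$Y)
  tau_max <- rep(tau_max, length.out = J)
  residual <- spec$error == "residual"
  set.seed(seed %% .Machine$integer.max)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, settings$chains)
  p_all <- array(NA_real_, c(n_keep * settings$chains, K, L),
                 dimnames = list(NULL, spec$sources, spec$levels))
  tau_all <- matrix(NA_real_, n_keep * settings$chains, if (residual) J else 0)
  if (residual) colnames(tau_all) <- spec$tracers
  chain <- rep(seq_len(settings$chains), each = n_keep)
  acc <- numeric(settings$chains)
  for (ch in seq_len(settings$chains)) {
    set.seed(chain_seeds[ch])
    res <- run_chain_cpp(md$Y, md$lev - 1L, L,
                         unname(spec$summaries$mean),
                         unname(spec$summaries$sd),
                         unname(spec$summaries$n),
                         spec$source_fit == "draw",
                         conc, unname(spec$alpha), residual, tau_max,
                         settings$chain_length, settings$burn,
                         settings$thin, 0.2)
    rows <- (ch - 1) * n_keep + seq_len(n_keep)
    p_all[rows, , ] <- res$p
    if (residual) tau_all[rows, ] <- res$tau
    acc[ch] <- res$accept_rate
  }
  structure(list(p = p_all, tau = tau_all, chain = chain,
                 sources = spec$sources, classes = spec$classes,
                 levels = spec$levels, tracers = spec$tracers,
                 node = spec$node, settings = settings,
                 accept_rate = acc, seed = seed),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws: node", x$node, "-", dim(x$p)[1], "draws (",
      max(x$chain), "chains ), K =", dim(x$p)[2], "sources, levels:",
      paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' Construct degenerate (point-mass) posterior draws
#'
#' Builds a `posterior_draws` object whose every draw equals the given
#' proportions. Useful for worked examples and for deconvoluting published
#' node-level posterior means.
#'
#' @param p named numeric vector on the simplex (one level), or an L x K
#'   matrix with rownames = levels, colnames = sources.
#' @param n number of draws (default 1000).
#' @param node node label.
#' @param classes named character mapping source -> ultimate class.
#' @param chains nominal chain count for bookkeeping (default 1).
#' @return a `posterior_draws` object.
#' @export
point_mass_draws <- function(p, n = 1000, node = "M", classes = NULL,
                             chains = 1) {
  if (is.vector(p)) {
    p <- matrix(p, 1, dimnames = list("all", names(p)))
  }
  stopifnot(!is.null(colnames(p)), all(abs(rowSums(p) - 1) < 1e-6))
  K <- ncol(p)
  L <- nrow(p)
  arr <- array(NA_real_, c(n, K, L),
               dimnames = list(NULL, colnames(p), rownames(p)))
  for (l in seq_len(L)) arr[, , l] <- matrix(p[l, ], n, K, byrow = TRUE)
  if (is.null(classes)) classes <- setNames(colnames(p), colnames(p))
  structure(list(p = arr, tau = matrix(NA_real_, n, 0),
                 chain = rep(seq_len(chains), length.out = n),
                 sources = colnames(p), classes = classes,
                 levels = rownames(p), tracers = character(),
                 node = node, settings = NULL, accept_rate = NA_real_,
                 seed = NA_integer_),
            class = "posterior_draws")
}

# Flatten a posterior_draws object to a draws x parameters matrix with
# names like p[level,source] and tau[tracer].
draws_matrix <- function(x) {
  stopifnot(inherits(x, "posterior_draws"))
  K <- dim(x$p)[2]; L <- dim(x$p)[3]
  cols <- list()
  for (l in seq_len(L)) {
    m <- x$p[, , l, drop = FALSE]
    dim(m) <- dim(x$p)[1:2]
    colnames(m) <- sprintf("p[%s,%s]", x$levels[l], x$sources)
    cols[[l]] <- m
  }
  out <- do.call(cbind, cols)
  if (ncol(x$tau) > 0) {
    tt <- x$tau
    colnames(tt) <- sprintf("tau[%s]", x$tracers)
    out <- cbind(out, tt)
  }
  out
}

#' Posterior summary of draws
#'
#' @param object a `posterior_draws` object.
#' @param ... unused.
#' @return data.frame: node, level, source, mean, sd, q2.5, q25, q50, q75,
#'   q97.5.
#' @export
summary.posterior_draws <- function(object, ...) {
  K <- dim(object$p)[2]; L <- dim(object$p)[3]
  rows <- list()
  for (l in seq_len(L)) {
    for (k in seq_len(K)) {
      v <- object$p[, k, l]
      q <- quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        node = object$node, level = object$levels[l],
        source = object$sources[k], mean = mean(v), sd = sd(v),
        q2.5 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q97.5 = q[5])
    }
  }
  do.call(rbind, rows)
}
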