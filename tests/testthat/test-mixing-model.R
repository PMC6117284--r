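test_that("source parameter draws follow the closed-form posterior", {
  # plug-in identity
  pl <- source_param_draw(mean = 5, sd = 2, n = 10, plugin = TRUE)
  expect_identical(pl, list(mu = 5, sigma = 2))
  expect_error(source_param_draw(1, 1, n = 1), "n >= 2")

  # large-n concentration at the sample mean
  set.seed(4)
  mus <- replicate(200, source_param_draw(5, 2, n = 1e6)$mu)
  expect_lt(sd(mus), 0.01)

  # standardized mean draws are Student-t with n - 1 df
  set.seed(12)
  n <- 8; xbar <- 3; s <- 2
  z <- replicate(1e4, (source_param_draw(xbar, s, n)$mu - xbar) / (s / sqrt(n)))
  ks <- ks.test(z, pt, df = n - 1)
  expect_gt(ks$p.value, 0.01)

  # zero-SD tracers stay at plug-in values
  d0 <- source_param_draw(c(1, 2), c(0, 1), n = 5)
  expect_equal(d0$mu[1], 1)
  expect_equal(d0$sigma[1], 0)
})

test_that("concentration adjustment renormalises proportions per tracer", {
  # equal concentrations cancel
  p <- c(0.2, 0.3, 0.5)
  expect_equal(apply_concentration(p, matrix(7, 3, 2)),
               matrix(p, 3, 2))
  # worked two-source case
  expect_equal(apply_concentration(c(0.5, 0.5), c(2, 1))[, 1],
               c(2 / 3, 1 / 3))
  # random K = 4: sums to one and matches the direct quotient
  set.seed(14)
  for (rep in 1:20) {
    p <- rgamma_dirichlet(rep(1, 4))
    cc <- matrix(runif(4 * 3, 0.1, 5), 4, 3)
    pp <- apply_concentration(p, cc)
    expect_equal(colSums(pp), rep(1, 3))
    direct <- sapply(1:3, function(j) p * cc[, j] / sum(p * cc[, j]))
    expect_equal(pp, direct)
  }
  expect_error(apply_concentration(c(0.5, 0.5), c(-1, 1)), "positive")
})

test_that("mixture mean is the weighted combination of source means", {
  mu <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  # vertex: pure source k
  expect_equal(mixture_mean(c(0, 1, 0), mu), mu[2, ])
  # constancy: identical sources
  expect_equal(mixture_mean(c(0.3, 0.3, 0.4), matrix(7, 3, 2)), c(7, 7))
  # naive double loop oracle
  set.seed(15)
  p <- rgamma_dirichlet(c(1, 1, 1))
  pp <- apply_concentration(p, matrix(runif(6, 0.5, 2), 3, 2))
  m <- mixture_mean(pp, mu)
  naive <- numeric(2)
  for (j in 1:2) for (k in 1:3) naive[j] <- naive[j] + pp[k, j] * mu[k, j]
  expect_equal(m, naive)
})

test_that("log posterior has a flat Dirichlet prior and mirror symmetry", {
  src <- exact_sources(c(S1 = 1, S2 = -1), sd = 1, n = 10)
  spec <- node_model_spec(src, tau_max = 5)
  # alpha = 1: prior constant in p (no data)
  lp1 <- log_posterior(list(p = c(0.3, 0.7), tau = 1), NULL, spec)
  lp2 <- log_posterior(list(p = c(0.9, 0.1), tau = 1), NULL, spec)
  expect_equal(lp1, lp2)
  # symmetric sources, Y = 0: symmetric under p <-> 1 - p
  mt <- toy_mixture(0)
  lp3 <- log_posterior(list(p = c(0.3, 0.7), tau = 1), mt, spec)
  lp4 <- log_posterior(list(p = c(0.7, 0.3), tau = 1), mt, spec)
  expect_equal(lp3, lp4)
  # outside support
  expect_identical(log_posterior(list(p = c(0.5, 0.5), tau = -1), mt, spec),
                   -Inf)
})

test_that("retained draw accounting follows floor((length - burn)/thin)", {
  expect_identical(retained_draws(mcmc_settings(1e6, 7e5, 300, 3)), 1000L)
  expect_identical(retained_draws(mcmc_settings(1001, 500, 7, 2)), 71L)
  st <- mcmc_settings(2000, 1000, 7, 3)
  src <- toy_sources()
  d <- run_mcmc(node_model_spec(src, tau_max = 1), NULL, st, seed = 1)
  expect_equal(dim(d$p)[1], retained_draws(st) * 3)
  expect_equal(as.vector(table(d$chain)), rep(retained_draws(st), 3))
})

test_that("every retained draw lies on the simplex", {
  truth <- truth_spec(make_topology("simple"), levels = c("EW", "MW"),
                      seed = 6)
  dat <- simulate_watershed(truth)
  f <- suppressWarnings(  # short chains: gate chatter is not under test
    mixfit(dat$mixtures$M, dat$sources$M, mcmc = quick_mcmc(), seed = 6))
  sums <- apply(f$draws$p, c(1, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_true(all(f$draws$p >= 0))
})

test_that("with no data the posterior recovers the Dirichlet prior", {
  src <- source_set("M", list(A = data.frame(x = c(0, 1)),
                              B = data.frame(x = c(9, 10)),
                              C = data.frame(x = c(4, 5)),
                              D = data.frame(x = c(7, 8))))
  st <- mcmc_settings(30000, 10000, 5, 3)
  # uninformative all-ones prior: mean 1/K
  d1 <- run_mcmc(node_model_spec(src, alpha = 1, tau_max = 1), NULL, st,
                 seed = 42)
  expect_equal(unname(apply(d1$p, 2, mean)), rep(0.25, 4), tolerance = 0.02)
  # informative channel-bank-style prior (0.01, 1, 1, 1): mean alpha/sum
  a <- c(A = 0.01, B = 1, C = 1, D = 1)
  d2 <- run_mcmc(node_model_spec(src, alpha = a, tau_max = 1), NULL, st,
                 seed = 43)
  expect_lt(max(abs(apply(d2$p, 2, mean) - a / sum(a))), 0.02)
})

test_that("prior-only marginals match the Beta marginal of the Dirichlet", {
  # asymmetric alpha so a wrong ILR Jacobian would shift the marginal
  src <- toy_sources()
  a <- c(A = 2, B = 1)
  d <- run_mcmc(node_model_spec(src, alpha = a, tau_max = 1), NULL,
                mcmc_settings(60000, 10000, 10, 3), seed = 44)
  ks <- suppressWarnings(ks.test(d$p[, 1, 1], pbeta, 2, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("all-equal concentrations reproduce the concentration-off fit", {
  truth <- truth_spec(make_topology("simple"), seed = 9)
  dat <- simulate_watershed(truth)
  st <- quick_mcmc()
  f_off <- mixfit(dat$mixtures$M, dat$sources$M, mcmc = st, seed = 5)
  conc <- matrix(3.7, 3, 8, dimnames = list(names(dat$sources$M$groups),
                                            truth$tracers))
  f_eq <- mixfit(dat$mixtures$M, dat$sources$M, concentration = conc,
                 mcmc = st, seed = 5)
  expect_identical(f_off$draws$p, f_eq$draws$p)
  expect_identical(f_off$draws$tau, f_eq$draws$tau)
})

test_that("mixfit methods expose coefficients, residuals and simulations", {
  truth <- truth_spec(make_topology("simple"), seed = 10)
  dat <- simulate_watershed(truth)
  f <- suppressWarnings(
    mixfit(dat$mixtures$M, dat$sources$M, mcmc = quick_mcmc(), seed = 2))
  cf <- coef(f)
  expect_equal(dim(cf), c(1, 3))
  expect_equal(sum(cf), 1, tolerance = 1e-9)
  s <- summary(f)
  expect_true(all(c("mean", "sd", "q2.5", "q97.5") %in% names(s)))
  r <- residuals(f)
  expect_equal(dim(r), c(6, 8))
  sim <- simulate(f, nsim = 2, seed = 1)
  expect_length(sim, 2)
  expect_equal(dim(sim[[1]]), dim(r))
  expect_output(print(f), "mixing model fit")
})
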