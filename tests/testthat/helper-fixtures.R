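# Shared fixture builders: tiny deterministic datasets for unit tests.

# Two well-separated one-tracer source groups (raw samples).
toy_sources <- function(mu = c(A = 0, B = 10), sd = 1, n = 5, seed = 1) {
  set.seed(seed)
  groups <- lapply(mu, function(m) data.frame(x = rnorm(n, m, sd)))
  source_set("M", groups)
}

# Summary-mode two-source set with exact means (for closed-form checks).
exact_sources <- function(mu = c(S1 = 10, S2 = 0), sd = 1e-8, n = 10) {
  groups <- lapply(mu, function(m) {
    data.frame(tracer = "x", mean = m, sd = sd, n = n)
  })
  source_set("M", groups)
}

toy_mixture <- function(y, level = NULL) {
  df <- data.frame(x = y)
  if (!is.null(level)) {
    df$lev <- level
    tracer_table(df, "M", "x", factor = "lev")
  } else {
    tracer_table(df, "M", "x")
  }
}

# Short MCMC profile for unit tests where only rough posterior location
# matters.
quick_mcmc <- function() mcmc_settings(8000, 4000, 4, 3)

# Test-scale profile used for the quantitative acceptance checks.
test_mcmc <- function() mcmc_settings(50000, 25000, 25, 3)
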