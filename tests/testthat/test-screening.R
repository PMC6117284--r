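test_that("range test flags containment and exclusion correctly", {
  src <- source_set("M", list(A = data.frame(x = c(1, 2, 3)),
                              B = data.frame(x = c(4, 5, 6))))
  inside <- toy_mixture(c(2, 3, 5))
  rt <- range_test(src, inside)
  expect_equal(rt$in_range_fraction, 1)
  expect_true(rt$pass)
  expect_equal(rt$source_min, 1)
  expect_equal(rt$source_max, 6)

  # mixture entirely above the pooled source maximum (non-conservative)
  above <- toy_mixture(c(10, 12, 14))
  rt2 <- range_test(src, above)
  expect_equal(rt2$in_range_fraction, 0)
  expect_false(rt2$pass)
})

test_that("in-range fraction equals a brute-force count on random instances", {
  set.seed(99)
  for (rep in 1:100) {
    n_src <- sample(3:10, 2, replace = TRUE)
    src <- source_set("M", list(A = data.frame(x = runif(n_src[1], 0, 10)),
                                B = data.frame(x = runif(n_src[2], 0, 10))))
    y <- runif(sample(3:10, 1), -2, 12)
    mt <- toy_mixture(y)
    rt <- range_test(src, mt)
    pooled <- c(src$groups$A$samples$x, src$groups$B$samples$x)
    brute <- sum(y >= min(pooled) & y <= max(pooled)) / length(y)
    expect_equal(rt$in_range_fraction, brute)
  }
})

test_that("range test is invariant to group relabeling and sample order", {
  set.seed(7)
  a <- data.frame(x = rnorm(6)); b <- data.frame(x = rnorm(6, 2))
  y <- rnorm(5, 1)
  r1 <- range_test(source_set("M", list(A = a, B = b)), toy_mixture(y))
  r2 <- range_test(source_set("M", list(Zed = b, Q = a)),
                   toy_mixture(rev(y)))
  expect_equal(r1$in_range_fraction, r2$in_range_fraction)
  expect_equal(r1$source_min, r2$source_min)
})

test_that("summary-only sources require the explicit mean +/- 2 SD opt-in", {
  src <- exact_sources(c(S1 = 5, S2 = 10), sd = 1, n = 10)
  mt <- toy_mixture(c(6, 7))
  expect_error(range_test(src, mt), "mean_pm_2sd")
  rt <- range_test(src, mt, summary_bounds = "mean_pm_2sd")
  expect_equal(rt$source_min, 3)
  expect_equal(rt$source_max, 12)
  expect_true(rt$pass)
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  # identical groups: no between-group variance
  r0 <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)

  # hand computation for (1,2,3) vs (4,5,6): grand mean 3.5,
  # SSB = 3*(2-3.5)^2 + 3*(5-3.5)^2 = 13.5, SSW = 2+2 = 4,
  # F = (13.5/1)/(4/4) = 13.5
  r <- one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(r$F, 13.5)
  expect_equal(r$df_between, 1)
  expect_equal(r$df_within, 4)
  expect_equal(r$p, pf(13.5, 1, 4, lower.tail = FALSE))

  # equal means, unequal values: F small
  r2 <- one_way_anova(list(a = c(0, 2), b = c(-1, 3), c = c(1, 1)))
  expect_lt(r2$F, 1)
  expect_gt(r2$p, 0.5)

  expect_error(one_way_anova(list(a = c(2, 2), b = c(2, 2))), "identical")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(11)
  for (rep in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), 1)
    f <- one_way_anova(list(a = a, b = b))$F
    t <- t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(f, unname(t^2), tolerance = 1e-10)
  }
})

test_that("Tukey HSD matches stats::TukeyHSD and behaves monotonically", {
  set.seed(21)
  groups <- list(a = rnorm(6, 0), b = rnorm(5, 1), c = rnorm(7, 3))
  th <- tukey_hsd(groups)
  x <- unlist(groups)
  g <- factor(rep(names(groups), lengths(groups)))
  ref <- TukeyHSD(aov(x ~ g))$g
  expect_equal(th$p_adj[match(rownames(ref), th$pair)],
               unname(ref[, "p adj"]), tolerance = 1e-8)

  # identical groups: nothing significant
  th0 <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_false(any(th0$significant))

  # extreme separation: the single pair significant
  set.seed(2)
  th1 <- tukey_hsd(list(a = rnorm(5, 0), b = rnorm(5, 10)))
  expect_true(all(th1$significant))

  # adjusted p decreases as the mean difference grows, all else fixed
  base <- c(-1, 0, 1)
  p_at <- vapply(c(1, 3, 6), function(d) {
    tukey_hsd(list(a = base, b = base + d))$p_adj
  }, 0)
  expect_true(all(diff(p_at) < 0))
})

test_that("Tukey adjusted p agrees with a Monte-Carlo studentized range", {
  # balanced one-way null: P(q_max > q_obs) by direct simulation
  k <- 3; n <- 5; df <- k * (n - 1)
  q_obs <- 3.2
  set.seed(31)
  sims <- replicate(4000, {
    m <- matrix(rnorm(k * n), n, k)
    s2 <- mean(apply(m, 2, var))
    diff(range(colMeans(m))) / sqrt(s2 / n)
  })
  mc <- mean(sims > q_obs)
  expect_equal(ptukey(q_obs, k, df, lower.tail = FALSE), mc,
               tolerance = 0.03)
})

test_that("screen_panel applies the range test then manual overrides", {
  set.seed(5)
  src <- source_set("M", list(A = data.frame(ok = rnorm(6, 0),
                                             bad = rnorm(6, 0)),
                              B = data.frame(ok = rnorm(6, 5),
                                             bad = rnorm(6, 1))))
  mix <- tracer_table(data.frame(ok = c(2, 3), bad = c(50, 60)), "M",
                      c("ok", "bad"))
  sc <- screen_panel(src, mix)
  expect_identical(sc$retained, "ok")
  expect_match(sc$report$reason[sc$report$tracer == "bad"], "outside")

  # expert withdrawal of a passing tracer (e.g. sorting-sensitive element)
  sc2 <- screen_panel(src, mix, screen_policy(exclude = "ok",
                                              include = "bad"))
  expect_identical(sc2$retained, "bad")
  expect_match(sc2$report$reason[sc2$report$tracer == "ok"], "manual")

  # all pass, no overrides: identity
  mix_in <- tracer_table(data.frame(ok = c(2, 3), bad = c(0.5, 0.8)), "M",
                         c("ok", "bad"))
  expect_setequal(screen_panel(src, mix_in)$retained, c("ok", "bad"))

  # everything eliminated: actionable error
  mix_out <- tracer_table(data.frame(ok = c(50, 60), bad = c(50, 60)), "M",
                          c("ok", "bad"))
  expect_error(screen_panel(src, mix_out), "threshold")
})

test_that("normality EDA reports descriptive stats and Shapiro p", {
  set.seed(8)
  eda <- normality_eda(list(a = rnorm(20), b = rexp(20)))
  expect_equal(nrow(eda), 2)
  expect_true(all(eda$shapiro_p >= 0 & eda$shapiro_p <= 1))
  expect_gt(eda$skewness[2], eda$skewness[1])
})
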