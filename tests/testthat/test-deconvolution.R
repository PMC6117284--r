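test_that("unmixing order is topological with lexicographic tie-breaks", {
  long <- make_topology("longitudinal")
  expect_identical(unmixing_order(long), c("M1", "M2", "M3", "M4"))

  dist <- make_topology("distributed")
  ord <- unmixing_order(dist)
  expect_true(which(ord == "M1") < which(ord == "M3"))
  expect_true(which(ord == "M2") < which(ord == "M3"))
  expect_true(which(ord == "M3") < which(ord == "M5"))
  expect_true(which(ord == "M4") < which(ord == "M5"))

  expect_identical(unmixing_order(make_topology("simple")), "M")

  # cycle detection on a raw graph structure
  cyc <- list(nodes = c("A", "B"),
              edges = data.frame(from = c("A", "B"), to = c("B", "A")))
  expect_error(unmixing_order(cyc), "cycle")
})

test_that("node sources combine upstream mixtures with local groups", {
  truth <- truth_spec(make_topology("longitudinal"), seed = 20)
  dat <- simulate_watershed(truth)
  # M3 unmixes against upstream M2 plus its local groups A3, D3
  spec <- assemble_node_sources(truth$graph, "M3", dat$mixtures,
                                dat$sources)
  expect_identical(spec$sources, c("M2", "A3", "D3"))
  # headwater node: local groups only
  spec1 <- assemble_node_sources(truth$graph, "M1", dat$mixtures,
                                 dat$sources)
  expect_identical(spec1$sources, c("A1", "B1", "C1"))

  # confluence node with no local groups unmixes its two upstream nodes
  truth_d <- truth_spec(make_topology("distributed"), seed = 21)
  dat_d <- simulate_watershed(truth_d)
  spec3 <- assemble_node_sources(truth_d$graph, "M3", dat_d$mixtures,
                                 dat_d$sources)
  expect_identical(spec3$sources, c("M1", "M2"))

  # upstream node with < 2 mixture samples cannot act as a pseudo-source
  short <- dat$mixtures
  short$M2$data <- short$M2$data[1, , drop = FALSE]
  expect_error(assemble_node_sources(truth$graph, "M3", short, dat$sources),
               "fewer than 2")
})

test_that("deconvolution chains point-mass proportions exactly", {
  g <- watershed_graph(
    nodes = c("M1", "M2"),
    edges = data.frame(from = "M1", to = "M2"),
    local_sources = list(M1 = c("A1", "B1"), M2 = "B2"),
    group_classes = c(A1 = "A", B1 = "B", B2 = "B"))
  nd <- list(
    M1 = point_mass_draws(c(A1 = 0.6, B1 = 0.4), node = "M1",
                          classes = c(A1 = "A", B1 = "B")),
    M2 = point_mass_draws(c(M1 = 0.5, B2 = 0.5), node = "M2",
                          classes = c(M1 = "M1", B2 = "B")))
  comp <- deconvolute(nd, graph = g, seed = 1)
  s <- comp$summary
  # p(B -> M2) = p_B1 * p_M1 + p_B2 = 0.4*0.5 + 0.5 = 0.7
  expect_equal(s$mean[s$node == "M2" & s$source == "B"], 0.7)
  expect_equal(s$mean[s$node == "M2" & s$source == "A"], 0.3)
  expect_equal(s$sd[s$node == "M2"], c(0, 0))
  # leaf node: its own posterior through the class indicator
  expect_equal(s$mean[s$node == "M1" & s$source == "A"], 0.6)
})

test_that("a q = 1 pass-through node copies the upstream composite", {
  g <- watershed_graph(
    nodes = c("M1", "M2"),
    edges = data.frame(from = "M1", to = "M2"),
    local_sources = list(M1 = c("A1", "B1")),
    group_classes = c(A1 = "A", B1 = "B"))
  set.seed(30)
  q <- rgamma_dirichlet(c(2, 2))
  m1 <- matrix(rep(NA_real_, 200), 100, 2,
               dimnames = list(NULL, c("A1", "B1")))
  for (i in 1:100) m1[i, ] <- rgamma_dirichlet(c(2, 2))
  d1 <- point_mass_draws(c(A1 = 0.5, B1 = 0.5), n = 100, node = "M1",
                         classes = c(A1 = "A", B1 = "B"))
  d1$p[, , 1] <- m1
  d2 <- point_mass_draws(c(M1 = 1), n = 100, node = "M2")
  comp <- deconvolute(list(M1 = d1, M2 = d2), graph = g, seed = 2)
  # identical draw-for-draw (same pairing permutation applies upstream)
  expect_equal(comp$draws$M2$all, comp$draws$M1$all)
})

test_that("composite draws conserve the simplex and dampen via edges", {
  truth <- truth_spec(make_topology("distributed"), seed = 22,
                      n_mixtures = 4, n_sources = 10)
  dat <- simulate_watershed(truth)
  rf <- fit_network(truth$graph, dat$mixtures, dat$sources,
                    mcmc = quick_mcmc(), seed = 3, force = TRUE)
  comp <- deconvolute(rf, seed = 4)
  for (node in names(comp$draws)) {
    for (lev in names(comp$draws[[node]])) {
      expect_lt(max(abs(rowSums(comp$draws[[node]][[lev]]) - 1)), 1e-10)
    }
  }
  s <- comp$summary
  expect_true(all(s$mean >= 0 & s$mean <= 1))

  # monotone dampening, exact per draw: with the confluence proportions
  # fixed at q = (0.3, 0.7), class A (entering only via M1) can never
  # exceed 0.3 in any composite draw
  nd <- lapply(rf$fits, function(f) f$draws)
  nd$M3 <- point_mass_draws(c(M1 = 0.3, M2 = 0.7),
                            n = dim(nd$M3$p)[1], node = "M3")
  nd$M3$levels <- rf$fits$M3$draws$levels
  dimnames(nd$M3$p)[[3]] <- nd$M3$levels
  comp2 <- deconvolute(nd, graph = truth$graph, seed = 4)
  expect_lte(max(comp2$draws$M3$all[, "A"]), 0.3 + 1e-12)
})

test_that("deconvoluted composites agree with the exact truth oracle", {
  # point-mass draws at random truths across all topologies, many seeds
  for (kind in c("simple", "longitudinal", "distributed")) {
    for (r in 1:8) {
      truth <- truth_spec(make_topology(kind), seed = 100 * r + 7)
      g <- truth$graph
      nd <- lapply(g$nodes, function(node) {
        p <- truth$proportions[[node]]
        cls <- setNames(colnames(p), colnames(p))
        local <- intersect(colnames(p), names(g$group_classes))
        cls[local] <- g$group_classes[local]
        point_mass_draws(p[1, ], n = 50, node = node, classes = cls)
      })
      names(nd) <- g$nodes
      comp <- deconvolute(nd, graph = g, seed = r)
      tc <- true_composite(truth)
      s <- comp$summary
      merged <- merge(s, tc, by.x = c("node", "source"),
                      by.y = c("node", "class"))
      expect_equal(merged$mean, merged$proportion, tolerance = 1e-12)
    }
  }
})

test_that("composite means are invariant to the pairing permutation seed", {
  truth <- truth_spec(make_topology("distributed"), seed = 23,
                      n_mixtures = 4, n_sources = 10)
  dat <- simulate_watershed(truth)
  rf <- fit_network(truth$graph, dat$mixtures, dat$sources,
                    mcmc = quick_mcmc(), seed = 5, force = TRUE)
  c1 <- summarize_composite(deconvolute(rf, seed = 1))
  c2 <- summarize_composite(deconvolute(rf, seed = 999))
  # node posteriors are independent, so any pairing leaves means unchanged
  # up to Monte Carlo error in the draw subset
  expect_equal(c1$mean, c2$mean, tolerance = 0.05)
})

test_that("independent products average to the product of means", {
  set.seed(40)
  g <- watershed_graph(
    nodes = c("M1", "M2"),
    edges = data.frame(from = "M1", to = "M2"),
    local_sources = list(M1 = c("A1", "B1"), M2 = "B2"),
    group_classes = c(A1 = "A", B1 = "B", B2 = "B"))
  n <- 4000
  d1 <- point_mass_draws(c(A1 = 0.5, B1 = 0.5), n = n, node = "M1",
                         classes = c(A1 = "A", B1 = "B"))
  d2 <- point_mass_draws(c(M1 = 0.5, B2 = 0.5), n = n, node = "M2")
  for (i in seq_len(n)) {
    d1$p[i, , 1] <- rgamma_dirichlet(c(2, 2))
    d2$p[i, , 1] <- rgamma_dirichlet(c(2, 2))
  }
  comp <- deconvolute(list(M1 = d1, M2 = d2), graph = g, seed = 3)
  mean_q <- mean(d2$p[, "M1", 1])
  mean_a <- mean(d1$p[, "A1", 1])
  got <- mean(comp$draws$M2$all[, "A"])
  mcse <- sd(comp$draws$M2$all[, "A"]) / sqrt(n)
  expect_lt(abs(got - mean_q * mean_a), 3 * mcse + 0.01)
})

test_that("factor levels chain like-with-like across nodes", {
  g <- watershed_graph(
    nodes = c("M1", "M2"),
    edges = data.frame(from = "M1", to = "M2"),
    local_sources = list(M1 = c("A1", "B1"), M2 = "B2"),
    group_classes = c(A1 = "A", B1 = "B", B2 = "B"))
  p1 <- rbind(EW = c(A1 = 0.9, B1 = 0.1), MW = c(A1 = 0.1, B1 = 0.9))
  p2 <- rbind(EW = c(M1 = 1, B2 = 0), MW = c(M1 = 1, B2 = 0))
  d1 <- point_mass_draws(p1, node = "M1", classes = c(A1 = "A", B1 = "B"))
  d2 <- point_mass_draws(p2, node = "M2")
  comp <- deconvolute(list(M1 = d1, M2 = d2), graph = g, seed = 1)
  expect_equal(mean(comp$draws$M2$EW[, "A"]), 0.9)
  expect_equal(mean(comp$draws$M2$MW[, "A"]), 0.1)
  # upstream without the downstream factor: pooled upstream draws are used
  d1p <- point_mass_draws(c(A1 = 0.5, B1 = 0.5), node = "M1",
                          classes = c(A1 = "A", B1 = "B"))
  comp2 <- deconvolute(list(M1 = d1p, M2 = d2), graph = g, seed = 1)
  expect_equal(mean(comp2$draws$M2$EW[, "A"]), 0.5)
})

test_that("pooled sources merge classes across sub-watersheds", {
  truth <- truth_spec(make_topology("longitudinal"), seed = 24,
                      n_mixtures = 3, n_sources = 8)
  dat <- simulate_watershed(truth)
  f <- suppressWarnings(pooled_fit(truth$graph, dat$mixtures, dat$sources,
                                   nodes = "M4", mcmc = quick_mcmc(),
                                   seed = 7))
  expect_setequal(f$spec$sources, c("A", "B", "C", "D"))
  # pooled raw group sizes are the summed member group sizes
  # classes B appears in M1 (B1) and M2 (B2): 8 + 8 samples
  ps <- rivermix:::pool_sources(truth$graph, dat$sources)
  expect_equal(unname(source_sizes(ps)["B"]), 16L)

  # pooled summary statistics match the concatenated-sample statistics
  raw_b <- rbind(dat$sources$M1$groups$B1$samples,
                 dat$sources$M2$groups$B2$samples)
  sums <- lapply(dat$sources, function(s) {
    groups <- lapply(s$groups, function(g) {
      data.frame(tracer = names(g$samples),
                 mean = vapply(g$samples, mean, 0),
                 sd = vapply(g$samples, sd, 0), n = nrow(g$samples))
    })
    source_set(s$node, groups, classes = s$classes)
  })
  ps2 <- rivermix:::pool_sources(truth$graph, sums)
  st <- ps2$groups$B$stats
  expect_equal(st$mean[st$tracer == "T1"], mean(raw_b$T1))
  expect_equal(st$sd[st$tracer == "T1"], sd(raw_b$T1))
})

test_that("pooling a single sub-watershed reduces to the single-node model", {
  truth <- truth_spec(make_topology("simple"), seed = 25)
  dat <- simulate_watershed(truth)
  pooled <- rivermix:::pool_sources(truth$graph, dat$sources)
  direct <- dat$sources$M
  expect_setequal(names(pooled$groups), names(direct$groups))
  for (g in names(direct$groups)) {
    expect_equal(pooled$groups[[g]]$samples, direct$groups[[g]]$samples,
                 ignore_attr = TRUE)
  }
})

test_that("pooled and deconvolutional means agree for exchangeable sources", {
  # identical class signatures across sub-watersheds: pooling loses nothing
  truth <- truth_spec(make_topology("distributed"), group_offset = 0,
                      n_mixtures = 6, n_sources = 12, seed = 26)
  dat <- simulate_watershed(truth)
  st <- mcmc_settings(20000, 10000, 10, 3)
  rf <- fit_network(truth$graph, dat$mixtures, dat$sources, mcmc = st,
                    seed = 8, force = TRUE)
  comp <- deconvolute(rf, seed = 8)
  pf <- suppressWarnings(pooled_fit(truth$graph, dat$mixtures, dat$sources,
                                    nodes = "M5", mcmc = st, seed = 8))
  cs <- comp$summary[comp$summary$node == "M5", ]
  pm <- coef(pf)[1, ]
  expect_equal(unname(pm[cs$source]), cs$mean, tolerance = 0.05)
})
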