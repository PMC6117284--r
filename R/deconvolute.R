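# Deconvolution of node-level posterior proportions over the watershed DAG:
# re-expresses each node's posterior over its immediate inputs (local
# groups + upstream nodes) as a posterior over the ultimate source classes,
# propagating uncertainty draw-by-draw. The recursion per draw is
#   composite(node) = sum_i q_i * composite(input_i)
# with composite(local group) = indicator of its ultimate class; e.g. the
# contribution of class B to M2 through upstream node M1 is
# p_B1 * p_M1 + p_B2.

#' Deconvolute node posteriors into ultimate-source apportionment
#'
#' @param x a `river_fit` (from [fit_network()]) or a named list of
#'   `posterior_draws` objects, one per graph node (e.g. built with
#'   [point_mass_draws()] from published node-level means).
#' @param graph a [watershed_graph()] (taken from `x` when it is a
#'   `river_fit`).
#' @param seed pairing seed: because independently fitted node posteriors
#'   are statistically independent, their draws are paired after an
#'   independent seeded permutation of each node's pooled retained draws.
#' @param level_map optional named character mapping a downstream factor
#'   level to the upstream level to chain with; by default levels chain
#'   like-with-like, and an upstream node lacking the downstream level
#'   contributes its draws pooled across its own levels.
#' @return object of class `composite_apportionment`: `draws` (node ->
#'   level -> draws x classes matrix), `summary` (data.frame), `graph`,
#'   `seed`.
#' @export
deconvolute <- function(x, graph = NULL, seed = 1, level_map = NULL) {
  if (inherits(x, "river_fit")) {
    graph <- x$graph
    node_draws <- lapply(x$fits, function(f) f$draws)
  } else {
    node_draws <- x
  }
  stopifnot(inherits(graph, "watershed_graph"))
  miss <- setdiff(graph$nodes, names(node_draws))
  if (length(miss) > 0) {
    stop("no posterior draws for node(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ord <- unmixing_order(graph)
  n_total <- vapply(node_draws, function(d) dim(d$p)[1], 1L)
  T_n <- min(n_total)
  classes <- graph$classes
  # independent seeded permutation per node (deterministic node order)
  set.seed(seed %% .Machine$integer.max)
  perms <- lapply(graph$nodes[order(graph$nodes)], function(nd) {
    sample.int(n_total[[nd]])
  })
  names(perms) <- graph$nodes[order(graph$nodes)]
  comp <- list()         # node -> level -> T x C matrix
  comp_pooled <- list()  # node -> T x C matrix (draws pooled over levels)
  for (node in ord) {
    d <- node_draws[[node]]
    idx <- perms[[node]][seq_len(T_n)]
    levels_n <- d$levels
    inputs <- d$sources
    comp[[node]] <- list()
    for (l in seq_along(levels_n)) {
      lev <- levels_n[l]
      acc <- matrix(0, T_n, length(classes),
                    dimnames = list(NULL, classes))
      q <- d$p[idx, , l, drop = FALSE]
      dim(q) <- c(T_n, length(inputs))
      for (i in seq_along(inputs)) {
        inp <- inputs[i]
        if (inp %in% graph$nodes) {
          lev_up <- if (!is.null(level_map) && lev %in% names(level_map))
            level_map[[lev]] else lev
          Ci <- if (lev_up %in% names(comp[[inp]])) {
            comp[[inp]][[lev_up]]
          } else {
            comp_pooled[[inp]]
          }
        } else {
          cl <- if (inp %in% names(graph$group_classes))
            graph$group_classes[[inp]] else d$classes[[inp]]
          if (is.null(cl) || !cl %in% classes) {
            stop("group ", inp, " maps to unknown class ", cl, call. = FALSE)
          }
          Ci <- matrix(0, T_n, length(classes),
                       dimnames = list(NULL, classes))
          Ci[, cl] <- 1
        }
        acc <- acc + q[, i] * Ci
      }
      if (any(abs(rowSums(acc) - 1) > 1e-10)) {
        stop("composite simplex violation at node ", node, call. = FALSE)
      }
      comp[[node]][[lev]] <- acc
    }
    # pooled-over-levels composite for downstream chaining across factors
    all_lev <- do.call(rbind, comp[[node]])
    if (nrow(all_lev) > T_n) {
      pidx <- sample.int(nrow(all_lev))[seq_len(T_n)]
      comp_pooled[[node]] <- all_lev[pidx, , drop = FALSE]
    } else {
      comp_pooled[[node]] <- all_lev
    }
  }
  out <- structure(list(draws = comp, graph = graph, seed = seed,
                        n_draws = T_n),
                   class = "composite_apportionment")
  out$summary <- summarize_composite(out)
  out
}

#' Summary table of a composite apportionment
#'
#' @param composite a `composite_apportionment`.
#' @return data.frame: node, level, source (ultimate class), mean, sd,
#'   q2.5, q25, q50, q75, q97.5.
#' @export
summarize_composite <- function(composite) {
  stopifnot(inherits(composite, "composite_apportionment"))
  rows <- list()
  for (node in names(composite$draws)) {
    for (lev in names(composite$draws[[node]])) {
      m <- composite$draws[[node]][[lev]]
      for (cl in colnames(m)) {
        v <- m[, cl]
        q <- quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          node = node, level = lev, source = cl, mean = mean(v),
          sd = sd(v), q2.5 = q[1], q25 = q[2], q50 = q[3], q75 = q[4],
          q97.5 = q[5])
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.composite_apportionment <- function(x, ...) {
  cat("Composite apportionment over ultimate source classes (",
      x$n_draws, "paired draws )\n")
  writeLines(render_apportionment_table(x$summary))
  invisible(x)
}

#' Write composite apportionment outputs
#'
#' Writes the summary as CSV and text (via
#' [render_apportionment_table()]) and, optionally, the raw composite draws
#' as a long CSV (`draw`, `node`, `level`, `class`, `value`).
#'
#' @param composite a `composite_apportionment`.
#' @param path output stem.
#' @param draws also write raw draws (default FALSE; can be large).
#' @export
write_composite <- function(composite, path, draws = FALSE) {
  render_apportionment_table(composite$summary, path = path)
  if (draws) {
    long <- list()
    for (node in names(composite$draws)) {
      for (lev in names(composite$draws[[node]])) {
        m <- composite$draws[[node]][[lev]]
        for (cl in colnames(m)) {
          long[[length(long) + 1]] <- data.frame(
            draw = seq_len(nrow(m)), node = node, level = lev,
            class = cl, value = m[, cl])
        }
      }
    }
    write.csv(do.call(rbind, long), paste0(path, "_draws.csv"),
              row.names = FALSE)
  }
  invisible(path)
}
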