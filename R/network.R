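# Network-level orchestration: topological fitting order, assembly of
# per-node source sets (upstream mixtures acting as sources), sequential
# fitting, and the pooled-source baseline model.

#' Topological unmixing order of a watershed graph
#'
#' Upstream nodes are fitted before downstream nodes; ties are broken
#' deterministically by node label.
#'
#' @param graph a [watershed_graph()] (or a list with `nodes` and `edges`).
#' @return character vector of node labels in fitting order.
#' @export
unmixing_order <- function(graph) {
  nodes <- graph$nodes
  edges <- graph$edges
  indeg <- setNames(integer(length(nodes)), nodes)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  order_out <- character(0)
  avail <- sort(nodes[indeg == 0])
  while (length(avail) > 0) {
    v <- avail[1]
    avail <- avail[-1]
    order_out <- c(order_out, v)
    for (w in edges$to[edges$from == v]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0) avail <- sort(c(avail, w))
    }
  }
  if (length(order_out) < length(nodes)) {
    stop("watershed graph has a cycle involving: ",
         paste(setdiff(nodes, order_out), collapse = ", "), call. = FALSE)
  }
  order_out
}

#' Assemble the model specification for one node of the network
#'
#' The node's candidate sources are its local stratified source groups plus
#' one pseudo-source per upstream edge, whose "source samples" are the
#' upstream node's mixture samples (pooled across factor levels). Upstream
#' pseudo-sources are listed first (sorted), then local groups.
#'
#' @param graph a [watershed_graph()].
#' @param node node label.
#' @param mixtures named list: node -> [tracer_table()].
#' @param sources named list: node -> [source_set()] of its local groups.
#' @param tracers tracer panel for this node; default: tracers shared by
#'   the node's mixture table and all its inputs.
#' @param ... further arguments passed to [node_model_spec()] (`alpha`,
#'   `error`, `concentration`, ...).
#' @return a [node_model_spec()]; pseudo-source groups are named after
#'   their upstream node and mapped to themselves as class.
#' @export
assemble_node_sources <- function(graph, node, mixtures, sources,
                                  tracers = NULL, ...) {
  stopifnot(inherits(graph, "watershed_graph"), node %in% graph$nodes)
  ups <- upstream_nodes(graph, node)
  groups <- list()
  classes <- character()
  for (u in ups) {
    mt <- mixtures[[u]]
    if (is.null(mt)) stop("no mixture table for upstream node ", u,
                          call. = FALSE)
    if (nrow(mt$data) < 2) {
      stop("upstream node ", u, " has fewer than 2 mixture samples; ",
           "pseudo-source SD undefined", call. = FALSE)
    }
    groups[[u]] <- mt$data[mt$tracers]
    classes[u] <- u
  }
  local <- graph$local_sources[[node]]
  if (length(local) > 0) {
    ls <- sources[[node]]
    if (is.null(ls)) stop("no local source set for node ", node,
                          call. = FALSE)
    miss <- setdiff(local, names(ls$groups))
    if (length(miss) > 0) {
      stop("node ", node, ": local group(s) missing from source set: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    for (g in local) {
      grp <- ls$groups[[g]]
      groups[[g]] <- if (grp$type == "raw") grp$samples else grp$stats
      classes[g] <- graph$group_classes[[g]]
    }
  }
  if (is.null(tracers)) {
    tracers <- mixtures[[node]]$tracers
    for (g in groups) {
      pan <- if (all(c("tracer", "mean", "sd", "n") %in% names(g)))
        g$tracer else names(g)
      tracers <- intersect(tracers, pan)
    }
    if (length(tracers) == 0) {
      stop("node ", node, ": no tracers shared by mixture and all sources",
           call. = FALSE)
    }
  }
  groups <- lapply(groups, function(g) {
    if (all(c("tracer", "mean", "sd", "n") %in% names(g))) {
      g[g$tracer %in% tracers, , drop = FALSE]
    } else {
      g[tracers]
    }
  })
  ss <- source_set(node = node, groups = groups, classes = classes)
  node_model_spec(ss, tracers = tracers,
                  levels = mixtures[[node]]$levels, node = node, ...)
}

#' Fit mixing models sequentially over a watershed network
#'
#' Nodes are fitted in topological order so that every upstream node's
#' mixture samples are available as pseudo-source samples downstream. Each
#' node's convergence is gated on the Gelman-Rubin diagnostic; a failing
#' node is automatically retried once with doubled chain length, and a
#' persistent failure halts the run unless `force = TRUE` (the failure stays
#' flagged in the returned object either way).
#'
#' @param graph a [watershed_graph()].
#' @param mixtures named list node -> [tracer_table()].
#' @param sources named list node -> [source_set()] (only nodes with local
#'   groups need an entry).
#' @param alpha,error,concentration,source_fit passed per node (alpha may be
#'   a named list node -> alpha to vary by node).
#' @param tracers optional named list node -> tracer panel.
#' @param mcmc an [mcmc_settings()].
#' @param seed master seed; per-node seeds are derived from it.
#' @param retry automatic single retry with doubled chain length on
#'   convergence failure (default TRUE).
#' @param force continue past persistently unconverged nodes (default FALSE).
#' @return object of class `river_fit`: `fits` (node -> list with `draws`,
#'   `rhat`, `convergence`, `spec`, `settings`), `graph`, `order`, `seed`.
#' @export
fit_network <- function(graph, mixtures, sources, alpha = 1,
                        error = "residual", concentration = NULL,
                        source_fit = "draw", tracers = NULL,
                        mcmc = mcmc_settings(), seed = 1, retry = TRUE,
                        force = FALSE) {
  stopifnot(inherits(graph, "watershed_graph"))
  ord <- unmixing_order(graph)
  set.seed(seed %% .Machine$integer.max)
  node_seeds <- setNames(sample.int(.Machine$integer.max - 1L, length(ord)),
                         ord)
  fits <- list()
  for (node in ord) {
    a <- if (is.list(alpha)) {
      if (!is.null(alpha[[node]])) alpha[[node]] else 1
    } else alpha
    spec <- assemble_node_sources(graph, node, mixtures, sources,
                                  tracers = tracers[[node]], alpha = a,
                                  error = error,
                                  concentration = concentration,
                                  source_fit = source_fit)
    st <- mcmc
    draws <- run_mcmc(spec, mixtures[[node]], settings = st,
                      seed = node_seeds[[node]])
    rhat <- gelman_rubin(draws)
    conv <- check_convergence(rhat)
    retried <- FALSE
    if (!conv$pass && retry) {
      st <- mcmc_settings(chain_length = 2L * mcmc$chain_length,
                          burn = mcmc$burn, thin = mcmc$thin,
                          chains = mcmc$chains)
      draws <- run_mcmc(spec, mixtures[[node]], settings = st,
                        seed = (node_seeds[[node]] + 1L) %% .Machine$integer.max)
      retried <- TRUE
      rhat <- gelman_rubin(draws)
      conv <- check_convergence(rhat)
    }
    if (!conv$pass) {
      msg <- paste0("node ", node, " failed the convergence gate (",
                    conv$n_above, "/", conv$n_total,
                    " variables with Rhat > ", conv$limit, ")",
                    if (retried) " after one retry with doubled chain length")
      if (!force) stop(msg, "; rerun with longer chains or force = TRUE",
                       call. = FALSE)
      warning(msg, call. = FALSE)
    }
    fits[[node]] <- list(draws = draws, rhat = rhat, convergence = conv,
                         spec = spec, settings = st, retried = retried)
  }
  structure(list(fits = fits, graph = graph, order = ord, seed = seed),
            class = "river_fit")
}

#' @export
print.river_fit <- function(x, ...) {
  cat("Sequential network fit:", length(x$fits), "node(s) in order",
      paste(x$order, collapse = " -> "), "\n")
  for (node in x$order) {
    f <- x$fits[[node]]
    cat(sprintf("  %s: sources [%s], %s\n", node,
                paste(f$spec$sources, collapse = ", "),
                if (f$convergence$pass) "converged" else "NOT CONVERGED"))
  }
  invisible(x)
}

#' @export
summary.river_fit <- function(object, ...) {
  do.call(rbind, lapply(object$order, function(node) {
    summary(object$fits[[node]]$draws)
  }))
}

# Pool same-class source groups across the watershed into one group per
# ultimate class. Raw groups are concatenated; summary groups are combined
# with exact pooled mean/SD formulas.
pool_sources <- function(graph, sources, tracers = NULL) {
  by_class <- split(names(graph$group_classes), unname(graph$group_classes))
  find_group <- function(g) {
    for (ss in sources) if (g %in% names(ss$groups)) return(ss$groups[[g]])
    NULL
  }
  groups <- list()
  for (cl in names(by_class)) {
    members <- lapply(by_class[[cl]], find_group)
    members <- members[!vapply(members, is.null, TRUE)]
    if (length(members) == 0) {
      stop("ultimate class ", cl, " present in no sub-watershed",
           call. = FALSE)
    }
    types <- vapply(members, function(g) g$type, "")
    if (all(types == "raw")) {
      groups[[cl]] <- do.call(rbind, lapply(members, function(g) g$samples))
    } else {
      stats <- lapply(members, function(g) {
        if (g$type == "summary") return(g$stats)
        data.frame(tracer = names(g$samples),
                   mean = vapply(g$samples, mean, 0),
                   sd = vapply(g$samples, sd, 0), n = nrow(g$samples))
      })
      all_tr <- Reduce(intersect, lapply(stats, function(s) s$tracer))
      pooled <- do.call(rbind, lapply(all_tr, function(tr) {
        rows <- do.call(rbind, lapply(stats, function(s) s[s$tracer == tr, ]))
        n <- sum(rows$n)
        m <- sum(rows$n * rows$mean) / n
        ssq <- sum((rows$n - 1) * rows$sd^2 + rows$n * rows$mean^2)
        data.frame(tracer = tr, mean = m,
                   sd = sqrt(max(ssq - n * m^2, 0) / (n - 1)), n = n)
      }))
      groups[[cl]] <- pooled
    }
  }
  source_set(node = "pooled", groups = groups,
             classes = setNames(names(groups), names(groups)))
}

#' Pooled-source baseline model
#'
#' The non-hierarchical baseline: source groups of the same ultimate class
#' are merged across sub-watersheds into a single basin-wide group per
#' class, and the chosen node mixtures are unmixed against those pooled
#' classes in one model, ignoring the network structure.
#'
#' @param graph a [watershed_graph()].
#' @param mixtures named list node -> [tracer_table()].
#' @param sources named list node -> [source_set()].
#' @param nodes mixture nodes to include (default: all with data).
#' @param factor `"node"` (each node gets its own proportion simplex),
#'   `"level"` (use the tables' own factor levels) or `"none"`.
#' @param tracers tracer panel (default: shared by all inputs).
#' @param ... passed to [mixfit()] (`alpha`, `error`, `mcmc`, `seed`, ...).
#' @return a `mixfit` whose sources are the ultimate classes.
#' @export
pooled_fit <- function(graph, mixtures, sources,
                       nodes = names(mixtures),
                       factor = c("node", "level", "none"),
                       tracers = NULL, ...) {
  factor <- match.arg(factor)
  stopifnot(length(nodes) >= 1)
  if (length(nodes) == 1 && factor == "node") factor <- "none"
  rows <- do.call(rbind, lapply(nodes, function(nd) {
    d <- mixtures[[nd]]$data
    d$.node <- nd
    d
  }))
  lev <- switch(factor, node = rows$.node, level = rows$.level,
                none = rep("all", nrow(rows)))
  pooled <- pool_sources(graph, sources)
  if (is.null(tracers)) {
    tracers <- Reduce(intersect,
                      c(list(pooled$tracers),
                        lapply(nodes, function(nd) mixtures[[nd]]$tracers)))
  }
  df <- rows[tracers]
  df$level <- lev
  mt <- tracer_table(df, node = paste(nodes, collapse = "+"),
                     tracers = tracers, factor = "level")
  mixfit(mt, pooled, tracers = tracers, ...)
}
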