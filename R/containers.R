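# S3 containers for tracer data, stratified sources and watershed topology.

#' Mixture tracer table for one river-network node
#'
#' Holds the sediment-mixture tracer measurements collected at a single
#' sampling node, one row per sample, one column per tracer (element
#' concentrations in mg/kg, oxide percentages, or delta13C of fatty acids in
#' per mil), plus an optional fixed factor such as sediment type or season.
#'
#' Rows with a missing value in any panel tracer are dropped with a warning;
#' an empty table is an error.
#'
#' @param data data.frame of samples.
#' @param node node label, e.g. `"M1"`.
#' @param tracers character vector naming the tracer columns of `data`.
#' @param factor name of the factor column in `data`, or `NULL` for a single
#'   level `"all"`.
#' @param units optional units string or named vector (metadata only).
#' @return An object of class `tracer_table` with elements `node`, `data`
#'   (columns `.sample`, `.level`, then tracers), `tracers`, `levels`, `units`.
#' @export
tracer_table <- function(data, node = "M", tracers, factor = NULL,
                         units = NULL) {
  stopifnot(is.data.frame(data), is.character(tracers), length(tracers) >= 1)
  missing_cols <- setdiff(tracers, names(data))
  if (length(missing_cols) > 0) {
    stop("tracer column(s) missing from table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.null(factor)) {
    if (!factor %in% names(data)) {
      stop("factor column missing from table: ", factor, call. = FALSE)
    }
    level <- as.character(data[[factor]])
  } else {
    level <- rep("all", nrow(data))
  }
  vals <- data[tracers]
  for (j in tracers) vals[[j]] <- as.numeric(vals[[j]])
  keep <- complete.cases(vals)
  if (any(!keep)) {
    warning(sprintf("dropping %d sample(s) with missing tracer values at node %s: %s",
                    sum(!keep), node,
                    paste(rownames(data)[!keep], collapse = ", ")),
            call. = FALSE)
  }
  vals <- vals[keep, , drop = FALSE]
  level <- level[keep]
  if (nrow(vals) < 1) stop("tracer table for node ", node,
                           " has no complete samples", call. = FALSE)
  out <- data.frame(.sample = seq_len(nrow(vals)), .level = level,
                    vals, check.names = FALSE)
  structure(list(node = node, data = out, tracers = tracers,
                 levels = unique(level), units = units),
            class = "tracer_table")
}

#' @export
print.tracer_table <- function(x, ...) {
  cat("Tracer table: node", x$node, "-", nrow(x$data), "sample(s),",
      length(x$tracers), "tracer(s)\n")
  cat("  levels:", paste(x$levels, collapse = ", "), "\n")
  cat("  tracers:", paste(x$tracers, collapse = ", "), "\n")
  invisible(x)
}

#' Stratified source groups for one node
#'
#' A set of source groups (e.g. land-use classes sampled within one
#' sub-watershed) against which a node's mixture is unmixed. Each group holds
#' either raw samples (data.frame, columns = tracers) or summary statistics
#' (data.frame with columns `tracer`, `mean`, `sd`, `n`).
#'
#' @param node node label the sources belong to.
#' @param groups named list of data.frames (raw samples or summaries).
#' @param classes named character vector mapping group name to ultimate
#'   source class; defaults to each group being its own class.
#' @return Object of class `source_set`: `node`, `groups` (each a list with
#'   `type` ("raw"/"summary") and `samples` or `stats`), `tracers`, `classes`.
#' @export
source_set <- function(node = "M", groups, classes = NULL) {
  stopifnot(is.list(groups), length(groups) >= 1)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("source groups must be named", call. = FALSE)
  }
  parsed <- lapply(names(groups), function(g) {
    df <- groups[[g]]
    if (inherits(df, "source_group")) return(df)
    stopifnot(is.data.frame(df))
    if (all(c("tracer", "mean", "sd", "n") %in% names(df))) {
      if (any(df$n < 2)) {
        stop("group ", g, ": n < 2 in summary mode (SD undefined)",
             call. = FALSE)
      }
      if (any(df$sd < 0)) stop("group ", g, ": negative SD", call. = FALSE)
      structure(list(type = "summary",
                     stats = df[c("tracer", "mean", "sd", "n")]),
                class = "source_group")
    } else {
      vals <- df[vapply(df, is.numeric, logical(1))]
      keep <- complete.cases(vals)
      if (any(!keep)) {
        warning("group ", g, ": dropping ", sum(!keep),
                " sample(s) with missing values", call. = FALSE)
        vals <- vals[keep, , drop = FALSE]
      }
      if (nrow(vals) < 2) {
        stop("group ", g, ": fewer than 2 complete samples", call. = FALSE)
      }
      structure(list(type = "raw", samples = vals), class = "source_group")
    }
  })
  names(parsed) <- names(groups)
  panels <- lapply(parsed, function(g) {
    sort(if (g$type == "raw") names(g$samples) else g$stats$tracer)
  })
  if (length(unique(panels)) != 1) {
    stop("tracer panel mismatch across source groups: ",
         paste(vapply(panels, paste, "", collapse = ","), collapse = " vs "),
         call. = FALSE)
  }
  tracers <- if (parsed[[1]]$type == "raw") names(parsed[[1]]$samples)
             else parsed[[1]]$stats$tracer
  if (is.null(classes)) {
    classes <- setNames(names(parsed), names(parsed))
  }
  if (!all(names(parsed) %in% names(classes))) {
    stop("every source group needs an ultimate class mapping", call. = FALSE)
  }
  structure(list(node = node, groups = parsed, tracers = tracers,
                 classes = classes[names(parsed)]),
            class = "source_set")
}

#' @export
print.source_set <- function(x, ...) {
  cat("Source set: node", x$node, "-", length(x$groups), "group(s),",
      length(x$tracers), "tracer(s)\n")
  for (g in names(x$groups)) {
    grp <- x$groups[[g]]
    n <- if (grp$type == "raw") nrow(grp$samples) else grp$stats$n[1]
    cat(sprintf("  %s (class %s): %s, n = %s\n", g, x$classes[[g]],
                grp$type, n))
  }
  invisible(x)
}

#' Per-group sample sizes of a source set
#' @param x a `source_set`.
#' @return named integer vector.
#' @export
source_sizes <- function(x) {
  stopifnot(inherits(x, "source_set"))
  vapply(x$groups, function(g) {
    as.integer(if (g$type == "raw") nrow(g$samples) else g$stats$n[1])
  }, integer(1))
}

# Summary statistics (mean, sd, n) per group x tracer, computing them from
# raw samples where needed. Returns list(mean, sd: K x J matrices; n: K).
source_summaries <- function(x, tracers = x$tracers) {
  K <- length(x$groups)
  J <- length(tracers)
  m <- s <- matrix(NA_real_, K, J,
                   dimnames = list(names(x$groups), tracers))
  n <- setNames(numeric(K), names(x$groups))
  for (k in seq_len(K)) {
    g <- x$groups[[k]]
    if (g$type == "raw") {
      sub <- g$samples[tracers]
      m[k, ] <- vapply(sub, mean, 0)
      s[k, ] <- vapply(sub, sd, 0)
      n[k] <- nrow(sub)
    } else {
      idx <- match(tracers, g$stats$tracer)
      if (anyNA(idx)) {
        stop("summary group ", names(x$groups)[k], " lacks tracer(s): ",
             paste(tracers[is.na(idx)], collapse = ", "), call. = FALSE)
      }
      m[k, ] <- g$stats$mean[idx]
      s[k, ] <- g$stats$sd[idx]
      n[k] <- g$stats$n[idx][1]
    }
  }
  list(mean = m, sd = s, n = n)
}

#' Watershed network topology
#'
#' Directed acyclic graph of mixture nodes: edges point downstream (upstream
#' node feeds downstream node), each node may carry local source groups, and
#' every local group maps to one ultimate source class. Optional node areas
#' (km^2, incremental per sub-watershed) are reporting metadata only and
#' never enter inference.
#'
#' @param nodes character vector of node labels.
#' @param edges data.frame with columns `from`, `to` (or NULL for no edges).
#' @param local_sources named list: node -> character vector of group names.
#' @param group_classes named character: group name -> ultimate class.
#' @param classes optional character vector of ultimate class labels
#'   (defaults to unique values of `group_classes`).
#' @param areas optional named numeric vector of incremental areas (km^2).
#' @return Object of class `watershed_graph`.
#' @export
watershed_graph <- function(nodes, edges = NULL, local_sources = list(),
                            group_classes = character(), classes = NULL,
                            areas = NULL) {
  stopifnot(is.character(nodes), length(nodes) >= 1, !anyDuplicated(nodes))
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(from = character(), to = character())
  }
  edges <- as.data.frame(edges)[c("from", "to")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  bad <- setdiff(unique(c(edges$from, edges$to)), nodes)
  if (length(bad) > 0) {
    stop("edge references undeclared node(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  local_sources <- local_sources[intersect(nodes, names(local_sources))]
  for (nd in nodes) {
    ins <- sum(edges$to == nd) + length(local_sources[[nd]])
    if (ins < 1) {
      stop("node ", nd, " has no inputs (no local sources, no upstream edges)",
           call. = FALSE)
    }
  }
  all_groups <- unlist(local_sources, use.names = FALSE)
  clash <- intersect(all_groups, nodes)
  if (length(clash) > 0) {
    stop("source group name(s) clash with node labels: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(all_groups)) {
    stop("source group declared at more than one node: ",
         paste(unique(all_groups[duplicated(all_groups)]), collapse = ", "),
         call. = FALSE)
  }
  unmapped <- setdiff(all_groups, names(group_classes))
  if (length(unmapped) > 0) {
    stop("local group(s) without an ultimate class: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  if (is.null(classes)) classes <- unique(unname(group_classes[all_groups]))
  g <- structure(list(nodes = nodes, edges = edges,
                      local_sources = local_sources,
                      group_classes = group_classes, classes = classes,
                      areas = areas),
                 class = "watershed_graph")
  unmixing_order(g)  # errors on cycles
  g
}

#' @export
print.watershed_graph <- function(x, ...) {
  cat("Watershed graph:", length(x$nodes), "node(s),", nrow(x$edges),
      "edge(s),", length(x$classes), "ultimate class(es)\n")
  for (nd in x$nodes) {
    ups <- x$edges$from[x$edges$to == nd]
    cat(sprintf("  %s <- [%s]%s\n", nd,
                paste(c(ups, x$local_sources[[nd]]), collapse = ", "),
                if (!is.null(x$areas) && nd %in% names(x$areas))
                  sprintf("  (%.2f km2)", x$areas[[nd]]) else ""))
  }
  invisible(x)
}

# Upstream (parent) nodes feeding `node`, sorted for determinism.
upstream_nodes <- function(graph, node) {
  sort(graph$edges$from[graph$edges$to == node])
}

#' Fractional area share of a node within the watershed above another node
#'
#' Computes the incremental area of `node` divided by the total contributing
#' area above (and including) node `at`, in percent. Purely descriptive: used
#' to compare apportionment against sub-watershed size.
#'
#' @param graph a `watershed_graph` with `areas` set.
#' @param node node whose share is wanted.
#' @param at reference node (default: last node in topological order, i.e.
#'   the outlet).
#' @return percentage (0-100).
#' @export
area_share <- function(graph, node, at = NULL) {
  stopifnot(inherits(graph, "watershed_graph"))
  if (is.null(graph$areas)) stop("graph has no node areas", call. = FALSE)
  ord <- unmixing_order(graph)
  if (is.null(at)) at <- ord[length(ord)]
  stopifnot(node %in% graph$nodes, at %in% graph$nodes)
  anc <- at
  repeat {
    more <- unique(c(anc, graph$edges$from[graph$edges$to %in% anc]))
    if (length(more) == length(anc)) break
    anc <- more
  }
  if (!node %in% anc) stop(node, " is not upstream of ", at, call. = FALSE)
  areas <- graph$areas[anc]
  areas[is.na(areas)] <- 0
  100 * graph$areas[[node]] / sum(areas)
}

#' MCMC settings
#'
#' Defaults follow common practice for these models on field data: chain
#' length 1e6, burn-in 7e5, thinning 300, 3 chains, which retains
#' `floor((1e6 - 7e5)/300) = 1000` draws per chain. For tests and synthetic
#' studies a shorter profile (e.g. `mcmc_settings(50000, 25000, 25, 3)`) is
#' adequate.
#'
#' @param chain_length iterations per chain.
#' @param burn burn-in iterations discarded (must be `< chain_length`).
#' @param thin thinning interval (>= 1).
#' @param chains number of chains (>= 2 so convergence can be diagnosed).
#' @return object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chain_length = 1e6, burn = 7e5, thin = 300,
                          chains = 3) {
  stopifnot(burn >= 0, burn < chain_length, thin >= 1, chains >= 2)
  structure(list(chain_length = as.integer(chain_length),
                 burn = as.integer(burn), thin = as.integer(thin),
                 chains = as.integer(chains)),
            class = "mcmc_settings")
}

#' Retained draws per chain implied by MCMC settings
#' @param settings an `mcmc_settings` object.
#' @return integer: `floor((chain_length - burn)/thin)`.
#' @export
retained_draws <- function(settings) {
  as.integer((settings$chain_length - settings$burn) %/% settings$thin)
}
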