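# CSV / YAML / JSON input-output and report rendering.
#
# CSV dialect: comma-separated, UTF-8, header row required, decimal point.

#' Load a mixture tracer table from CSV
#'
#' @param path CSV file, one row per sediment sample.
#' @param tracers character vector of tracer column names (the panel).
#' @param factor name of a factor column (e.g. `"type"`, `"season"`), or
#'   `NULL` for a single level `"all"`.
#' @param node node label to attach (default: file name without extension).
#' @return a [tracer_table()].
#' @export
load_mixture_table <- function(path, tracers, factor = NULL, node = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("empty mixture table: ", path, call. = FALSE)
  if (is.null(node)) node <- sub("\\.[^.]*$", "", basename(path))
  tracer_table(df, node = node, tracers = tracers, factor = factor)
}

#' Write a mixture tracer table to CSV
#' @param x a `tracer_table`.
#' @param path output CSV.
#' @export
write_mixture_table <- function(x, path) {
  stopifnot(inherits(x, "tracer_table"))
  df <- x$data
  names(df)[names(df) == ".level"] <- "level"
  df$.sample <- NULL
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load a source-sample table from CSV
#'
#' Raw mode expects one row per source sample with a `group` column and one
#' column per tracer. Summary mode expects long format with columns `group`,
#' `tracer`, `mean`, `sd`, `n`.
#'
#' @param path CSV file.
#' @param mode `"raw"` or `"summary"`.
#' @param tracers tracer panel; default (raw mode): all numeric columns.
#' @param classes named character group -> ultimate class (optional).
#' @param node node label (default from file name).
#' @return a [source_set()].
#' @export
load_source_table <- function(path, mode = c("raw", "summary"),
                              tracers = NULL, classes = NULL, node = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  if (is.null(node)) node <- sub("\\.[^.]*$", "", basename(path))
  if (!"group" %in% names(df)) {
    stop("source table needs a 'group' column: ", path, call. = FALSE)
  }
  if (mode == "raw") {
    if (is.null(tracers)) {
      tracers <- names(df)[vapply(df, is.numeric, logical(1))]
    }
    missing_cols <- setdiff(tracers, names(df))
    if (length(missing_cols) > 0) {
      stop("source table missing tracer column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    groups <- split(df[tracers], df$group)
  } else {
    need <- c("tracer", "mean", "sd", "n")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols) > 0) {
      stop("summary source table missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    groups <- split(df[need], df$group)
  }
  source_set(node = node, groups = groups, classes = classes)
}

#' Write a source set to CSV (raw or summary layout, matching its contents)
#' @param x a `source_set`.
#' @param path output CSV.
#' @export
write_source_table <- function(x, path) {
  stopifnot(inherits(x, "source_set"))
  types <- vapply(x$groups, function(g) g$type, "")
  if (all(types == "raw")) {
    rows <- lapply(names(x$groups), function(g) {
      cbind(group = g, x$groups[[g]]$samples)
    })
  } else if (all(types == "summary")) {
    rows <- lapply(names(x$groups), function(g) {
      cbind(group = g, x$groups[[g]]$stats)
    })
  } else {
    stop("cannot serialise a source set mixing raw and summary groups",
         call. = FALSE)
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Load a concentration table (source group x tracer) from CSV
#'
#' Concentrations weight source proportions tracer-by-tracer so that
#' tracer-space and mass-space proportions stay consistent; they must be
#' strictly positive and share one mass unit across groups.
#'
#' @param path CSV with a `group` column and one column per tracer.
#' @return numeric matrix, rownames = groups, colnames = tracers.
#' @export
load_concentration_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  if (!"group" %in% names(df)) {
    stop("concentration table needs a 'group' column", call. = FALSE)
  }
  m <- as.matrix(df[setdiff(names(df), "group")])
  rownames(m) <- df$group
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("concentrations must be strictly positive and finite", call. = FALSE)
  }
  m
}

#' Load a watershed network configuration (YAML or JSON)
#'
#' Expected keys: `nodes` (list), `edges` (list of `{from, to}`),
#' `local_sources` (node -> group list), `group_classes` (group -> class),
#' optional `classes` and `areas`. Validates acyclicity and that every
#' referenced group is declared.
#'
#' @param path `.yml`/`.yaml` or `.json` file.
#' @return a [watershed_graph()].
#' @export
load_network_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  edges <- cfg$edges
  if (!is.null(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) {
      data.frame(from = e$from, to = e$to)
    }))
  }
  watershed_graph(nodes = unlist(cfg$nodes),
                  edges = edges,
                  local_sources = lapply(cfg$local_sources, unlist),
                  group_classes = unlist(cfg$group_classes),
                  classes = if (!is.null(cfg$classes)) unlist(cfg$classes),
                  areas = if (!is.null(cfg$areas)) unlist(cfg$areas))
}

#' Write a watershed graph to YAML (or JSON)
#' @param graph a `watershed_graph`.
#' @param path output path; format chosen by extension.
#' @export
write_network_config <- function(graph, path) {
  stopifnot(inherits(graph, "watershed_graph"))
  cfg <- list(nodes = as.list(graph$nodes),
              edges = lapply(seq_len(nrow(graph$edges)), function(i) {
                list(from = graph$edges$from[i], to = graph$edges$to[i])
              }),
              local_sources = lapply(graph$local_sources, as.list),
              group_classes = as.list(graph$group_classes),
              classes = as.list(graph$classes))
  if (!is.null(graph$areas)) cfg$areas <- as.list(graph$areas)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Render an apportionment summary as a "mean +/- SD" report
#'
#' Formats posterior proportions to two decimals in the conventional
#' `"0.52 ± 0.14"` style, rows grouped by node then source. If `path` is
#' given, writes both a plain-text report (`<path>.txt`) and a
#' machine-readable CSV twin (`<path>.csv`).
#'
#' @param summary data.frame with columns `node`, `level`, `source`, `mean`,
#'   `sd` (extra columns are carried into the CSV twin).
#' @param path output stem, or `NULL` to only return the text.
#' @return character vector of report lines, invisibly.
#' @export
render_apportionment_table <- function(summary, path = NULL) {
  need <- c("node", "level", "source", "mean", "sd")
  stopifnot(all(need %in% names(summary)))
  lines <- sprintf("%-10s %-10s %-12s %s", "node", "level", "source",
                   "proportion")
  if (nrow(summary) > 0) {
    ord <- order(match(summary$node, unique(summary$node)),
                 match(summary$source, unique(summary$source)),
                 match(summary$level, unique(summary$level)))
    s <- summary[ord, ]
    lines <- c(lines, sprintf("%-10s %-10s %-12s %.2f ± %.2f",
                              s$node, s$level, s$source, s$mean, s$sd))
  } else {
    s <- summary
  }
  if (!is.null(path)) {
    writeLines(lines, paste0(path, ".txt"))
    write.csv(s, paste0(path, ".csv"), row.names = FALSE)
  }
  invisible(lines)
}
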