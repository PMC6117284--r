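# Tracer screening: range tests, one-way ANOVA + Tukey HSD, normality EDA.
#
# Screening precedes model fitting: tracers whose mixture values fall
# largely outside the span of the pooled source samples are treated as
# non-conservative (altered during transport) and removed from the panel.

#' Range test of mixture tracer values against pooled source samples
#'
#' For every tracer, computes bounds over all source samples pooled across
#' groups at the node and the fraction of mixture samples falling inside
#' them. A tracer passes if that fraction is at least `threshold`.
#'
#' @param sources a [source_set()] (raw samples; for summary-only groups set
#'   `summary_bounds = "mean_pm_2sd"` to opt in to mean +/- 2 SD bounds).
#' @param mixtures a [tracer_table()].
#' @param threshold minimum inside fraction to pass (default 0.5, i.e.
#'   "largely outside" means more than half the mixture samples outside).
#' @param bounds `"minmax"` (default) or `"iqr"` for boxplot-whisker bounds
#'   (1.5 x IQR beyond the quartiles).
#' @param summary_bounds `"error"` (default) or `"mean_pm_2sd"`.
#' @return data.frame of class `range_test` with one row per tracer:
#'   `tracer`, `source_min`, `source_max`, `in_range_fraction`, `pass`; the
#'   per-sample inside flags are in `attr(, "inside")`.
#' @export
range_test <- function(sources, mixtures, threshold = 0.5,
                       bounds = c("minmax", "iqr"),
                       summary_bounds = c("error", "mean_pm_2sd")) {
  bounds <- match.arg(bounds)
  summary_bounds <- match.arg(summary_bounds)
  stopifnot(inherits(sources, "source_set"), inherits(mixtures, "tracer_table"),
            threshold >= 0, threshold <= 1)
  tracers <- intersect(mixtures$tracers, sources$tracers)
  if (length(tracers) == 0) stop("no shared tracers", call. = FALSE)
  types <- vapply(sources$groups, function(g) g$type, "")
  inside <- matrix(NA, nrow(mixtures$data), length(tracers),
                   dimnames = list(NULL, tracers))
  out <- data.frame(tracer = tracers, source_min = NA_real_,
                    source_max = NA_real_, in_range_fraction = NA_real_,
                    pass = NA)
  for (j in seq_along(tracers)) {
    tr <- tracers[j]
    if (all(types == "raw")) {
      pooled <- unlist(lapply(sources$groups, function(g) g$samples[[tr]]))
      if (bounds == "minmax") {
        lo <- min(pooled); hi <- max(pooled)
      } else {
        q <- quantile(pooled, c(0.25, 0.75), names = FALSE)
        iqr <- q[2] - q[1]
        lo <- q[1] - 1.5 * iqr; hi <- q[2] + 1.5 * iqr
      }
    } else if (summary_bounds == "mean_pm_2sd") {
      ss <- source_summaries(sources, tr)
      lo <- min(ss$mean - 2 * ss$sd); hi <- max(ss$mean + 2 * ss$sd)
    } else {
      stop("summary-mode sources have no raw samples for range bounds; ",
           "opt in with summary_bounds = \"mean_pm_2sd\"", call. = FALSE)
    }
    y <- mixtures$data[[tr]]
    inside[, j] <- y >= lo & y <= hi
    out$source_min[j] <- lo
    out$source_max[j] <- hi
    out$in_range_fraction[j] <- mean(inside[, j])
    out$pass[j] <- out$in_range_fraction[j] >= threshold
  }
  attr(out, "inside") <- inside
  attr(out, "threshold") <- threshold
  class(out) <- c("range_test", "data.frame")
  out
}

#' Classical one-way fixed-effects ANOVA
#'
#' Used to assess whether a tracer discriminates the source groups
#' (significance conventionally judged at p < 0.05).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, plus group means and the within mean square.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (var(x) == 0) stop("all values identical: zero variance", call. = FALSE)
  tab <- anova(lm(x ~ g))
  if (tab["Residuals", "Mean Sq"] == 0) {
    stop("zero within-group variance", call. = FALSE)
  }
  structure(list(F = tab["g", "F value"],
                 df_between = tab["g", "Df"],
                 df_within = tab["Residuals", "Df"],
                 p = tab["g", "Pr(>F)"],
                 means = vapply(groups, mean, 0),
                 msw = tab["Residuals", "Mean Sq"]),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise group comparisons on the studentized-range distribution with
#' the ANOVA within-group degrees of freedom; unbalanced designs use the
#' Tukey-Kramer form.
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return data.frame of class `tukey_result`: `pair`, `diff`, `q`,
#'   `p_adj`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  aov_res <- one_way_anova(groups)
  k <- length(groups)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("g", seq_len(k))
  n <- vapply(groups, length, 1L)
  m <- aov_res$means
  pairs <- utils::combn(k, 2)
  res <- data.frame(pair = character(ncol(pairs)), diff = NA_real_,
                    q = NA_real_, p_adj = NA_real_, significant = NA)
  for (idx in seq_len(ncol(pairs))) {
    i <- pairs[1, idx]; jj <- pairs[2, idx]
    se <- sqrt(aov_res$msw / 2 * (1 / n[i] + 1 / n[jj]))
    q <- abs(m[i] - m[jj]) / se
    p <- ptukey(q, nmeans = k, df = aov_res$df_within, lower.tail = FALSE)
    res$pair[idx] <- paste(nms[jj], nms[i], sep = "-")
    res$diff[idx] <- m[jj] - m[i]
    res$q[idx] <- q
    res$p_adj[idx] <- p
    res$significant[idx] <- p < alpha
  }
  attr(res, "alpha") <- alpha
  class(res) <- c("tukey_result", "data.frame")
  res
}

#' Normality EDA summary per group
#'
#' Descriptive only: mixture tracer values are weighted combinations of
#' source means, so approximate normality is expected by the central limit
#' theorem; these summaries support eyeballing, they are never a filter.
#'
#' @param groups named list of numeric vectors.
#' @return data.frame: group, n, mean, sd, skewness, shapiro_p (NA if n < 3).
#' @export
normality_eda <- function(groups) {
  stopifnot(is.list(groups))
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("g", seq_along(groups))
  do.call(rbind, lapply(seq_along(groups), function(i) {
    x <- groups[[i]]
    sk <- if (length(x) > 2 && sd(x) > 0) {
      mean((x - mean(x))^3) / sd(x)^3
    } else NA_real_
    sp <- if (length(x) >= 3 && length(x) <= 5000 && sd(x) > 0) {
      shapiro.test(x)$p.value
    } else NA_real_
    data.frame(group = nms[i], n = length(x), mean = mean(x), sd = sd(x),
               skewness = sk, shapiro_p = sp)
  }))
}

#' Screening policy
#' @param threshold range-test pass threshold.
#' @param bounds `"minmax"` or `"iqr"`.
#' @param include tracers to force-retain regardless of the range test.
#' @param exclude tracers to remove even if they pass (expert judgement,
#'   e.g. elements sensitive to hydraulic sorting).
#' @return list of class `screen_policy`.
#' @export
screen_policy <- function(threshold = 0.5, bounds = "minmax",
                          include = character(), exclude = character()) {
  structure(list(threshold = threshold, bounds = bounds,
                 include = include, exclude = exclude),
            class = "screen_policy")
}

#' Screen a tracer panel for a node
#'
#' Applies the range test, then any manual include/exclude overrides from
#' the policy (overrides are applied after the automatic step and flagged in
#' the report).
#'
#' @param sources a [source_set()].
#' @param mixtures a [tracer_table()].
#' @param policy a [screen_policy()].
#' @return list of class `screening`: `retained` (character), `report`
#'   (data.frame: tracer, bounds, fraction, pass, decision, reason).
#' @export
screen_panel <- function(sources, mixtures, policy = screen_policy()) {
  stopifnot(inherits(policy, "screen_policy"))
  rt <- range_test(sources, mixtures, threshold = policy$threshold,
                   bounds = policy$bounds)
  report <- data.frame(tracer = rt$tracer, source_min = rt$source_min,
                       source_max = rt$source_max,
                       fraction = rt$in_range_fraction, pass = rt$pass,
                       decision = ifelse(rt$pass, "retain", "drop"),
                       reason = ifelse(rt$pass, "range test passed",
                                       "mixture largely outside source range"))
  for (tr in intersect(policy$include, report$tracer)) {
    i <- report$tracer == tr
    if (report$decision[i] == "drop") {
      report$decision[i] <- "retain"
      report$reason[i] <- "manual include override"
    }
  }
  for (tr in intersect(policy$exclude, report$tracer)) {
    i <- report$tracer == tr
    report$decision[i] <- "drop"
    report$reason[i] <- "manual exclude override"
  }
  retained <- report$tracer[report$decision == "retain"]
  if (length(retained) == 0) {
    stop("all tracers eliminated by screening; review the threshold or ",
         "bounds policy", call. = FALSE)
  }
  structure(list(retained = retained, report = report), class = "screening")
}

#' @export
print.screening <- function(x, ...) {
  cat("Tracer screening:", length(x$retained), "of", nrow(x$report),
      "retained\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
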