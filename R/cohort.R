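#' Per-region means of a metric map
#'
#' Unweighted arithmetic mean of node values within each of the four
#' regions. On the structured tubes used here node density is nearly
#' uniform, so area weighting would change means by well under 1%.
#'
#' @param map `metric_map` (or numeric vector).
#' @param labels `region_labels` covering the same nodes.
#' @return named numeric, one mean per region level.
#' @export
region_means <- function(map, labels) {
  x <- as.numeric(map)
  if (length(x) != length(labels$label))
    stop("map and labels cover different node counts")
  counts <- table(labels$label)
  if (any(counts == 0L))
    stop("empty region(s): ",
         paste(names(counts)[counts == 0L], collapse = ", "))
  out <- tapply(x, labels$label, mean)
  stats::setNames(as.numeric(out[region_levels()]), region_levels())
}

#' Region-metric table for a synthetic cohort
#'
#' Computes all seven metric maps for every vessel of the cohort (LSI/HSI
#' thresholds calibrated per mouse from its own contralateral control, or
#' pooled over all controls), optionally display-normalizes each metric to
#' [0, 1] using cohort-wide observed maxima where no theoretical maximum
#' exists, and reduces to per-region means - the per-mouse raw-value table
#' underlying the regional bar comparisons.
#'
#' @param cohort a `synthetic_cohort`.
#' @param threshold_mode `"per_mouse"` (default) or `"pooled"`.
#' @param normalize display-normalize before averaging (default `TRUE`).
#' @return data.frame with columns `mouse_id`, `vessel`, `region`,
#'   `metric`, `mean_value`; attribute `observed_max` records the divisors
#'   used.
#' @export
cohort_region_table <- function(cohort,
                                threshold_mode = c("per_mouse", "pooled"),
                                normalize = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  threshold_mode <- match.arg(threshold_mode)
  mice <- cohort$mice
  pooled_thr <- NULL
  if (threshold_mode == "pooled") {
    all_ctrl <- unlist(lapply(mice, function(m)
      as.numeric(tawss(m$control$field))))
    pooled_thr <- fit_thresholds(all_ctrl)
  }
  # adjacency depends only on the mesh topology, shared across the cohort
  adj_cache <- list()
  metrics <- lapply(mice, function(m) {
    thr <- if (is.null(pooled_thr))
      fit_thresholds(tawss(m$control$field)) else pooled_thr
    out <- list()
    for (v in c("instrumented", "control")) {
      key <- paste(nrow(m[[v]]$mesh$nodes), nrow(m[[v]]$mesh$triangles))
      if (is.null(adj_cache[[key]]))
        adj_cache[[key]] <<- node_neighbors(m[[v]]$mesh)
      out[[v]] <- compute_metrics(m[[v]]$field, thr, adj_cache[[key]])
    }
    out
  })
  obs_max <- c(TAWSS = NA_real_, tSS = NA_real_, RRT = NA_real_)
  if (normalize) {
    for (mm in c("TAWSS", "tSS", "RRT")) {
      vals <- unlist(lapply(metrics, function(m)
        c(as.numeric(m$instrumented[[mm]]), as.numeric(m$control[[mm]]))))
      obs_max[[mm]] <- max(vals[is.finite(vals)])
    }
  }
  rows <- list()
  for (mi in seq_along(mice)) {
    for (v in c("instrumented", "control")) {
      lab <- mice[[mi]][[v]]$labels
      for (mm in metric_names()) {
        map <- metrics[[mi]][[v]][[mm]]
        if (normalize)
          map <- normalize_display(map, observed_max = obs_max[mm])
        rm_ <- region_means(map, lab)
        rows[[length(rows) + 1L]] <- data.frame(
          mouse_id = names(mice)[mi], vessel = v,
          region = names(rm_), metric = mm, mean_value = as.numeric(rm_))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "observed_max") <- obs_max
  out
}

#' Floor near-zero values and scale by the control cohort mean
#'
#' To compare instrumented against control vessels, per-mouse region means
#' at or near zero are first set to the small non-zero floor 0.005 (to
#' avoid ratio blow-up when dividing by near-zero control values), then
#' every value is divided by the cohort mean of the control values for that
#' (region, metric). Scaled control values therefore average to exactly 1
#' in every (region, metric) cell.
#'
#' @param table data.frame from [cohort_region_table()].
#' @param floor replacement floor (default 0.005).
#' @return the table with `mean_value` floored and a `scaled_value` column
#'   added.
#' @export
floor_and_scale <- function(table, floor = 0.005) {
  need <- c("mouse_id", "vessel", "region", "metric", "mean_value")
  if (!all(need %in% names(table))) stop("malformed region-metric table")
  # every (mouse, region, metric) must have both vessels
  key <- paste(table$mouse_id, table$region, table$metric)
  both <- tapply(table$vessel, key, function(v)
    all(c("instrumented", "control") %in% v))
  if (any(!both)) {
    miss <- strsplit(names(both)[!both][1L], " ")[[1L]]
    stop("missing vessel pair for mouse ", miss[1L])
  }
  table$mean_value <- pmax(table$mean_value, floor)
  cm_key <- paste(table$region, table$metric)
  ctrl <- table$vessel == "control"
  cmeans <- tapply(table$mean_value[ctrl], cm_key[ctrl], mean)
  table$scaled_value <- table$mean_value / as.numeric(cmeans[cm_key])
  table
}

#' One-sided two-sample t test (instrumented > control)
#'
#' Tests whether a flow metric is larger in the instrumented vessels than
#' in controls: equal-variance two-sample t statistic with one-sided p for
#' the alternative `instrumented > control` (a paired version is
#' available). If both groups are constant with equal means the test is
#' uninformative and p is 0.5 by convention.
#'
#' @param instr_values,ctrl_values per-mouse values.
#' @param paired use a paired t test (contralateral design).
#' @return list of class `wss_comparison`: `fold_factor`
#'   (mean(instr)/mean(ctrl)), `t_statistic`, `p_one_sided`, `n_pairs`.
#' @export
one_sided_t_test <- function(instr_values, ctrl_values, paired = FALSE) {
  if (length(instr_values) < 2L || length(ctrl_values) < 2L)
    stop("need >= 2 values per group")
  if (paired && length(instr_values) != length(ctrl_values))
    stop("paired test needs equal group sizes")
  res <- tryCatch(
    stats::t.test(instr_values, ctrl_values, alternative = "greater",
                  var.equal = TRUE, paired = paired),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$statistic)) {
    dm <- mean(instr_values) - mean(ctrl_values)
    if (dm == 0) {
      tt <- 0; p <- 0.5
    } else {
      tt <- sign(dm) * Inf; p <- if (dm > 0) 0 else 1
    }
  } else {
    tt <- unname(res$statistic)
    p <- res$p.value
  }
  structure(list(fold_factor = mean(instr_values) / mean(ctrl_values),
                 t_statistic = tt, p_one_sided = p,
                 n_pairs = min(length(instr_values), length(ctrl_values))),
            class = "wss_comparison")
}

#' One-way ANOVA across groups
#'
#' Standard fixed-effects one-way analysis of variance (used for blood
#' velocity and vessel diameter comparisons across vessel groups).
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return list with `F` and `p`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) < 2L))
    stop("need >= 2 groups with >= 2 values each")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep.int(seq_along(groups), lengths(groups)))
  if (stats::var(x) == 0) return(list(F = 0, p = 1))
  res <- stats::oneway.test(x ~ g, var.equal = TRUE)
  Fv <- unname(res$statistic)
  if (!is.finite(Fv)) {
    # zero within-group variance: any between-group difference is infinite
    gm <- vapply(groups, mean, 0)
    if (stats::var(gm) > 0) return(list(F = Inf, p = 0))
    return(list(F = 0, p = 1))
  }
  list(F = Fv, p = unname(res$p.value))
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "")))
}

#' Regional instrumented-vs-control summary of a cohort
#'
#' The full regional comparison: per (region, metric), the cohort means and
#' standard errors of the control-scaled values for both vessels, the
#' one-sided t test for elevation in the instrumented vessel, and
#' significance stars at 0.05 / 0.01 / 0.001. No multiple-testing
#' correction is applied: each metric is compared only between vessels,
#' never across metrics.
#'
#' @param table region-metric table from [cohort_region_table()] (raw;
#'   flooring and scaling are applied here).
#' @param floor near-zero floor passed to [floor_and_scale()].
#' @param paired use a paired t test.
#' @return object of class `wss_cohort_summary`: `table` (floored and
#'   scaled per-mouse values) and `comparisons` (one row per region x
#'   metric).
#' @export
summarize_cohort <- function(table, floor = 0.005, paired = FALSE) {
  tab <- floor_and_scale(table, floor = floor)
  n_mice <- length(unique(tab$mouse_id))
  if (n_mice < 2L) stop("need >= 2 mice")
  comps <- list()
  for (rg in region_levels()) {
    for (mm in metric_names()) {
      sel <- tab$region == rg & tab$metric == mm
      iv <- tab$scaled_value[sel & tab$vessel == "instrumented"]
      cv <- tab$scaled_value[sel & tab$vessel == "control"]
      tt <- one_sided_t_test(iv, cv, paired = paired)
      comps[[length(comps) + 1L]] <- data.frame(
        region = rg, metric = mm,
        mean_instrumented = mean(iv), se_instrumented = stats::sd(iv) / sqrt(length(iv)),
        mean_control = mean(cv), se_control = stats::sd(cv) / sqrt(length(cv)),
        fold_factor = tt$fold_factor, t_statistic = tt$t_statistic,
        p_one_sided = tt$p_one_sided, n_pairs = tt$n_pairs,
        stars = significance_stars(tt$p_one_sided))
    }
  }
  comparisons <- do.call(rbind, comps)
  rownames(comparisons) <- NULL
  structure(list(table = tab, comparisons = comparisons,
                 floor = floor, paired = paired),
            class = "wss_cohort_summary")
}

#' @export
print.wss_cohort_summary <- function(x, digits = 3, ...) {
  cat("Regional instrumented-vs-control comparison",
      sprintf("(%d mice, %s t test)\n",
              length(unique(x$table$mouse_id)),
              if (x$paired) "paired" else "unpaired"))
  df <- x$comparisons
  df$mean_instrumented <- signif(df$mean_instrumented, digits)
  df$fold_factor <- signif(df$fold_factor, digits)
  df$p_one_sided <- signif(df$p_one_sided, digits)
  print(df[, c("region", "metric", "mean_instrumented", "fold_factor",
               "p_one_sided", "stars")], row.names = FALSE)
  invisible(x)
}
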