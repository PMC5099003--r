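#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline in one place, with
#' defaults matching the study conditions the synthetic generator emulates:
#' an 8 Hz cardiac cycle in 300 steps with every 10th step exported, blood
#' viscosity 3.5 mPa s and density 1050 kg/m^3, a 500 to 250 um tapered
#' cuff, instrumented/control mean inlet velocities 112.8 / 153.4 mm/s, a
#' 1.6 mm upstream plaque region, the 0.67 log-SD quantile multiplier for
#' threshold calibration, and the 0.005 near-zero floor for control
#' scaling.
#'
#' @param n_mice cohort size.
#' @param seed master seed.
#' @param instrumented,control `vessel_spec` objects for the two vessels.
#' @param fluid `fluid_props`.
#' @param plaque_extent upstream plaque-region extent (mm).
#' @param floor near-zero floor for control scaling.
#' @param threshold_multiplier log-SD multiplier for LSI/HSI thresholds.
#' @param threshold_mode `"per_mouse"` or `"pooled"` calibration.
#' @param t_test `"unpaired"` or `"paired"`.
#' @param enface_bins integer length-2: axial and circumferential bin
#'   counts of en-face maps.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_mice = 7, seed = 1L,
                            instrumented = vessel_spec(),
                            control = control_vessel_spec(),
                            fluid = fluid_props(),
                            plaque_extent = 1.6, floor = 0.005,
                            threshold_multiplier = 0.67,
                            threshold_mode = c("per_mouse", "pooled"),
                            t_test = c("unpaired", "paired"),
                            enface_bins = c(40L, 12L)) {
  structure(list(
    n_mice = as.integer(n_mice), seed = as.integer(seed),
    instrumented = instrumented, control = control, fluid = fluid,
    plaque_extent = plaque_extent, floor = floor,
    threshold_multiplier = threshold_multiplier,
    threshold_mode = match.arg(threshold_mode),
    t_test = match.arg(t_test),
    enface_bins = as.integer(enface_bins)),
    class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' The configuration round-trips losslessly (numeric values serialized at
#' full precision).
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @return `read_config` returns a `pipeline_config`; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild_spec <- function(s) {
    if (is.null(s)) return(NULL)
    dist <- if (is.null(s$disturbance)) NULL else
      do.call(disturbance_spec, s$disturbance)
    args <- s[setdiff(names(s), "disturbance")]
    args <- args[!vapply(args, is.null, TRUE)]
    sp <- do.call(vessel_spec, c(args, list(disturbance = dist)))
    if (is.null(dist)) sp$disturbance <- NULL
    if (is.null(s$cuff_start)) {
      sp$cuff_start <- NULL
      sp$cuff_end <- NULL
    }
    sp
  }
  pipeline_config(
    n_mice = x$n_mice, seed = x$seed,
    instrumented = rebuild_spec(x$instrumented),
    control = rebuild_spec(x$control),
    fluid = do.call(fluid_props, x$fluid),
    plaque_extent = x$plaque_extent, floor = x$floor,
    threshold_multiplier = x$threshold_multiplier,
    threshold_mode = x$threshold_mode, t_test = x$t_test,
    enface_bins = x$enface_bins)
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

# Small order-independent provenance hash of the serialized config
# (dependency-free; not cryptographic).
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA)
  b <- utf8ToInt(as.character(s))
  h <- 0
  for (i in seq_along(b)) h <- (h * 31 + b[i]) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' En-face projection of a metric map
#'
#' Unwraps the lumen surface onto a 2D (axial x circumferential) grid: each
#' node is binned by its (s, theta) coordinates and each cell takes the
#' mean of its member nodes. Rows run from upstream (bottom) to downstream
#' (top). Empty cells are filled from the nearest occupied cell along the
#' circumferential direction of the same axial row (count recorded in
#' attribute `n_filled`).
#'
#' @param map `metric_map`.
#' @param frame matching `centerline_frame`.
#' @param n_s_bins,n_theta_bins grid resolution.
#' @return object of class `enface_grid`: `values` (n_s_bins x
#'   n_theta_bins matrix), `s_edges`, `theta_edges`, `metric`.
#' @export
enface <- function(map, frame, n_s_bins = 40, n_theta_bins = 12) {
  x <- as.numeric(map)
  s_edges <- seq(0, frame$length, length.out = n_s_bins + 1L)
  t_edges <- seq(0, 2 * pi, length.out = n_theta_bins + 1L)
  si <- pmin(pmax(findInterval(frame$s, s_edges, rightmost.closed = TRUE),
                  1L), n_s_bins)
  ti <- pmin(pmax(findInterval(frame$theta, t_edges,
                               rightmost.closed = TRUE), 1L), n_theta_bins)
  grid <- matrix(NA_real_, n_s_bins, n_theta_bins)
  cell <- (ti - 1L) * n_s_bins + si
  sums <- rowsum_safe(x, cell, n_s_bins * n_theta_bins)
  cnts <- rowsum_safe(rep(1, length(x)), cell, n_s_bins * n_theta_bins)
  grid[] <- ifelse(cnts > 0, sums / cnts, NA_real_)
  n_filled <- 0L
  if (anyNA(grid)) {
    for (r in seq_len(n_s_bins)) {
      row <- grid[r, ]
      na <- which(is.na(row))
      occ <- which(!is.na(row))
      if (length(na) && length(occ)) {
        for (j in na) {
          # circular distance to nearest occupied theta bin
          d <- pmin(abs(occ - j), n_theta_bins - abs(occ - j))
          grid[r, j] <- row[occ[which.min(d)]]
          n_filled <- n_filled + 1L
        }
      }
    }
  }
  structure(list(values = grid, s_edges = s_edges, theta_edges = t_edges,
                 metric = attr(map, "metric"), n_filled = n_filled),
            class = "enface_grid")
}

#' Write / read a WSS field series as CSV
#'
#' Long format, one row per node and exported instant: `node_id`,
#' `t_index`, `t_s`, `tau_x_Pa`, `tau_y_Pa`, `tau_z_Pa`. The cycle period
#' is recovered on read from the uniform instant spacing.
#'
#' @param field a `wss_field`.
#' @param path CSV path.
#' @param mesh the `tri_mesh` the field lives on (its node count must match
#'   the CSV).
#' @return `read_field_csv` returns a `wss_field`; `write_field_csv`
#'   returns `path` invisibly.
#' @export
write_field_csv <- function(field, path) {
  n <- dim(field$vectors)[1L]
  ni <- dim(field$vectors)[3L]
  df <- data.frame(
    node_id = rep(seq_len(n), ni),
    t_index = rep(seq_len(ni), each = n),
    t_s = rep(field$times, each = n),
    tau_x_Pa = as.vector(field$vectors[, 1L, ]),
    tau_y_Pa = as.vector(field$vectors[, 2L, ]),
    tau_z_Pa = as.vector(field$vectors[, 3L, ]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path, mesh) {
  df <- utils::read.csv(path)
  need <- c("node_id", "t_index", "t_s", "tau_x_Pa", "tau_y_Pa", "tau_z_Pa")
  if (!all(need %in% names(df))) stop("malformed field CSV: ", path)
  n <- max(df$node_id)
  if (n != nrow(mesh$nodes))
    stop("field CSV node count (", n, ") does not match mesh (",
         nrow(mesh$nodes), ")")
  ni <- max(df$t_index)
  df <- df[order(df$t_index, df$node_id), ]
  vec <- array(0, c(n, 3L, ni))
  vec[, 1L, ] <- df$tau_x_Pa
  vec[, 2L, ] <- df$tau_y_Pa
  vec[, 3L, ] <- df$tau_z_Pa
  times <- sort(unique(df$t_s))
  dt <- if (ni > 1L) times[2L] - times[1L] else NA_real_
  frame <- parameterize(mesh)
  structure(list(vectors = vec, times = times, period = dt * ni,
                 mesh = mesh, frame = frame), class = "wss_field")
}

#' Write metric maps as CSV
#'
#' @param maps named list of `metric_map`s (e.g. from [compute_metrics()]).
#' @param frame matching `centerline_frame`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_csv <- function(maps, frame, path) {
  rows <- lapply(maps, function(m) data.frame(
    node_id = seq_along(frame$s), s_mm = frame$s, theta_rad = frame$theta,
    metric = attr(m, "metric"), value = as.numeric(m),
    units = attr(m, "units")))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write calibrated thresholds as JSON
#'
#' @param thresholds `tawss_thresholds`.
#' @param path JSON path.
#' @param source free-text provenance label (e.g. the mouse id).
#' @return `path`, invisibly.
#' @export
write_thresholds_json <- function(thresholds, path, source = "control") {
  jsonlite::write_json(list(low_Pa = thresholds$low,
                            high_Pa = thresholds$high,
                            mean_log = thresholds$mean_log,
                            sd_log = thresholds$sd_log, source = source),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full pipeline: simulate, measure, analyze, report
#'
#' Generates the synthetic cohort, writes per-vessel geometry (STL) and WSS
#' field series (CSV), computes and writes all metric maps and per-mouse
#' thresholds, produces the floored/scaled region-metric table and the
#' regional comparison table, en-face grids for the first mouse, and a run
#' log with seeds and a config hash. Outputs are a pure function of the
#' configuration: re-running with the same config reproduces them byte for
#' byte.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @param write_fields write the (large) per-vessel field CSVs; default
#'   `TRUE`.
#' @return the `wss_cohort_summary`, invisibly; files under `out_dir`.
#' @export
run_full_pipeline <- function(config, out_dir, write_fields = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("config_hash: %s", config_hash(config)),
                 sprintf("master_seed: %d", config$seed),
                 sprintf("n_mice: %d", config$n_mice))
  cohort <- synth_cohort(config$n_mice, config$instrumented,
                         config$control, seed = config$seed,
                         fluid = config$fluid,
                         plaque_extent = config$plaque_extent)
  for (nm in names(cohort$mice)) {
    m <- cohort$mice[[nm]]
    log_lines <- c(log_lines, sprintf("%s_seed: %d", nm, m$seed))
    for (v in c("instrumented", "control")) {
      stage <- sprintf("%s/%s", nm, v)
      tryCatch({
        write_stl(m[[v]]$mesh, file.path(out_dir,
                                         sprintf("%s_%s.stl", nm, v)))
        if (write_fields)
          write_field_csv(m[[v]]$field, file.path(
            out_dir, sprintf("%s_%s_field.csv", nm, v)))
      }, error = function(e)
        stop("pipeline stage geometry/field failed for ", stage, ": ",
             conditionMessage(e)))
    }
  }
  tab <- tryCatch(
    cohort_region_table(cohort, threshold_mode = config$threshold_mode),
    error = function(e) stop("pipeline stage metrics failed: ",
                             conditionMessage(e)))
  # per-mouse thresholds + metric CSVs
  for (nm in names(cohort$mice)) {
    m <- cohort$mice[[nm]]
    thr <- fit_thresholds(tawss(m$control$field),
                          multiplier = config$threshold_multiplier)
    write_thresholds_json(thr, file.path(out_dir,
                                         sprintf("%s_thresholds.json", nm)),
                          source = sprintf("%s control", nm))
    for (v in c("instrumented", "control")) {
      maps <- compute_metrics(m[[v]]$field, thr)
      write_metric_csv(maps, m[[v]]$frame, file.path(
        out_dir, sprintf("%s_%s_metrics.csv", nm, v)))
    }
  }
  summ <- tryCatch(
    summarize_cohort(tab, floor = config$floor,
                     paired = config$t_test == "paired"),
    error = function(e) stop("pipeline stage analyze failed: ",
                             conditionMessage(e)))
  utils::write.csv(summ$table, file.path(out_dir, "region_metric_table.csv"),
                   row.names = FALSE)
  utils::write.csv(summ$comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  # en-face grids for the first mouse's instrumented vessel
  m1 <- cohort$mice[[1L]]
  thr1 <- fit_thresholds(tawss(m1$control$field),
                         multiplier = config$threshold_multiplier)
  maps1 <- compute_metrics(m1$instrumented$field, thr1)
  for (mm in names(maps1)) {
    g <- enface(maps1[[mm]], m1$instrumented$frame,
                config$enface_bins[1L], config$enface_bins[2L])
    utils::write.csv(g$values, file.path(
      out_dir, sprintf("enface_%s.csv", mm)), row.names = FALSE)
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(summ)
}
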