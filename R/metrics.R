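#' Metric map constructor
#'
#' A `metric_map` is one scalar per surface node for a named WSS metric,
#' with units recorded (`Pa` for TAWSS and transWSS, `1/Pa` for RRT, `rad`
#' for SAD, dimensionless for OSI/LSI/HSI).
#'
#' @param values numeric vector, one value per node.
#' @param metric metric name, one of `TAWSS`, `OSI`, `RRT`, `tSS`, `SAD`,
#'   `LSI`, `HSI`.
#' @return numeric vector of class `metric_map` with attributes `metric`
#'   and `units`.
#' @export
metric_map <- function(values, metric) {
  metric <- match.arg(metric, metric_names())
  units <- c(TAWSS = "Pa", OSI = "", RRT = "1/Pa", tSS = "Pa",
             SAD = "rad", LSI = "", HSI = "")[[metric]]
  structure(as.numeric(values), metric = metric, units = units,
            class = "metric_map")
}

#' Names of the seven computed WSS metrics
#' @return character vector.
#' @export
metric_names <- function() c("TAWSS", "OSI", "RRT", "tSS", "SAD", "LSI", "HSI")

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf("metric_map %s [%s]: %d nodes, range %.4g..%.4g\n",
              attr(x, "metric"), attr(x, "units"), length(x),
              min(x), max(x)))
  invisible(x)
}

# Internal accessors over the n_nodes x 3 x n_inst vector array.
field_magnitudes <- function(field) {
  v <- field$vectors
  m <- sqrt(v[, 1L, , drop = FALSE]^2 + v[, 2L, , drop = FALSE]^2 +
              v[, 3L, , drop = FALSE]^2)
  matrix(m, dim(v)[1L], dim(v)[3L])   # n_nodes x n_inst
}

field_mean_vector <- function(field) {
  # time-mean WSS vector per node (equal-weight rectangle rule on the
  # uniform periodic grid)
  apply(field$vectors, c(1L, 2L), mean)
}

check_field <- function(field) {
  if (!inherits(field, "wss_field")) stop("expected a wss_field")
  if (dim(field$vectors)[3L] < 2L)
    stop("field must contain at least 2 exported instants")
}

#' Time-averaged wall shear stress magnitude (TAWSS)
#'
#' `TAWSS = (1/T) sum_i ||tau_i|| dt`, i.e. the mean WSS magnitude over the
#' exported instants of one cardiac cycle.
#'
#' @param field a `wss_field`.
#' @return `metric_map` in Pa.
#' @export
tawss <- function(field) {
  check_field(field)
  metric_map(rowMeans(field_magnitudes(field)), "TAWSS")
}

#' Oscillatory shear index (OSI)
#'
#' Degree of 180-degree flow reversal relative to the time-mean WSS vector:
#' `OSI = 0.5 (1 - ||sum tau_i dt|| / sum ||tau_i|| dt)`, in [0, 0.5]; 0 for
#' unidirectional shear, 0.5 for perfectly oscillatory shear. Nodes whose
#' WSS is identically zero get OSI 0 (count reported via attribute
#' `n_zero`).
#'
#' @param field a `wss_field`.
#' @return dimensionless `metric_map`.
#' @export
osi <- function(field) {
  check_field(field)
  mv <- field_mean_vector(field)
  num <- sqrt(rowSums(mv^2))
  den <- rowMeans(field_magnitudes(field))
  out <- numeric(length(den))
  nz <- den > 0
  out[nz] <- 0.5 * (1 - num[nz] / den[nz])
  m <- metric_map(pmin(pmax(out, 0), 0.5), "OSI")
  attr(m, "n_zero") <- sum(!nz)
  m
}

#' Relative residence time (RRT)
#'
#' `RRT = 1 / ((1 - 2 OSI) TAWSS) = 1 / ||time-mean WSS vector||`, a proxy
#' for near-wall residence of transported species: large where shear is low
#' and/or strongly oscillatory. Nodes with a vanishing mean vector get an
#' infinite sentinel (capped later at the display stage); their count is in
#' attribute `n_sentinel`.
#'
#' @param field a `wss_field`.
#' @return `metric_map` in 1/Pa.
#' @export
rrt <- function(field) {
  check_field(field)
  mv <- field_mean_vector(field)
  nrm <- sqrt(rowSums(mv^2))
  out <- ifelse(nrm > 0, 1 / nrm, Inf)
  m <- metric_map(out, "RRT")
  attr(m, "n_sentinel") <- sum(nrm == 0)
  m
}

#' Transverse wall shear stress (transWSS / tSS)
#'
#' Multidirectionality metric: the time-average of the WSS component along
#' the in-plane direction perpendicular to the time-mean WSS vector,
#' `tSS = (1/T) sum |tau_i . q| dt` with `q = n x p / ||n x p||` and
#' `p` the unit time-mean WSS vector. Captures direction changes other than
#' pure reversal; zero where the mean vector vanishes.
#'
#' @param field a `wss_field`.
#' @param normals per-node outward unit normals; defaults to the field
#'   mesh's normals.
#' @return `metric_map` in Pa.
#' @export
transwss <- function(field, normals = field$mesh$normals) {
  check_field(field)
  mv <- field_mean_vector(field)
  nrm <- sqrt(rowSums(mv^2))
  n_nodes <- nrow(mv)
  out <- numeric(n_nodes)
  ok <- nrm > 0
  p <- mv
  p[ok, ] <- mv[ok, , drop = FALSE] / nrm[ok]
  q <- cbind(normals[, 2L] * p[, 3L] - normals[, 3L] * p[, 2L],
             normals[, 3L] * p[, 1L] - normals[, 1L] * p[, 3L],
             normals[, 1L] * p[, 2L] - normals[, 2L] * p[, 1L])
  qn <- sqrt(rowSums(q^2))
  ok <- ok & qn > 0
  q[ok, ] <- q[ok, , drop = FALSE] / qn[ok]
  v <- field$vectors
  proj <- abs(v[, 1L, , drop = FALSE] * q[, 1L] +
                v[, 2L, , drop = FALSE] * q[, 2L] +
                v[, 3L, , drop = FALSE] * q[, 3L])
  proj <- matrix(proj, dim(v)[1L], dim(v)[3L])
  out[ok] <- rowMeans(proj)[ok]
  metric_map(out, "tSS")
}

#' Shear stress angle deviation (SAD)
#'
#' Spatial direction-change metric: for node j at instant i, the mean angle
#' between its WSS vector and those of its edge neighbours,
#' `arccos(tau_i(j) . tau_i(k) / (||tau_i(j)|| ||tau_i(k)||))`, averaged
#' first over the neighbours and then over the exported instants.
#' Node-instant pairs where either vector vanishes contribute a zero angle
#' (count in attribute `n_zero_pairs`).
#'
#' @param field a `wss_field`.
#' @param adjacency neighbour list from [node_neighbors()]; defaults to the
#'   field mesh's adjacency.
#' @return `metric_map` in rad, values in [0, pi].
#' @export
sad <- function(field, adjacency = node_neighbors(field$mesh)) {
  check_field(field)
  deg <- lengths(adjacency)
  if (any(deg == 0L)) stop("isolated node(s): ", which(deg == 0L)[1L])
  n_nodes <- length(adjacency)
  ej <- rep.int(seq_len(n_nodes), deg)
  ek <- unlist(adjacency, use.names = FALSE)
  v <- field$vectors
  n_inst <- dim(v)[3L]
  acc <- numeric(n_nodes)
  n_zero_pairs <- 0L
  for (i in seq_len(n_inst)) {
    vi <- matrix(v[, , i], n_nodes, 3L)
    nj <- sqrt(rowSums(vi^2))
    dotjk <- vi[ej, 1L] * vi[ek, 1L] + vi[ej, 2L] * vi[ek, 2L] +
      vi[ej, 3L] * vi[ek, 3L]
    den <- nj[ej] * nj[ek]
    ang <- numeric(length(den))
    good <- den > 0
    n_zero_pairs <- n_zero_pairs + sum(!good)
    ang[good] <- acos(pmin(pmax(dotjk[good] / den[good], -1), 1))
    acc <- acc + rowsum_safe(ang, ej, n_nodes) / deg
  }
  m <- metric_map(acc / n_inst, "SAD")
  attr(m, "n_zero_pairs") <- n_zero_pairs
  m
}

#' Calibrate low/high TAWSS thresholds from a control vessel
#'
#' The contralateral control vessel is taken to represent non-atherogenic
#' flow. Its node TAWSS values are log-transformed; with `m` the mean and
#' `s` the sample SD (n-1 denominator) of `ln TAWSS`, the thresholds are
#' `low = exp(m - 0.67 s)` and `high = exp(m + 0.67 s)` - the bottom and
#' top 25% of a log-normal distribution (0.67 is the standard-normal 75th
#' percentile to two decimals, used literally).
#'
#' @param control_tawss `metric_map` (or numeric vector) of control-vessel
#'   TAWSS values, all positive, length >= 2.
#' @param multiplier quantile multiplier on the log-scale SD; 0.67 (the
#'   two-decimal 75th percentile of the standard normal) by default.
#' @return object of class `tawss_thresholds`: `low`, `high` (Pa),
#'   `mean_log`, `sd_log`.
#' @export
fit_thresholds <- function(control_tawss, multiplier = 0.67) {
  x <- as.numeric(control_tawss)
  if (length(x) < 2L) stop("need at least 2 control TAWSS values")
  if (any(x <= 0)) stop("control TAWSS values must all be positive")
  lx <- log(x)
  m <- mean(lx)
  s <- stats::sd(lx)
  structure(list(low = exp(m - multiplier * s),
                 high = exp(m + multiplier * s),
                 mean_log = m, sd_log = s),
            class = "tawss_thresholds")
}

#' @export
print.tawss_thresholds <- function(x, ...) {
  cat(sprintf(paste0("TAWSS thresholds: low %.4g Pa, high %.4g Pa ",
                     "(mean_log %.4g, sd_log %.4g)\n"),
              x$low, x$high, x$mean_log, x$sd_log))
  invisible(x)
}

#' Low shear index (LSI)
#'
#' Continuous measure of atherogenically low TAWSS:
#' `LSI = max(0, (low - TAWSS) / low)`, zero at or above the calibrated low
#' threshold, approaching 1 as TAWSS approaches zero. Applied identically
#' to instrumented and control vessels.
#'
#' @param tawss_map `metric_map` of TAWSS values.
#' @param thresholds `tawss_thresholds`.
#' @return dimensionless `metric_map` in [0, 1].
#' @export
lsi <- function(tawss_map, thresholds) {
  stopifnot(inherits(thresholds, "tawss_thresholds"))
  metric_map(pmax(0, (thresholds$low - as.numeric(tawss_map)) /
                    thresholds$low), "LSI")
}

#' High shear index (HSI)
#'
#' Continuous measure of atherogenically high TAWSS:
#' `HSI = max(0, (TAWSS - high) / TAWSS)`, zero at or below the calibrated
#' high threshold, approaching 1 as TAWSS grows without bound. Because
#' `low <= high`, LSI and HSI are never simultaneously positive, leaving a
#' window of normal WSS in between.
#'
#' @param tawss_map `metric_map` of TAWSS values.
#' @param thresholds `tawss_thresholds`.
#' @return dimensionless `metric_map` in [0, 1).
#' @export
hsi <- function(tawss_map, thresholds) {
  stopifnot(inherits(thresholds, "tawss_thresholds"))
  x <- as.numeric(tawss_map)
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- pmax(0, (x[pos] - thresholds$high) / x[pos])
  metric_map(out, "HSI")
}

#' Scale a metric map to [0, 1] for display
#'
#' Divides by the metric's theoretical maximum (OSI: 0.5; SAD: pi; LSI and
#' HSI: 1) or, for metrics without a finite theoretical maximum (TAWSS,
#' tSS, RRT), by an observed maximum supplied by the caller (conventionally
#' the maximum over all vessels of the cohort). Results are clipped to
#' [0, 1]; infinite RRT sentinels are capped at 1.
#'
#' @param map a `metric_map`.
#' @param observed_max cohort-observed maximum; required for TAWSS, tSS and
#'   RRT, ignored otherwise.
#' @return dimensionless `metric_map` in [0, 1].
#' @export
normalize_display <- function(map, observed_max = NULL) {
  metric <- attr(map, "metric")
  div <- switch(metric, OSI = 0.5, SAD = pi, LSI = 1, HSI = 1,
                TAWSS = , tSS = , RRT = {
                  if (is.null(observed_max) || !is.finite(observed_max) ||
                      observed_max <= 0)
                    stop("observed_max required to display-normalize ",
                         metric)
                  observed_max
                })
  out <- pmin(pmax(as.numeric(map) / div, 0), 1)
  out[!is.finite(as.numeric(map))] <- 1   # RRT sentinel cap
  structure(out, metric = metric, units = "", class = "metric_map")
}

#' Compute all seven metric maps for one vessel
#'
#' Convenience wrapper running TAWSS, OSI, RRT, transWSS, SAD and, given
#' thresholds, LSI and HSI on a field.
#'
#' @param field a `wss_field`.
#' @param thresholds `tawss_thresholds` calibrated from the paired control
#'   vessel.
#' @param adjacency optional precomputed adjacency for SAD.
#' @return named list of `metric_map`s.
#' @export
compute_metrics <- function(field, thresholds,
                            adjacency = node_neighbors(field$mesh)) {
  tw <- tawss(field)
  list(TAWSS = tw,
       OSI = osi(field),
       RRT = rrt(field),
       tSS = transwss(field),
       SAD = sad(field, adjacency),
       LSI = lsi(tw, thresholds),
       HSI = hsi(tw, thresholds))
}
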