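#' Segment a cuffed vessel into four axial regions
#'
#' Labels every node of a parameterized vessel as one of four regions used
#' for regional plaque/flow comparisons: upstream of the cuff outside the
#' vulnerable-plaque region, upstream within the plaque region (a fixed
#' axial extent proximal to the cuff entrance, 1.6 mm by default), inside
#' the cuff, and downstream of the cuff. Boundary nodes are assigned to the
#' more distal region so the cuff interval is closed.
#'
#' @param frame a `centerline_frame` from [parameterize()].
#' @param cuff_start,cuff_end axial positions (mm) of the cuff entrance and
#'   exit, with `0 < cuff_start < cuff_end < L`.
#' @param plaque_extent axial extent (mm) of the upstream plaque region,
#'   measured back from the cuff entrance; default 1.6 mm.
#' @return object of class `region_labels`: list with `label` (factor,
#'   levels `upstream_outside`, `upstream_plaque`, `cuff`, `downstream`) and
#'   `boundaries` (named numeric: `plaque_start`, `cuff_start`, `cuff_end`).
#' @export
segment_regions <- function(frame, cuff_start, cuff_end,
                            plaque_extent = 1.6) {
  if (plaque_extent <= 0) stop("plaque_extent must be > 0")
  if (!(0 < cuff_start && cuff_start < cuff_end && cuff_end < frame$length))
    stop("cuff interval must satisfy 0 < cuff_start < cuff_end < L")
  plaque_start <- cuff_start - plaque_extent
  if (plaque_start < 0)
    stop("plaque region extends beyond the proximal end of the vessel")
  s <- frame$s
  lab <- rep("upstream_outside", length(s))
  lab[s >= plaque_start & s < cuff_start] <- "upstream_plaque"
  lab[s >= cuff_start & s <= cuff_end] <- "cuff"
  lab[s > cuff_end] <- "downstream"
  structure(list(
    label = factor(lab, levels = region_levels()),
    boundaries = c(plaque_start = plaque_start, cuff_start = cuff_start,
                   cuff_end = cuff_end)),
    class = "region_labels")
}

region_levels <- function() {
  c("upstream_outside", "upstream_plaque", "cuff", "downstream")
}

#' Transfer region boundaries to a control vessel
#'
#' The contralateral control carotid has no cuff; for regional comparison it
#' is divided at the same distances from its distal end as the instrumented
#' vessel, yielding segments of comparable length.
#'
#' @param frame_control `centerline_frame` of the control vessel.
#' @param labels_instrumented `region_labels` of the instrumented vessel.
#' @param frame_instrumented `centerline_frame` of the instrumented vessel.
#' @param plaque_extent plaque-region extent (mm), matching the instrumented
#'   segmentation.
#' @return `region_labels` for the control vessel.
#' @export
control_regions <- function(frame_control, labels_instrumented,
                            frame_instrumented, plaque_extent = 1.6) {
  b <- labels_instrumented$boundaries
  Li <- frame_instrumented$length
  Lc <- frame_control$length
  # distal anchoring: preserve distance from the downstream end
  cs <- Lc - (Li - b[["cuff_start"]])
  ce <- Lc - (Li - b[["cuff_end"]])
  if (cs - plaque_extent < 0 || cs <= 0)
    stop("control vessel shorter than the required region span")
  segment_regions(frame_control, cs, ce, plaque_extent)
}

#' Areal stenosis of a tapered constriction
#'
#' Percentage reduction in cross-sectional area between inlet and outlet of
#' a circular constriction: `100 * (1 - (d_out/d_in)^2)`. For the tapered
#' cuff (500 um inlet, 250 um outlet) this gives 75%.
#'
#' @param d_inlet,d_outlet inlet and outlet diameters (any common unit).
#' @return stenosis in percent.
#' @examples
#' areal_stenosis(500, 250)  # 75
#' @export
areal_stenosis <- function(d_inlet, d_outlet) {
  if (any(d_inlet <= 0) || any(d_outlet <= 0))
    stop("diameters must be positive")
  100 * (1 - (d_outlet / d_inlet)^2)
}

#' Export region labels as a data frame
#'
#' @param labels `region_labels`.
#' @param frame matching `centerline_frame`.
#' @return data.frame with `node_id`, `s_mm`, `theta_rad`, `region`.
#' @export
region_table <- function(labels, frame) {
  data.frame(node_id = seq_along(frame$s), s_mm = frame$s,
             theta_rad = frame$theta,
             region = as.character(labels$label))
}
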