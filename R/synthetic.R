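#' Blood fluid properties
#'
#' Newtonian constants used by the quasi-steady shear closure. Defaults are
#' the standard whole-blood values at high shear rate: dynamic viscosity
#' 3.5 mPa s and density 1050 kg/m^3; blood behaves Newtonian here because
#' mean wall shear rates in these vessels exceed 1000 1/s.
#'
#' @param viscosity dynamic viscosity (Pa s).
#' @param density mass density (kg/m^3).
#' @return list of class `fluid_props`.
#' @export
fluid_props <- function(viscosity = 3.5e-3, density = 1050) {
  if (viscosity <= 0 || density <= 0)
    stop("viscosity and density must be positive")
  structure(list(viscosity = viscosity, density = density),
            class = "fluid_props")
}

#' Downstream flow-disturbance parameters
#'
#' Parametric surrogate for the time-varying vortex that forms downstream of
#' the cuff: within a recirculation zone of length `recirc_length` after the
#' cuff exit, the axial WSS is modulated (reversing at peak when
#' `reversal_amplitude > 0.5`) and a rotating circumferential component is
#' added, producing oscillatory and multidirectional shear.
#'
#' @param recirc_length axial extent of the recirculation zone (mm).
#' @param reversal_amplitude fraction of the local axial WSS reversed at the
#'   modulation peak (dimensionless, >= 0).
#' @param circ_amplitude scale of the added circumferential component as a
#'   fraction of the undisturbed axial magnitude (>= 0).
#' @param vortex_frequency_multiplier vortex shedding frequency in units of
#'   the cardiac frequency.
#' @return list of class `disturbance_spec`.
#' @export
disturbance_spec <- function(recirc_length = 2.5, reversal_amplitude = 1,
                             circ_amplitude = 0.5,
                             vortex_frequency_multiplier = 2) {
  if (recirc_length < 0 || reversal_amplitude < 0 || circ_amplitude < 0 ||
      vortex_frequency_multiplier < 0)
    stop("disturbance parameters must be non-negative")
  structure(list(recirc_length = recirc_length,
                 reversal_amplitude = reversal_amplitude,
                 circ_amplitude = circ_amplitude,
                 vortex_frequency_multiplier = vortex_frequency_multiplier),
            class = "disturbance_spec")
}

#' Synthetic vessel specification
#'
#' Describes one carotid-scale vessel for the synthetic flow generator. An
#' instrumented vessel carries a tapered cuff (inner diameter 500 um at the
#' entrance narrowing to 250 um at the exit, i.e. a 75% areal stenosis) and
#' a downstream disturbance; a control vessel is a uniform tube. The cardiac
#' cycle is 8 Hz (0.125 s), discretized into 300 steps with every 10th step
#' exported (30 instants).
#'
#' @param inlet_diameter vessel inner diameter (um) outside the cuff.
#' @param vessel_length axial length (mm).
#' @param cuff_start,cuff_end axial cuff interval (mm); `NULL` for a control
#'   vessel without a cuff.
#' @param cuff_inlet_diameter,cuff_outlet_diameter cuff inner diameters (um).
#' @param mean_velocity cycle-averaged inlet velocity U (mm/s).
#' @param heart_rate cardiac frequency (Hz).
#' @param n_steps_per_cycle time steps per cardiac cycle.
#' @param export_every export stride (time steps); must divide
#'   `n_steps_per_cycle`.
#' @param waveform_a1,waveform_a2,waveform_phi harmonic amplitudes and phase
#'   of the pulsatile inlet waveform (see [make_waveform()]).
#' @param disturbance a `disturbance_spec`, or `NULL` for none.
#' @param heterogeneity_sigma_log log-scale SD of the per-node spatial
#'   heterogeneity of WSS magnitude (dimensionless).
#' @param n_axial,n_circ mesh resolution (rings x nodes per ring).
#' @param seed integer seed for the vessel's stochastic components.
#' @return list of class `vessel_spec`.
#' @export
vessel_spec <- function(inlet_diameter = 600, vessel_length = 10,
                        cuff_start = 5.0, cuff_end = 6.2,
                        cuff_inlet_diameter = 500,
                        cuff_outlet_diameter = 250,
                        mean_velocity = 112.8, heart_rate = 8,
                        n_steps_per_cycle = 300, export_every = 10,
                        waveform_a1 = 0.4, waveform_a2 = 0.15,
                        waveform_phi = pi / 4,
                        disturbance = disturbance_spec(),
                        heterogeneity_sigma_log = 0.3,
                        n_axial = 81, n_circ = 24, seed = 1L) {
  if (inlet_diameter <= 0 || cuff_inlet_diameter <= 0 ||
      cuff_outlet_diameter <= 0)
    stop("diameters must be positive")
  if (!is.null(cuff_start)) {
    if (!(0 < cuff_start && cuff_start < cuff_end &&
          cuff_end < vessel_length))
      stop("cuff interval must lie inside the vessel")
  }
  if (n_steps_per_cycle %% export_every != 0L)
    stop("n_steps_per_cycle must be divisible by export_every")
  if (!is.null(disturbance) && !is.null(cuff_start) &&
      disturbance$recirc_length > vessel_length - cuff_end)
    stop("recirculation zone extends beyond the vessel")
  if (heterogeneity_sigma_log < 0)
    stop("heterogeneity_sigma_log must be >= 0")
  structure(list(
    inlet_diameter = inlet_diameter, vessel_length = vessel_length,
    cuff_start = cuff_start, cuff_end = cuff_end,
    cuff_inlet_diameter = cuff_inlet_diameter,
    cuff_outlet_diameter = cuff_outlet_diameter,
    mean_velocity = mean_velocity, heart_rate = heart_rate,
    n_steps_per_cycle = as.integer(n_steps_per_cycle),
    export_every = as.integer(export_every),
    waveform_a1 = waveform_a1, waveform_a2 = waveform_a2,
    waveform_phi = waveform_phi, disturbance = disturbance,
    heterogeneity_sigma_log = heterogeneity_sigma_log,
    n_axial = as.integer(n_axial), n_circ = as.integer(n_circ),
    seed = as.integer(seed)), class = "vessel_spec")
}

#' Control-vessel specification
#'
#' Convenience wrapper over [vessel_spec()]: a uniform tube with no cuff and
#' no downstream disturbance. The default mean inlet velocity 153.4 mm/s is
#' the contralateral control value (instrumented vessels default to
#' 112.8 mm/s, reflecting the flow-limiting stenosis).
#'
#' @param mean_velocity cycle-averaged inlet velocity (mm/s).
#' @param ... further arguments passed to [vessel_spec()].
#' @return a `vessel_spec` with `cuff_start = NULL`.
#' @export
control_vessel_spec <- function(mean_velocity = 153.4, ...) {
  spec <- vessel_spec(mean_velocity = mean_velocity, ...)
  spec$cuff_start <- NULL
  spec$cuff_end <- NULL
  spec$disturbance <- NULL
  spec
}

#' Radius profile of a vessel specification (mm)
#'
#' @param spec a `vessel_spec`.
#' @return function s (mm) -> radius (mm): the vessel radius outside the
#'   cuff and the linearly tapering cuff lumen inside it.
#' @export
radius_profile <- function(spec) {
  r_vessel <- spec$inlet_diameter / 2000   # um -> mm
  if (is.null(spec$cuff_start)) return(function(s) rep_len(r_vessel, length(s)))
  r0 <- spec$cuff_inlet_diameter / 2000
  r1 <- spec$cuff_outlet_diameter / 2000
  s0 <- spec$cuff_start
  s1 <- spec$cuff_end
  function(s) {
    r <- rep_len(r_vessel, length(s))
    inside <- s >= s0 & s <= s1
    r[inside] <- r0 + (r1 - r0) * (s[inside] - s0) / (s1 - s0)
    r
  }
}

#' Pulsatile inlet velocity waveform
#'
#' Two-harmonic positive waveform over one cardiac cycle,
#' `U(t) = U (1 + a1 sin(2 pi t/T) + a2 sin(4 pi t/T + phi))`, rescaled so
#' the sample mean equals U exactly. A stand-in for the Doppler-averaged
#' inlet waveform; its harmonic content is generic, not vessel-specific.
#'
#' @param spec a `vessel_spec`.
#' @return list of class `velocity_waveform` with `times` (s, uniform over
#'   one period, left endpoints), `velocity` (mm/s) and `period` (s).
#' @export
make_waveform <- function(spec) {
  T <- 1 / spec$heart_rate
  n <- spec$n_steps_per_cycle
  t <- (seq_len(n) - 1L) * T / n
  u <- 1 + spec$waveform_a1 * sin(2 * pi * t / T) +
    spec$waveform_a2 * sin(4 * pi * t / T + spec$waveform_phi)
  if (any(u <= 0))
    stop("waveform amplitudes drive the inlet velocity non-positive")
  u <- u * (spec$mean_velocity / mean(u))
  structure(list(times = t, velocity = u, period = T),
            class = "velocity_waveform")
}

#' Quasi-steady Poiseuille wall shear stress field
#'
#' At Reynolds number ~40 and Womersley number ~2 the wall shear in a long
#' straight tube tracks the instantaneous flow rate closely, so each
#' exported instant is closed with the steady fully developed value: with
#' volumetric flow `Q(t) = U(t) pi R_inlet^2` conserved along the tube,
#' `|tau|(s, t) = 4 mu Q(t) / (pi R(s)^3)`, directed along the +axial unit
#' vector. Only instants on the export stride are retained.
#'
#' @param mesh `tri_mesh` of the vessel wall.
#' @param frame `centerline_frame` for the mesh.
#' @param rprof radius profile function s -> R(s) (mm).
#' @param waveform `velocity_waveform`.
#' @param fluid `fluid_props`.
#' @param spec `vessel_spec` (supplies the export stride and inlet radius).
#' @return object of class `wss_field`: list with `vectors` (array
#'   n_nodes x 3 x n_export, Pa), `times` (s), `period` (s), plus the mesh
#'   and frame.
#' @export
quasi_steady_wss <- function(mesh, frame, rprof, waveform, fluid, spec) {
  keep <- seq(1L, spec$n_steps_per_cycle, by = spec$export_every)
  times <- waveform$times[keep]
  u <- waveform$velocity[keep]
  R_in <- spec$inlet_diameter / 2000
  R <- rprof(frame$s)
  if (any(R <= 0)) stop("radius profile must be positive")
  # tau in Pa: mu [Pa s] * (mm/s / mm) = Pa
  mag <- outer(4 * fluid$viscosity * R_in^2 / R^3, u)  # n_nodes x n_export
  n_nodes <- nrow(mesh$nodes)
  vec <- array(0, c(n_nodes, 3L, length(keep)))
  vec[, 3L, ] <- mag                     # +axial = +z for generated tubes
  structure(list(vectors = vec, times = times, period = waveform$period,
                 mesh = mesh, frame = frame),
            class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("wss_field: %d nodes x %d exported instants, period %.4g s\n",
              dim(x$vectors)[1L], dim(x$vectors)[3L], x$period))
  invisible(x)
}

#' Impose the downstream vortex disturbance
#'
#' Modulates the WSS field in the recirculation zone behind the cuff exit.
#' With axial position envelope `w(s) = sin^2(pi (s - s_exit)/L_rec)`, the
#' axial component is multiplied by
#' `1 - A_rev w(s) (1 + sin(2 pi m t/T + theta))` (transiently negative when
#' `A_rev > 0.5`) and a circumferential component
#' `A_circ w(s) |tau_axial| cos(2 pi m t/T + 2 theta)` is added, where theta
#' is the node's circumferential angle and m the vortex frequency
#' multiplier. Nodes outside the zone are untouched.
#'
#' @param field `wss_field` from [quasi_steady_wss()].
#' @param frame matching `centerline_frame`.
#' @param spec `vessel_spec` carrying `cuff_end` and a `disturbance_spec`.
#' @return modified `wss_field`.
#' @export
apply_downstream_disturbance <- function(field, frame, spec) {
  d <- spec$disturbance
  if (is.null(d) || is.null(spec$cuff_end)) return(field)
  if (d$recirc_length == 0) return(field)
  s_exit <- spec$cuff_end
  if (s_exit + d$recirc_length > frame$length + 1e-9)
    stop("recirculation zone extends beyond the mesh")
  zone <- which(frame$s > s_exit & frame$s <= s_exit + d$recirc_length)
  if (length(zone) == 0L) return(field)
  w <- sin(pi * (frame$s[zone] - s_exit) / d$recirc_length)^2
  th <- frame$theta[zone]
  m <- d$vortex_frequency_multiplier
  # circumferential unit vector on a z-axis tube: (-sin th, cos th, 0)
  circ_x <- -sin(th)
  circ_y <- cos(th)
  vec <- field$vectors
  for (i in seq_along(field$times)) {
    t <- field$times[i]
    ax <- vec[zone, 3L, i]
    gain <- 1 - d$reversal_amplitude * w *
      (1 + sin(2 * pi * m * t / field$period + th))
    circ <- d$circ_amplitude * w * abs(ax) *
      cos(2 * pi * m * t / field$period + 2 * th)
    vec[zone, 3L, i] <- ax * gain
    vec[zone, 1L, i] <- vec[zone, 1L, i] + circ * circ_x
    vec[zone, 2L, i] <- vec[zone, 2L, i] + circ * circ_y
  }
  field$vectors <- vec
  field
}

# Evaluate expr with a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Apply per-node log-normal spatial heterogeneity
#'
#' Multiplies every node's WSS vectors (all instants) by a single per-node
#' factor `exp(g)` with `g ~ Normal(-sigma^2/2, sigma)`, so node-level TAWSS
#' becomes log-normally distributed about its deterministic value with
#' log-scale SD `sigma_log` and unchanged mean. Emulates the spatial
#' variation of wall shear seen in real vessels (surface irregularity,
#' diameter variation) that a smooth tube lacks. Time structure and vector
#' direction are unchanged.
#'
#' @param field `wss_field`.
#' @param sigma_log log-scale standard deviation (>= 0).
#' @param seed integer seed; the same seed reproduces the same field.
#' @return modified `wss_field`.
#' @export
apply_spatial_heterogeneity <- function(field, sigma_log, seed) {
  if (sigma_log < 0) stop("sigma_log must be >= 0")
  if (sigma_log == 0) return(field)
  n <- dim(field$vectors)[1L]
  g <- with_seed(seed, stats::rnorm(n, -sigma_log^2 / 2, sigma_log))
  field$vectors <- field$vectors * array(exp(g), dim(field$vectors))
  field
}

#' Generate one synthetic mouse (paired instrumented + control vessel)
#'
#' Builds the instrumented vessel (tapered-cuff tube, quasi-steady pulsatile
#' WSS, downstream vortex disturbance, spatial heterogeneity) and its
#' contralateral control (uniform tube with heterogeneity only), with
#' four-region labels attached; control regions are anchored at the distal
#' end to match the instrumented segmentation.
#'
#' @param spec_instrumented,spec_control `vessel_spec` objects; the control
#'   spec must have no cuff.
#' @param seed integer master seed for this mouse (overrides the specs'
#'   seeds; the two vessels use distinct derived streams).
#' @param fluid `fluid_props`.
#' @param plaque_extent plaque-region extent (mm).
#' @return list of class `synthetic_mouse` with elements `instrumented` and
#'   `control`, each holding `mesh`, `frame`, `field`, `labels`, `spec`.
#' @export
synth_mouse <- function(spec_instrumented = vessel_spec(),
                        spec_control = control_vessel_spec(),
                        seed = 1L, fluid = fluid_props(),
                        plaque_extent = 1.6) {
  if (!is.null(spec_control$cuff_start))
    stop("spec_control must not carry a cuff")
  build_one <- function(spec, vseed) {
    rprof <- radius_profile(spec)
    mesh <- build_tube_mesh(rprof, spec$vessel_length, spec$n_axial,
                            spec$n_circ)
    frame <- parameterize(mesh)
    wf <- make_waveform(spec)
    field <- quasi_steady_wss(mesh, frame, rprof, wf, fluid, spec)
    field <- apply_downstream_disturbance(field, frame, spec)
    field <- apply_spatial_heterogeneity(field, spec$heterogeneity_sigma_log,
                                         vseed)
    list(mesh = mesh, frame = frame, field = field, spec = spec)
  }
  instr <- build_one(spec_instrumented, derive_seed(seed, 1L))
  ctrl <- build_one(spec_control, derive_seed(seed, 2L))
  instr$labels <- segment_regions(instr$frame, spec_instrumented$cuff_start,
                                  spec_instrumented$cuff_end, plaque_extent)
  ctrl$labels <- control_regions(ctrl$frame, instr$labels, instr$frame,
                                 plaque_extent)
  structure(list(instrumented = instr, control = ctrl, seed = seed),
            class = "synthetic_mouse")
}

# Deterministic child seeds, kept within 32-bit integer range.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + as.numeric(index) * 104729) %%
               2147483647)
}

#' Generate a synthetic cohort of paired vessels
#'
#' Produces `n_mice` paired instrumented/control vessels with deterministic
#' per-mouse seeds derived from the master seed and mild per-mouse jitter
#' (uniform within +/-10%) on mean inlet velocity and heterogeneity,
#' emulating animal-to-animal physiological variation. The default cohort
#' size matches the seven-animal imaging cohort the pipeline's regional
#' statistics are designed for.
#'
#' @param n_mice number of mice (>= 2).
#' @param spec_instrumented,spec_control base `vessel_spec` objects.
#' @param seed master integer seed.
#' @param fluid `fluid_props`.
#' @param plaque_extent plaque-region extent (mm).
#' @return list of class `synthetic_cohort`: `mice` (list of
#'   `synthetic_mouse`), `seed`.
#' @export
synth_cohort <- function(n_mice = 7, spec_instrumented = vessel_spec(),
                         spec_control = control_vessel_spec(),
                         seed = 1L, fluid = fluid_props(),
                         plaque_extent = 1.6) {
  if (n_mice < 2) stop("n_mice must be >= 2 for cohort statistics")
  mice <- vector("list", n_mice)
  for (i in seq_len(n_mice)) {
    mseed <- derive_seed(seed, 100L + i)
    jit <- with_seed(derive_seed(seed, 200L + i), stats::runif(2, 0.9, 1.1))
    si <- spec_instrumented
    sc <- spec_control
    si$mean_velocity <- si$mean_velocity * jit[1L]
    sc$mean_velocity <- sc$mean_velocity * jit[1L]
    si$heterogeneity_sigma_log <- si$heterogeneity_sigma_log * jit[2L]
    sc$heterogeneity_sigma_log <- sc$heterogeneity_sigma_log * jit[2L]
    mice[[i]] <- synth_mouse(si, sc, seed = mseed, fluid = fluid,
                             plaque_extent = plaque_extent)
  }
  names(mice) <- sprintf("mouse%02d", seq_len(n_mice))
  structure(list(mice = mice, seed = seed), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d mice (paired instrumented + control)\n",
              length(x$mice)))
  invisible(x)
}
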