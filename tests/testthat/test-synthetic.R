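test_that("waveform has the study's time grid and exact mean velocity", {
  spec <- vessel_spec()
  wf <- make_waveform(spec)
  expect_length(wf$velocity, 300L)
  expect_equal(wf$period, 0.125)
  expect_equal(diff(wf$times)[1], 0.125 / 300)
  expect_equal(mean(wf$velocity), 112.8, tolerance = 1e-9)
  expect_true(all(wf$velocity > 0))
  # zero harmonics give a constant waveform
  flat <- make_waveform(vessel_spec(waveform_a1 = 0, waveform_a2 = 0))
  expect_equal(flat$velocity, rep(112.8, 300))
  # random admissible amplitudes keep the mean exact
  set.seed(42)
  for (i in 1:5) {
    a <- runif(2, 0, 0.4)
    wfr <- make_waveform(vessel_spec(waveform_a1 = a[1], waveform_a2 = a[2]))
    expect_equal(mean(wfr$velocity), 112.8, tolerance = 1e-9)
  }
  expect_error(make_waveform(vessel_spec(waveform_a1 = 1.5)),
               "non-positive")
})

test_that("quasi-steady closure reproduces Poiseuille wall shear", {
  spec <- small_ctrl_spec(mean_velocity = 150, waveform_a1 = 0,
                          waveform_a2 = 0, inlet_diameter = 600)
  tube <- build_tube_mesh(radius_profile(spec), 10, 41, 12)
  f <- parameterize(tube)
  fld <- quasi_steady_wss(tube, f, radius_profile(spec),
                          make_waveform(spec), fluid_props(), spec)
  # tau_w = 4 mu U / R = 4 * 3.5e-3 * 150 / 0.3 = 7 Pa, steady
  expect_equal(as.vector(field_mags(fld)), rep(7, 41 * 12 * 30),
               tolerance = 1e-12)
  # implied wall shear rate 8U/D equals |tau|/mu
  expect_equal(8 * 150 / 0.6, 7 / 3.5e-3, tolerance = 1e-9)
  expect_equal(dim(fld$vectors)[3], 30L)
  expect_equal(diff(fld$times)[1], 0.125 / 30)
})

test_that("mass conservation holds: |tau| R^3 constant along the tube", {
  spec <- small_instr_spec()
  rprof <- radius_profile(spec)
  tube <- build_tube_mesh(rprof, spec$vessel_length, 41, 12)
  f <- parameterize(tube)
  fld <- quasi_steady_wss(tube, f, rprof, make_waveform(spec),
                          fluid_props(), spec)
  R <- rprof(f$s)
  for (i in c(1, 13, 30)) {
    mags <- sqrt(rowSums(fld$vectors[, , i]^2))
    prod <- mags * R^3
    expect_lt(diff(range(prod)) / mean(prod), 1e-9)
  }
  # halving the radius multiplies |tau| by 8 at fixed t
  i_wide <- which.min(abs(f$s - 1))[1]
  r_half <- function(s) rprof(s) / ifelse(abs(s - f$s[i_wide]) < 1e-9, 2, 1)
  fld2 <- quasi_steady_wss(tube, f, r_half, make_waveform(spec),
                           fluid_props(), spec)
  expect_equal(sqrt(sum(fld2$vectors[i_wide, , 1]^2)),
               8 * sqrt(sum(fld$vectors[i_wide, , 1]^2)), tolerance = 1e-9)
})

test_that("downstream disturbance is local and creates reversal and swirl", {
  spec <- small_instr_spec()
  rprof <- radius_profile(spec)
  tube <- build_tube_mesh(rprof, spec$vessel_length, 41, 12)
  f <- parameterize(tube)
  base <- quasi_steady_wss(tube, f, rprof, make_waveform(spec),
                           fluid_props(), spec)
  # null disturbance: bitwise identity
  spec0 <- spec
  spec0$disturbance <- disturbance_spec(reversal_amplitude = 0,
                                        circ_amplitude = 0)
  expect_identical(apply_downstream_disturbance(base, f, spec0)$vectors,
                   base$vectors)
  dist <- apply_downstream_disturbance(base, f, spec)
  upstream <- f$s <= spec$cuff_end
  expect_identical(dist$vectors[upstream, , ], base$vectors[upstream, , ])
  # mid-zone node: reversal happens and metrics pick it up
  mid <- which.min(abs(f$s - (spec$cuff_end + spec$disturbance$recirc_length / 2)))
  expect_lt(min(dist$vectors[mid, 3, ]), 0)
  o <- osi(dist); t2 <- transwss(dist)
  expect_gt(o[mid], 0.05)
  expect_gt(t2[mid], 0)
  up_node <- which.min(abs(f$s - 2))
  expect_equal(o[up_node], 0)
  expect_equal(t2[up_node], 0)
  # zone overrunning the mesh is rejected
  spec_bad <- spec
  spec_bad$disturbance$recirc_length <- 99
  expect_error(apply_downstream_disturbance(base, f, spec_bad), "zone")
})

test_that("spatial heterogeneity is seeded, lognormal, direction-preserving", {
  spec <- small_ctrl_spec(heterogeneity_sigma_log = 0)
  rprof <- radius_profile(spec)
  tube <- build_tube_mesh(rprof, 10, 101, 30)   # 3030 nodes
  f <- parameterize(tube)
  base <- quasi_steady_wss(tube, f, rprof, make_waveform(spec),
                           fluid_props(), spec)
  expect_identical(apply_spatial_heterogeneity(base, 0, 1)$vectors,
                   base$vectors)
  h1 <- apply_spatial_heterogeneity(base, 0.5, 7)
  h1b <- apply_spatial_heterogeneity(base, 0.5, 7)
  h2 <- apply_spatial_heterogeneity(base, 0.5, 8)
  expect_identical(h1$vectors, h1b$vectors)
  expect_false(identical(h1$vectors, h2$vectors))
  # log TAWSS spread matches sigma_log within 5% at ~3000 nodes
  expect_equal(sd(log(as.numeric(tawss(h1)))), 0.5, tolerance = 0.05)
  # direction unchanged
  expect_equal(h1$vectors[, 1, ], base$vectors[, 1, ])
  expect_true(all(h1$vectors[, 3, ] > 0))
})

test_that("paired synthetic mouse reproduces the cuff flow pattern", {
  mouse <- synth_mouse(seed = 11)
  tw <- tawss(mouse$instrumented$field)
  rm_ <- region_means(tw, mouse$instrumented$labels)
  expect_gt(rm_[["cuff"]], rm_[["upstream_outside"]])
  # control is unidirectional: OSI, tSS identically zero even after
  # heterogeneity (a pure per-node rescale)
  expect_equal(max(osi(mouse$control$field)), 0)
  expect_equal(max(transwss(mouse$control$field)), 0)
  # same geometry, different shear across seeds
  mouse2 <- synth_mouse(seed = 12)
  expect_identical(mouse2$instrumented$mesh$nodes,
                   mouse$instrumented$mesh$nodes)
  expect_false(identical(as.numeric(tawss(mouse2$instrumented$field)),
                         as.numeric(tw)))
})

test_that("cohorts are reproducible with jittered per-mouse velocities", {
  c1 <- synth_cohort(3, small_instr_spec(), small_ctrl_spec(), seed = 5)
  c2 <- synth_cohort(3, small_instr_spec(), small_ctrl_spec(), seed = 5)
  expect_identical(c1$mice$mouse02$instrumented$field$vectors,
                   c2$mice$mouse02$instrumented$field$vectors)
  expect_error(synth_cohort(1, small_instr_spec(), small_ctrl_spec()),
               ">= 2")
  vels <- vapply(c1$mice, function(m) m$control$spec$mean_velocity, 0)
  expect_true(all(abs(vels - 153.4) / 153.4 <= 0.1 + 1e-12))
})
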