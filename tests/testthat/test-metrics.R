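# 30-instant reversal field: 20 instants at (+1,0,0) Pa, 10 at (-1,0,0) Pa
reversal_field <- function() {
  field_from_instants(c(replicate(20, c(1, 0, 0), simplify = FALSE),
                        replicate(10, c(-1, 0, 0), simplify = FALSE)))
}

test_that("TAWSS is the time-mean shear magnitude", {
  const <- field_from_instants(replicate(30, c(0, 0, 2), simplify = FALSE))
  expect_equal(as.numeric(tawss(const)), 2)
  expect_equal(as.numeric(tawss(reversal_field())), 1)
  # homogeneity of degree one
  f <- reversal_field()
  f$vectors <- f$vectors * 3.7
  expect_equal(as.numeric(tawss(f)), 3.7)
  empty <- make_field(array(0, c(1, 3, 1)))
  expect_error(tawss(empty), "instants")
})

test_that("OSI measures reversal, 0 unidirectional to 0.5 oscillatory", {
  uni <- field_from_instants(replicate(30, c(1, 0, 0), simplify = FALSE))
  expect_equal(as.numeric(osi(uni)), 0)
  half <- field_from_instants(c(replicate(15, c(2, 0, 0), simplify = FALSE),
                                replicate(15, c(-2, 0, 0), simplify = FALSE)))
  expect_equal(as.numeric(osi(half)), 0.5)
  expect_equal(as.numeric(osi(reversal_field())), 1 / 3)
  zero <- field_from_instants(replicate(30, c(0, 0, 0), simplify = FALSE))
  oz <- osi(zero)
  expect_equal(as.numeric(oz), 0)
  expect_equal(attr(oz, "n_zero"), 1L)
})

test_that("RRT is the reciprocal mean-vector magnitude", {
  const <- field_from_instants(replicate(30, c(0, 0, 2), simplify = FALSE))
  expect_equal(as.numeric(rrt(const)), 0.5)
  expect_equal(as.numeric(rrt(reversal_field())), 3)
  # identity RRT * ||mean vector|| = 1 and consistency with (1-2 OSI) TAWSS
  set.seed(1)
  vec <- array(rnorm(20 * 3 * 30), c(20, 3, 30))
  f <- make_field(vec)
  r <- as.numeric(rrt(f))
  alt <- 1 / ((1 - 2 * as.numeric(osi(f))) * as.numeric(tawss(f)))
  expect_equal(r, alt, tolerance = 1e-9)
})

test_that("transWSS catches multidirectionality but not pure reversal", {
  normals <- matrix(c(0, 0, 1), 1, 3, byrow = TRUE)
  # pure reversal along one axis: zero transverse component
  expect_equal(as.numeric(transwss(reversal_field(), normals)), 0)
  ortho <- field_from_instants(c(replicate(15, c(1, 0, 0), simplify = FALSE),
                                 replicate(15, c(0, 1, 0), simplify = FALSE)))
  expect_equal(as.numeric(transwss(ortho, normals)), 1 / sqrt(2),
               tolerance = 1e-12)
  # bound tSS <= TAWSS on random fields
  set.seed(2)
  vec <- array(rnorm(30 * 3 * 30), c(30, 3, 30))
  f <- make_field(vec)
  nm <- matrix(rnorm(90), 30, 3)
  nm <- nm / sqrt(rowSums(nm^2))
  expect_true(all(as.numeric(transwss(f, nm)) <=
                    as.numeric(tawss(f)) + 1e-12))
})

test_that("SAD averages neighbour angle differences over the cycle", {
  # two nodes, constant 90 degrees apart
  vec <- array(0, c(2, 3, 30))
  vec[1, 1, ] <- 1
  vec[2, 2, ] <- 1
  f <- make_field(vec)
  adj <- list(2L, 1L)
  expect_equal(as.numeric(sad(f, adj)), c(pi / 2, pi / 2))
  # spatially uniform direction: zero everywhere
  uni <- array(rep(c(1, 2, 3), each = 5), c(5, 3, 1))
  uni <- array(rep(uni, 30), c(5, 3, 30))
  fu <- make_field(uni)
  adj5 <- lapply(1:5, function(j) setdiff(1:5, j))
  expect_equal(as.numeric(sad(fu, adj5)), rep(0, 5), tolerance = 1e-7)
  # invariance under a global rotation of all vectors
  set.seed(3)
  vec <- array(rnorm(10 * 3 * 8), c(10, 3, 8))
  adj10 <- lapply(1:10, function(j) setdiff(1:10, j)[1:3])
  ang <- 1.1
  Rm <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
              c(0, 0, 1))
  rot <- vec
  for (i in 1:8) rot[, , i] <- vec[, , i] %*% t(Rm)
  expect_equal(as.numeric(sad(make_field(rot), adj10)),
               as.numeric(sad(make_field(vec), adj10)), tolerance = 1e-10)
  expect_error(sad(f, list(integer(0), 1L)), "isolated")
})

test_that("threshold calibration matches the log-normal quartiles", {
  # zero spread: both thresholds collapse onto the common value
  thr0 <- fit_thresholds(rep(1.5, 50))
  expect_equal(thr0$low, 1.5)
  expect_equal(thr0$high, 1.5)
  # population limit for standard log-normal
  set.seed(99)
  x <- exp(rnorm(1e4))
  thr <- fit_thresholds(x)
  expect_equal(thr$low, exp(-0.67), tolerance = 0.02)
  expect_equal(thr$high, exp(0.67), tolerance = 0.02)
  # bottom quartile isolated within 2 points
  expect_equal(100 * mean(x < thr$low), 25, tolerance = 0.08)
  # scale equivariance
  thr2 <- fit_thresholds(3 * x)
  expect_equal(thr2$low, 3 * thr$low, tolerance = 1e-9)
  expect_equal(thr2$high, 3 * thr$high, tolerance = 1e-9)
  expect_error(fit_thresholds(c(1, -1, 2)), "positive")
  expect_error(fit_thresholds(2), "at least 2")
})

test_that("LSI and HSI are clamped, mutually exclusive indices", {
  thr <- structure(list(low = 1, high = 2, mean_log = log(sqrt(2)),
                        sd_log = NA), class = "tawss_thresholds")
  tw <- metric_map(c(1, 0.5, 1.5, 2, 4, 1e6), "TAWSS")
  l <- as.numeric(lsi(tw, thr))
  h <- as.numeric(hsi(tw, thr))
  expect_equal(l, c(0, 0.5, 0, 0, 0, 0))
  expect_equal(h, c(0, 0, 0, 0, 0.5, 1 - 2e-6))
  expect_true(all(l * h == 0))
  expect_true(all(l >= 0 & l <= 1 & h >= 0 & h < 1))
  # zero TAWSS: HSI defined as 0
  expect_equal(as.numeric(hsi(metric_map(0, "TAWSS"), thr)), 0)
})

test_that("display normalization uses theoretical maxima where they exist", {
  expect_equal(as.numeric(normalize_display(metric_map(0.5, "OSI"))), 1)
  expect_equal(as.numeric(normalize_display(metric_map(pi / 2, "SAD"))), 0.5)
  r <- metric_map(c(0.2, 5, Inf), "RRT")
  nr <- as.numeric(normalize_display(r, observed_max = 5))
  expect_equal(nr, c(0.04, 1, 1))
  expect_error(normalize_display(metric_map(1, "TAWSS")), "observed_max")
})

test_that("vectorized metrics agree with brute-force oracles to 1e-10", {
  tube <- build_tube_mesh(0.25, 2, 5, 8)   # 40 nodes
  adj <- node_neighbors(tube)
  set.seed(17)
  for (rep in 1:3) {
    vec <- array(rnorm(40 * 3 * 30), c(40, 3, 30))
    # include some exactly-zero node-instants
    vec[1, , 5] <- 0
    f <- make_field(vec, mesh = tube)
    expect_equal(as.numeric(tawss(f)), oracle_tawss(vec), tolerance = 1e-10)
    expect_equal(as.numeric(osi(f)), oracle_osi(vec), tolerance = 1e-10)
    expect_equal(as.numeric(rrt(f)), oracle_rrt(vec), tolerance = 1e-10)
    expect_equal(as.numeric(transwss(f)), oracle_transwss(vec, tube$normals),
                 tolerance = 1e-10)
    expect_equal(as.numeric(sad(f, adj)), oracle_sad(vec, adj),
                 tolerance = 1e-10)
  }
})

test_that("30-instant export stride approximates the 300-step cycle to 2%", {
  spec30 <- small_instr_spec()
  spec300 <- small_instr_spec(export_every = 1)
  build <- function(spec) {
    rprof <- radius_profile(spec)
    tube <- build_tube_mesh(rprof, spec$vessel_length, spec$n_axial,
                            spec$n_circ)
    f <- parameterize(tube)
    fld <- quasi_steady_wss(tube, f, rprof, make_waveform(spec),
                            fluid_props(), spec)
    apply_downstream_disturbance(fld, f, spec)
  }
  f30 <- build(spec30)
  f300 <- build(spec300)
  rel <- function(a, b) max(abs(a - b) / pmax(abs(b), 0.05))
  expect_lt(rel(as.numeric(tawss(f30)), as.numeric(tawss(f300))), 0.02)
  expect_lt(rel(as.numeric(osi(f30)), as.numeric(osi(f300))), 0.02)
  expect_lt(rel(as.numeric(transwss(f30)), as.numeric(transwss(f300))),
            0.02)
})
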