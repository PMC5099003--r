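# Independent brute-force implementations of the shear metrics, written as
# plain loops over the definitions. They share no code with the package and
# exist to cross-check the vectorized implementations on small random
# fields.

oracle_tawss <- function(vec) {
  n <- dim(vec)[1L]; ni <- dim(vec)[3L]
  out <- numeric(n)
  for (j in seq_len(n)) {
    s <- 0
    for (i in seq_len(ni)) s <- s + sqrt(sum(vec[j, , i]^2))
    out[j] <- s / ni
  }
  out
}

oracle_osi <- function(vec) {
  n <- dim(vec)[1L]; ni <- dim(vec)[3L]
  out <- numeric(n)
  for (j in seq_len(n)) {
    mv <- c(0, 0, 0); den <- 0
    for (i in seq_len(ni)) {
      mv <- mv + vec[j, , i]
      den <- den + sqrt(sum(vec[j, , i]^2))
    }
    out[j] <- if (den > 0) 0.5 * (1 - sqrt(sum(mv^2)) / den) else 0
  }
  out
}

oracle_rrt <- function(vec) {
  n <- dim(vec)[1L]; ni <- dim(vec)[3L]
  out <- numeric(n)
  for (j in seq_len(n)) {
    mv <- c(0, 0, 0)
    for (i in seq_len(ni)) mv <- mv + vec[j, , i] / ni
    nrm <- sqrt(sum(mv^2))
    out[j] <- if (nrm > 0) 1 / nrm else Inf
  }
  out
}

oracle_transwss <- function(vec, normals) {
  n <- dim(vec)[1L]; ni <- dim(vec)[3L]
  out <- numeric(n)
  for (j in seq_len(n)) {
    mv <- c(0, 0, 0)
    for (i in seq_len(ni)) mv <- mv + vec[j, , i] / ni
    nrm <- sqrt(sum(mv^2))
    if (nrm == 0) next
    p <- mv / nrm
    nn <- normals[j, ]
    q <- c(nn[2] * p[3] - nn[3] * p[2],
           nn[3] * p[1] - nn[1] * p[3],
           nn[1] * p[2] - nn[2] * p[1])
    qn <- sqrt(sum(q^2))
    if (qn == 0) next
    q <- q / qn
    s <- 0
    for (i in seq_len(ni)) s <- s + abs(sum(vec[j, , i] * q))
    out[j] <- s / ni
  }
  out
}

oracle_sad <- function(vec, adjacency) {
  n <- dim(vec)[1L]; ni <- dim(vec)[3L]
  out <- numeric(n)
  for (j in seq_len(n)) {
    acc <- 0
    for (i in seq_len(ni)) {
      aj <- 0
      for (k in adjacency[[j]]) {
        nj <- sqrt(sum(vec[j, , i]^2))
        nk <- sqrt(sum(vec[k, , i]^2))
        if (nj > 0 && nk > 0) {
          cth <- sum(vec[j, , i] * vec[k, , i]) / (nj * nk)
          aj <- aj + acos(min(max(cth, -1), 1))
        }
      }
      acc <- acc + aj / length(adjacency[[j]])
    }
    out[j] <- acc / ni
  }
  out
}

# Wrap a raw vector array as the field object the package metrics consume.
make_field <- function(vec, period = 0.125, mesh = NULL) {
  ni <- dim(vec)[3L]
  structure(list(vectors = vec, times = (seq_len(ni) - 1) * period / ni,
                 period = period, mesh = mesh, frame = NULL),
            class = "wss_field")
}

# Constant-in-space field from a list of per-instant vectors replicated
# over n nodes.
field_from_instants <- function(instants, n_nodes = 1L) {
  ni <- length(instants)
  vec <- array(0, c(n_nodes, 3L, ni))
  for (i in seq_len(ni)) vec[, , i] <- matrix(instants[[i]], n_nodes, 3L,
                                              byrow = TRUE)
  make_field(vec)
}

# ASCII STL of the unit cube (12 facets), written by hand.
write_cube_stl <- function(path) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  tris <- rbind(c(1, 3, 2), c(1, 4, 3),   # z = 0
                c(5, 6, 7), c(5, 7, 8),   # z = 1
                c(1, 2, 6), c(1, 6, 5),   # y = 0
                c(3, 4, 8), c(3, 8, 7),   # y = 1
                c(2, 3, 7), c(2, 7, 6),   # x = 1
                c(4, 1, 5), c(4, 5, 8))   # x = 0
  lines <- c("solid cube")
  for (t in seq_len(nrow(tris))) {
    lines <- c(lines, " facet normal 0 0 0", "  outer loop")
    for (k in 1:3)
      lines <- c(lines, sprintf("   vertex %g %g %g",
                                v[tris[t, k], 1], v[tris[t, k], 2],
                                v[tris[t, k], 3]))
    lines <- c(lines, "  endloop", " endfacet")
  }
  writeLines(c(lines, "endsolid cube"), path)
  path
}

# Per-node-per-instant shear magnitudes, independent of package internals.
field_mags <- function(field) {
  sqrt(field$vectors[, 1, ]^2 + field$vectors[, 2, ]^2 +
         field$vectors[, 3, ]^2)
}

# Small vessel specs for fast end-to-end tests.
small_instr_spec <- function(...) {
  vessel_spec(n_axial = 41, n_circ = 12, ...)
}
small_ctrl_spec <- function(...) {
  control_vessel_spec(n_axial = 41, n_circ = 12, ...)
}
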