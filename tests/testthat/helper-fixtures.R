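# Shared fixtures and independent oracles used across test files.

# Hand-written 3-atom PDB (coordinates in Angstrom; 10 A = 1 nm).
write_tiny_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      10.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1      12.000   1.500  -2.500  1.00  0.00           C",
    "END"), path)
  path
}

# Minimal GRO file (nm units, fixed-width).
write_tiny_gro <- function(path) {
  writeLines(c(
    "toy system",
    "    3",
    "    1ALA      N    1   1.000   0.000   0.000",
    "    1ALA     CA    2   1.146   0.000   0.000",
    "    1ALA     CB    3   1.200   0.150  -0.250",
    "   5.00000   5.00000   5.00000"), path)
  path
}

# Independent superposition oracle: exhaustive Euler-angle grid search
# (coarse pass then local refinement) over proper rotations, optimal
# translation analytic (centroid match). Never calls the package fit.
grid_superpose_rmsd <- function(frame, reference) {
  rot_euler <- function(a, b, c) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cc <- cos(c); sc <- sin(c)
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
    Rz2 <- matrix(c(cc, -sc, 0, sc, cc, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  A <- sweep(frame, 2, colMeans(frame))
  B <- sweep(reference, 2, colMeans(reference))
  eval_rmsd <- function(a, b, c) {
    R <- rot_euler(a, b, c)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  best <- c(0, 0, 0); best_val <- Inf
  crs <- pi / 20                          # 9-degree coarse grid
  for (a in seq(0, 2 * pi - crs, by = crs))
    for (b in seq(0, pi, by = crs))
      for (c in seq(0, 2 * pi - crs, by = crs)) {
        v <- eval_rmsd(a, b, c)
        if (v < best_val) { best_val <- v; best <- c(a, b, c) }
      }
  for (step in c(pi / 180, pi / 720)) {   # 1-degree then 0.25-degree
    rng <- seq(-9 * step, 9 * step, by = step)
    centre <- best
    for (da in rng) for (db in rng) for (dc in rng) {
      v <- eval_rmsd(centre[1] + da, centre[2] + db, centre[3] + dc)
      if (v < best_val) {
        best_val <- v
        best <- centre + c(da, db, dc)
      }
    }
  }
  best_val
}

# Random proper rotation matrix.
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Single-residue two-state synthetic setup on the published flux scale.
two_state_spec <- function(n_pores = 8, duration_ns = 400,
                           sigma_u = 0.2, phi = 10) {
  synthetic_spec(
    n_pores = n_pores, duration_ns = duration_ns,
    residues = list(gate = list(states = c("open", "blocked"),
                                reference = "open",
                                stationary = c(0.7, 0.3),
                                base_dwell_ns = 10)),
    truth = list(alpha = log(4.6),
                 beta = c(gate.blocked = log(1.0 / 4.6)),
                 sigma_u = sigma_u, phi = phi))
}

# Event table from scratch (for windowing/ratio arithmetic tests).
make_events <- function(exit_ns, direction = 1L) {
  n <- length(exit_ns)
  ev <- data.frame(water_id = seq_len(n),
                   direction = rep_len(direction, n),
                   entry_ns = exit_ns - 0.5, exit_ns = exit_ns,
                   transit_ns = rep_len(0.5, n),
                   entry_frame = rep_len(1L, n),
                   exit_frame = rep_len(2L, n),
                   max_radial_nm = rep_len(0.1, n))
  class(ev) <- c("permeation_events", "data.frame")
  ev
}
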