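# Segment RMSD, water dipole tilt profile and hydrogen-bond counts.

test_that("segment RMSD is zero for the reference and after rigid motion", {
  ref <- synthetic_reference_structure()
  segs <- list(s1 = c(21, 29, 48), s2 = c(196, 200, 202, 206))
  m <- coords(ref)
  coords3 <- array(NA_real_, c(2, nrow(m), 3))
  coords3[1, , ] <- m
  set.seed(3)
  R <- random_rotation()
  coords3[2, , ] <- sweep(m %*% R, 2, c(0.5, -1, 2), "+")
  tr <- trajectory(coords3, ref$atoms$atom_id)
  out <- segment_rmsd(tr, ref, segs, chain_id = "A")
  expect_equal(out$mean_rmsd_nm, c(0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(segment_rmsd(tr, ref, list(bad = 999), chain_id = "A"),
               "unresolvable")
})

test_that("a uniformly displaced segment reports its displacement", {
  ref <- synthetic_reference_structure()
  segs <- list(moved = c(21, 29), fixed = c(196, 200, 202, 206, 48))
  fit_ids <- atom_ids_of(ref, "A", segs$fixed, "CA")
  m <- coords(ref)
  moved_ids <- as.character(atom_ids_of(ref, "A", segs$moved))
  m[moved_ids, 3] <- m[moved_ids, 3] + 0.1
  coords3 <- array(m, c(1, nrow(m), 3))
  coords3[1, , ] <- m
  tr <- trajectory(coords3, ref$atoms$atom_id)
  out <- segment_rmsd(tr, ref, segs, fit_selection = fit_ids,
                      chain_id = "A")
  expect_equal(out$mean_rmsd_nm[out$segment == "moved"], 0.1,
               tolerance = 1e-9)
  expect_equal(out$mean_rmsd_nm[out$segment == "fixed"], 0,
               tolerance = 1e-9)
  # SEM aggregation across protomers
  agg <- segment_rmsd_sem(list(out, out))
  expect_equal(agg$sem_rmsd_nm, c(0, 0))
  expect_equal(agg$n_pores, c(2L, 2L))
})

make_water_topology <- function(n) {
  structure_model(data.frame(
    atom_id = seq_len(3 * n),
    atom_name = rep(c("OW", "HW1", "HW2"), n),
    residue_name = "SOL",
    residue_number = rep(seq_len(n), each = 3),
    chain_id = "W", element = rep(c("O", "H", "H"), n),
    x = 0, y = 0, z = 0))
}

water_frame <- function(o, h1, h2) {
  cf <- array(NA_real_, c(1, 3, 3))
  cf[1, 1, ] <- o; cf[1, 2, ] <- h1; cf[1, 3, ] <- h2
  cf
}

test_that("dipole tilt is the bisector angle to the membrane normal", {
  top <- make_water_topology(1)
  d <- 0.08
  up <- trajectory(water_frame(c(0, 0, 0), c(d, 0, d), c(-d, 0, d)), 1:3)
  out <- dipole_tilt_profile(up, top, z_breaks = c(-1, 1))
  expect_equal(out$mean_tilt_deg, 0, tolerance = 1e-9)
  down <- trajectory(water_frame(c(0, 0, 0), c(d, 0, -d), c(-d, 0, -d)),
                     1:3)
  expect_equal(dipole_tilt_profile(down, top,
                                   c(-1, 1))$mean_tilt_deg, 180,
               tolerance = 1e-9)
  # empty bins are reported with n = 0
  out2 <- dipole_tilt_profile(up, top, z_breaks = c(-1, 0.5, 2))
  expect_equal(out2$n, c(1L, 0L))
})

test_that("isotropic water orientations average to 90 degrees", {
  n <- 400
  top <- make_water_topology(n)
  set.seed(8)
  cf <- array(NA_real_, c(1, 3 * n, 3))
  for (i in seq_len(n)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))  # uniform direction
    v <- stats::rnorm(3); v <- v - sum(v * u) * u
    v <- v / sqrt(sum(v^2))
    o <- stats::runif(3)
    cf[1, 3 * i - 2, ] <- o
    cf[1, 3 * i - 1, ] <- o + 0.06 * u + 0.08 * v
    cf[1, 3 * i, ] <- o + 0.06 * u - 0.08 * v
  }
  tr <- trajectory(cf, seq_len(3 * n))
  out <- dipole_tilt_profile(tr, top, z_breaks = c(-1, 2))
  se <- out$sd_tilt_deg / sqrt(out$n)
  expect_lt(abs(out$mean_tilt_deg - 90), 3 * se)
})

hbond_system <- function(o_pos, dist_oa = 0.29, residue_name = "ALA",
                         sc_atoms = c("CB", "CG", "OD1")) {
  n_res <- length(sc_atoms)
  atoms <- data.frame(
    atom_id = seq_len(3 + n_res),
    atom_name = c("OW", "HW1", "HW2", sc_atoms),
    residue_name = c(rep("SOL", 3), rep(residue_name, n_res)),
    residue_number = c(1, 1, 1, rep(10, n_res)),
    chain_id = c(rep("W", 3), rep("A", n_res)),
    element = c("O", "H", "H", substr(sc_atoms, 1, 1)),
    x = 0, y = 0, z = 0)
  top <- structure_model(atoms)
  cf <- array(0, c(1, 3 + n_res, 3))
  cf[1, 1, ] <- o_pos                          # water O
  cf[1, 2, ] <- o_pos + c(0.098, 0, 0)          # H pointing at acceptor
  cf[1, 3, ] <- o_pos + c(-0.03, 0.093, 0)
  acc <- o_pos + c(dist_oa, 0, 0)               # acceptor on the H axis
  for (k in seq_len(n_res))
    cf[1, 3 + k, ] <- acc + (k - n_res) * c(0.15, 0.12, 0)
  tr <- trajectory(cf, seq_len(3 + n_res))
  list(top = top, tr = tr)
}

test_that("hydrogen bonds follow the 0.35 nm / 30 degree criterion", {
  hs <- hbond_system(c(0, 0, 0), dist_oa = 0.29)
  out <- water_hbond_counts(hs$tr, hs$top, residues = 10)
  expect_equal(out$mean_hbonds, 1)
  far <- hbond_system(c(0, 0, 0), dist_oa = 0.40)
  expect_equal(water_hbond_counts(far$tr, far$top, 10)$mean_hbonds, 0)
  # swapping the two water hydrogens changes nothing
  swapped <- hs$tr
  h1 <- swapped$coords[1, 2, ]
  swapped$coords[1, 2, ] <- swapped$coords[1, 3, ]
  swapped$coords[1, 3, ] <- h1
  expect_equal(water_hbond_counts(swapped, hs$top, 10)$mean_hbonds, 1)
})

test_that("valine side chains form no hydrogen bonds with water", {
  hs <- hbond_system(c(0, 0, 0), dist_oa = 0.29, residue_name = "VAL",
                     sc_atoms = c("CB", "CG1", "CG2"))
  expect_equal(water_hbond_counts(hs$tr, hs$top, 10)$mean_hbonds, 0)
})

test_that("hydrogen-free topologies are rejected with guidance", {
  ref <- synthetic_reference_structure()
  m <- coords(ref)
  tr <- trajectory(array(m, c(1, nrow(m), 3)), ref$atoms$atom_id)
  expect_error(water_hbond_counts(tr, ref, 206),
               "no hydrogens")
})
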