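# Gating descriptors: dihedrals, minimal side-chain distances, state
# classification and populations.

ref <- synthetic_reference_structure()
reg <- gating_registry()

test_that("side-chain dihedrals reproduce the crystal-state calibration", {
  ids_w <- vapply(c("CA", "CB", "CG", "CD1"), function(nm)
    atom_ids_of(ref, "A", 48, nm), 0L)
  expect_equal(dihedral_angle(ref, ids_w, c(-180, 180)), 103,
               tolerance = 1 / 103)
  ids_r <- vapply(c("CA", "CB", "CG", "CZ"), function(nm)
    atom_ids_of(ref, "A", 206, nm), 0L)
  expect_equal(dihedral_angle(ref, ids_r, c(0, 360)), 311,
               tolerance = 1 / 311)
  # planar zig-zag quadruple is cis: torsion 0
  expect_equal(torsion(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_error(torsion(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "colinear")
})

test_that("dihedrals are rigid-motion invariant and mirror-negated", {
  set.seed(5)
  p <- lapply(1:4, function(i) stats::rnorm(3))
  d0 <- do.call(torsion, p)
  R <- random_rotation(); tv <- stats::rnorm(3)
  moved <- lapply(p, function(x) drop(R %*% x) + tv)
  expect_equal(do.call(torsion, moved), d0, tolerance = 1e-9)
  mirrored <- lapply(p, function(x) x * c(1, 1, -1))
  expect_equal(do.call(torsion, mirrored), -d0, tolerance = 1e-9)
})

test_that("minimal side-chain distances obey metric basics", {
  expect_equal(min_sidechain_distance(ref, ref, 202, 21), 0.82,
               tolerance = 0.02 / 0.82)
  # symmetry
  expect_equal(min_sidechain_distance(ref, ref, 21, 202),
               min_sidechain_distance(ref, ref, 202, 21))
  # 3-4-5 triangle on a toy two-residue structure
  toy <- structure_model(data.frame(
    atom_id = 1:4, atom_name = c("CB", "CG", "CB", "CG"),
    residue_name = "XXX", residue_number = c(1, 1, 2, 2),
    chain_id = "A", element = "C",
    x = c(0, 5, 0.3, 9), y = c(0, 5, 0.4, 9), z = 0))
  expect_equal(min_sidechain_distance(toy, toy, 1, 2), 0.5)
  # identical atom positions give zero
  toy$atoms$x[3] <- 0; toy$atoms$y[3] <- 0
  expect_equal(min_sidechain_distance(toy, toy, 1, 2), 0)
  # never exceeds any single inter-atom distance between the sets
  expect_lte(min_sidechain_distance(ref, ref, 200, 196),
             sqrt(sum((coords(ref, atom_ids_of(ref, "A", 200, "CG")) -
                         coords(ref, atom_ids_of(ref, "A", 196, "CG")))^2)))
  # glycine has no side chain under the heavy policy
  gly <- structure_model(data.frame(
    atom_id = 1:2, atom_name = c("N", "CA"), residue_name = "GLY",
    residue_number = 1, chain_id = "A", element = c("N", "C"),
    x = c(0, 0.15), y = 0, z = 0))
  expect_error(sidechain_atoms(gly, 1), "side-chain")
})

test_that("minimum-image convention is honoured under a periodic box", {
  toy <- structure_model(data.frame(
    atom_id = 1:2, atom_name = "CB", residue_name = "XXX",
    residue_number = 1:2, chain_id = "A", element = "C",
    x = c(0.1, 4.9), y = 0, z = 0))
  expect_equal(min_sidechain_distance(toy, toy, 1, 2), 4.8)
  expect_equal(min_sidechain_distance(toy, toy, 1, 2, box = c(5, 5, 5)),
               0.2, tolerance = 1e-9)
})

test_that("classification uses half-open bins with strict thresholds", {
  r206 <- reg$r206
  expect_equal(as.character(classify_states(311, r206)$states), "a290_360")
  w48 <- reg$w48
  expect_equal(as.character(classify_states(-120, w48)$states), "blocked")
  # a boundary value belongs to the upper bin: 0.37 is already "far"
  f200 <- reg$f200
  expect_equal(as.character(classify_states(0.37, f200)$states), "far")
  expect_equal(as.character(classify_states(0.37 - 1e-9, f200)$states),
               "near")
  # angle wrap happens inside the definition domain
  expect_equal(as.character(classify_states(-49, r206)$states), "a290_360")
})

test_that("the crystal-calibrated reference classifies as open everywhere", {
  for (rid in names(reg)) {
    d <- reg[[rid]]
    v <- if (d$metric == "dihedral") {
      ids <- vapply(d$atoms, function(nm)
        atom_ids_of(ref, "A", d$residue_number, nm), 0L)
      dihedral_angle(ref, ids, d$domain)
    } else {
      min_sidechain_distance(ref, ref, d$residue_number,
                             d$partner_residue)
    }
    expect_equal(as.character(classify_states(v, d)$states), d$reference,
                 label = paste(rid, "state"))
  }
})

test_that("state populations sum to one and match Markov stationarity", {
  tr <- state_trace(rep(c("a", "b"), c(3, 7)), frame_period_ps = 10)
  p <- state_populations(tr)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(unname(p["a"]), 0.3)
  one <- state_trace(rep("x", 5))
  expect_equal(unname(state_populations(one)), 1)
  expect_error(state_populations(tr, c(100, 200)), "no frames")

  # long CTMC with equal dwells: stationary 0.5/0.5 within 3 SE of the
  # effective number of dwell segments
  spec <- synthetic_spec(
    n_pores = 1, duration_ns = 5000,
    residues = list(g = list(states = c("a", "b"), reference = "a",
                             stationary = c(0.5, 0.5),
                             base_dwell_ns = 10)))
  tr2 <- simulate_state_traces(spec, seed = 2)[[1]]$g
  n_seg <- 5000 / 10
  se <- 0.5 / sqrt(n_seg)
  expect_lt(abs(state_populations(tr2)[["a"]] - 0.5), 3 * se)
})

test_that("the registry serialises to YAML and back", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_registry(reg, f)
  back <- read_registry(f)
  expect_equal(names(back), names(reg))
  for (rid in names(reg)) {
    expect_equal(back[[rid]]$breaks, reg[[rid]]$breaks)
    expect_equal(back[[rid]]$labels, reg[[rid]]$labels)
    expect_equal(back[[rid]]$reference, reg[[rid]]$reference)
  }
})

test_that("metric series over trajectories match per-frame evaluation", {
  m <- coords(ref)
  coords3 <- array(NA_real_, c(2, nrow(m), 3))
  coords3[1, , ] <- m
  R <- random_rotation()
  coords3[2, , ] <- sweep(m %*% R, 2, c(1, 0, -1), "+")
  tr <- trajectory(coords3, ref$atoms$atom_id)
  v <- gating_metric_series(tr, ref, reg$w48, chain_id = "A")
  expect_equal(v[1], 103, tolerance = 1 / 103)
  expect_equal(v[2], v[1], tolerance = 1e-6)   # rigid-motion invariant
  d <- gating_metric_series(tr, ref, reg$m202, chain_id = "A")
  expect_equal(d[2], d[1], tolerance = 1e-9)
})
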