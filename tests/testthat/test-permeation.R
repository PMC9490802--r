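# Cylinder compartments, the crossing state machine, the containment
# filter, windowed flux counts and transit statistics.

test_that("compartment labels follow the cylinder geometry", {
  # three waters in one frame: center, radially out, axially above
  coords <- array(NA_real_, c(1, 3, 3))
  coords[1, 1, ] <- c(0, 0, 0)         # center -> inside
  coords[1, 2, ] <- c(1.6, 0, 0)       # r = 1.6 > 1.5 -> outside_radius
  coords[1, 3, ] <- c(0, 0, 1.2)       # z = 1.2 > 1.1 -> above
  tr <- trajectory(coords, 1:3)
  comp <- assign_compartments(tr, cylinder_spec())
  expect_equal(comp$labels[1, ], c(2L, 4L, 3L))
  expect_error(
    assign_compartments(tr, cylinder_spec(),
                        topology = structure_model(data.frame(
                          atom_id = 1L, atom_name = "CA",
                          residue_name = "ALA", residue_number = 1L,
                          chain_id = "A", element = "C",
                          x = 0, y = 0, z = 0))),
    "no water")
})

test_that("the state machine detects, resets and voids crossings", {
  ev <- detect_permeation_events(
    matrix(c("below", "inside", "inside", "above"), ncol = 1),
    frame_period_ps = 1000)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, 1)
  expect_equal(ev$transit_ns, 2)       # exit at frame 4, entry at frame 2

  # cap revisit restarts the transit clock: entry at the SECOND inside
  ev2 <- detect_permeation_events(
    matrix(c("below", "inside", "below", "inside", "above"), ncol = 1),
    frame_period_ps = 1000)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$entry_ns, 3)        # frame 4 at 1 ns per frame
  expect_equal(ev2$transit_ns, 1)

  # touching outside_radius voids the attempt
  ev3 <- detect_permeation_events(
    matrix(c("below", "inside", "outside_radius", "above"), ncol = 1))
  expect_equal(nrow(ev3), 0)

  # reverse crossing carries direction -1
  ev4 <- detect_permeation_events(
    matrix(c("above", "inside", "below"), ncol = 1))
  expect_equal(ev4$direction, -1)

  expect_equal(nrow(detect_permeation_events(
    matrix(character(0), ncol = 1))), 0)
})

test_that("the containment filter removes around-protein paths only", {
  spec <- synthetic_spec()
  toy <- simulate_toy_trajectory(spec, seed = 3)
  comp <- assign_compartments(toy$trajectory, toy$cylinder)
  raw <- detect_permeation_events(comp)
  kept <- filter_spurious_events(raw, comp)
  expect_equal(nrow(kept), spec$toy$n_crossers)
  expect_equal(nrow(attr(kept, "removed")),
               spec$toy$n_radial_escapees)
  expect_true(all(kept$max_radial_nm < 0.4))
  expect_error(filter_spurious_events(raw, comp, r_sf = 2),
               "exceeds the cylinder radius")
  # with the containment radius opened to the cylinder, nothing is cut
  all_kept <- filter_spurious_events(raw, comp,
                                     r_sf = comp$cylinder$radius - 1e-9)
  expect_equal(nrow(all_kept), nrow(raw))
})

test_that("planted crossings are recovered exactly across seeds", {
  spec <- synthetic_spec()
  for (sd in 1:5) {
    toy <- simulate_toy_trajectory(spec, seed = sd)
    comp <- assign_compartments(toy$trajectory, toy$cylinder)
    kept <- filter_spurious_events(detect_permeation_events(comp), comp)
    expect_equal(nrow(kept), nrow(toy$truth))
    expect_equal(sort(kept$water_id), sort(toy$truth$water_id))
    expect_equal(kept$direction[order(kept$water_id)],
                 toy$truth$direction[order(toy$truth$water_id)])
  }
})

test_that("time reversal flips directions and negates the net count", {
  spec <- synthetic_spec()
  toy <- simulate_toy_trajectory(spec, seed = 4)
  comp <- assign_compartments(toy$trajectory, toy$cylinder)
  fwd <- filter_spurious_events(detect_permeation_events(comp), comp)
  rev_traj <- toy$trajectory
  rev_traj$coords <- rev_traj$coords[rev(seq_len(n_frames(rev_traj))), , ,
                                     drop = FALSE]
  comp_r <- assign_compartments(rev_traj, toy$cylinder)
  bwd <- filter_spurious_events(detect_permeation_events(comp_r), comp_r)
  expect_equal(nrow(bwd), nrow(fwd))
  expect_equal(sum(bwd$direction), -sum(fwd$direction))
  win <- matrix(c(0, spec$toy$duration_ns + 1), 1)
  expect_equal(flux_in_windows(bwd, win, "total"),
               flux_in_windows(fwd, win, "total"))
  expect_equal(flux_in_windows(bwd, win, "net"),
               -flux_in_windows(fwd, win, "net"))
})

test_that("windowed counts use half-open windows on exit times", {
  ev <- make_events(exit_ns = 1:10)
  expect_equal(flux_in_windows(ev, matrix(c(0, 100), 1), "total"), 10L)
  expect_equal(flux_in_windows(ev, matrix(c(0, 100), 1), "net"), 10L)

  bal <- make_events(exit_ns = 1:10, direction = rep(c(1L, -1L), 5))
  expect_equal(flux_in_windows(bal, matrix(c(0, 100), 1), "total"), 10L)
  expect_equal(flux_in_windows(bal, matrix(c(0, 100), 1), "net"), 0L)

  ev3 <- make_events(exit_ns = c(1, 2, 3))
  w <- rbind(c(0, 2), c(2, 4))
  expect_equal(flux_in_windows(ev3, w), c(1L, 2L))
  expect_error(flux_in_windows(ev3, rbind(c(0, 2), c(1, 3))),
               "overlap")
  expect_silent(flux_in_windows(ev3, rbind(c(0, 2), c(1, 3)),
                                allow_overlap = TRUE))
})

test_that("transit-time statistics are plain arithmetic", {
  ev <- make_events(exit_ns = c(2, 4, 6))
  ev$transit_ns <- c(1, 2, 3)
  st <- transit_time_stats(ev)
  expect_equal(st$mean_ns, 2)
  expect_equal(st$frac_below_1ns, 0)
  expect_equal(st$frac_below_3ns, 2 / 3)

  one <- make_events(exit_ns = 3); one$transit_ns <- 2.8
  expect_equal(transit_time_stats(one)$mean_ns, 2.8)
  expect_error(transit_time_stats(make_events(numeric(0))), "undefined")

  # seeded generator moments: gamma transits with known mean
  set.seed(21)
  tt <- stats::rgamma(1000, shape = 4, rate = 4 / 2.8)  # mean 2.8
  evg <- make_events(exit_ns = cumsum(tt)); evg$transit_ns <- tt
  se <- sd(tt) / sqrt(length(tt))
  expect_lt(abs(transit_time_stats(evg)$mean_ns - 2.8), 3 * se)
})
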