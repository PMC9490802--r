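# Synthetic generators: CTMC traces, NB flux counts, toy trajectories,
# and the analytic truth report.

test_that("generators are reproducible bit-for-bit per seed", {
  spec <- two_state_spec(n_pores = 2, duration_ns = 50)
  t1 <- simulate_state_traces(spec, seed = 11)
  t2 <- simulate_state_traces(spec, seed = 11)
  expect_identical(t1, t2)
  t3 <- simulate_state_traces(spec, seed = 12)
  expect_false(identical(t1[[1]]$gate$states, t3[[1]]$gate$states))

  sch <- interval_scheme(analysis_start = 1000, analysis_end = 1050)
  d1 <- simulate_flux_counts(t1, sch, spec, seed = 1)
  d2 <- simulate_flux_counts(t2, sch, spec, seed = 1)
  expect_identical(d1$flux_count, d2$flux_count)

  toy1 <- simulate_toy_trajectory(spec, seed = 5)
  toy2 <- simulate_toy_trajectory(spec, seed = 5)
  expect_identical(toy1$trajectory$coords, toy2$trajectory$coords)
})

test_that("stationary occupancies and degenerate chains behave", {
  # single-state chain is constant
  spec1 <- synthetic_spec(n_pores = 1, duration_ns = 20,
                          residues = list(g = list(
                            states = "only", reference = "only",
                            stationary = 1, base_dwell_ns = 10)),
                          truth = list(alpha = log(4.6),
                                       beta = numeric(0),
                                       sigma_u = 0.1, phi = 10))
  tr <- simulate_state_traces(spec1, seed = 1)[[1]]$g
  expect_equal(length(unique(tr$states)), 1L)

  # extremely uneven dwells give a near-constant majority state
  spec2 <- synthetic_spec(n_pores = 1, duration_ns = 500,
                          residues = list(g = list(
                            states = c("a", "b"), reference = "a",
                            stationary = c(0.995, 0.005),
                            base_dwell_ns = 50)))
  tr2 <- simulate_state_traces(spec2, seed = 2)[[1]]$g
  expect_gt(mean(tr2$states == "a"), 0.95)

  expect_error(synthetic_spec(residues = list(g = list(
    states = c("a", "b"), reference = "a", stationary = c(0.7, 0.7),
    base_dwell_ns = 1))), "sum to 1")
})

test_that("flux counts follow the planted linear model", {
  # Poisson-intercept limit: no effects, no group spread, huge shape
  spec <- synthetic_spec(
    n_pores = 4, duration_ns = 300,
    residues = list(g = list(states = c("a", "b"), reference = "a",
                             stationary = c(0.5, 0.5),
                             base_dwell_ns = 10)),
    truth = list(alpha = log(4.6), beta = c(g.b = 0), sigma_u = 0,
                 phi = 1e6))
  traces <- simulate_state_traces(spec, seed = 3)
  sch <- interval_scheme(analysis_start = 1000, analysis_end = 1300)
  ds <- simulate_flux_counts(traces, sch, spec, seed = 3)
  se <- stats::sd(ds$flux_count) / sqrt(nrow(ds))
  expect_lt(abs(mean(ds$flux_count) - 4.6), 3 * se)

  # windows fully in the blocking state average near its planted rate
  spec_b <- two_state_spec(n_pores = 6, duration_ns = 500, sigma_u = 0,
                           phi = 50)
  tr_b <- simulate_state_traces(spec_b, seed = 8)
  sch_b <- interval_scheme(analysis_start = 1000, analysis_end = 1500)
  ds_b <- simulate_flux_counts(tr_b, sch_b, spec_b, seed = 8)
  blocked <- ds_b$flux_count[ds_b$gate.blocked > 0.99]
  expect_gt(length(blocked), 30)
  se_b <- stats::sd(blocked) / sqrt(length(blocked))
  expect_lt(abs(mean(blocked) - 1.0), 3 * se_b)

  # doubling the group spread inflates between-pore variance
  v_of <- function(su, seed) {
    sp <- two_state_spec(n_pores = 12, duration_ns = 200, sigma_u = su)
    tr <- simulate_state_traces(sp, seed = seed)
    d <- simulate_flux_counts(tr,
                              interval_scheme(analysis_start = 1000,
                                              analysis_end = 1200),
                              sp, seed = seed)
    stats::var(tapply(d$flux_count, d$pore_id, mean))
  }
  expect_gt(mean(vapply(1:3, function(s) v_of(0.4, s), 0)),
            mean(vapply(1:3, function(s) v_of(0.1, s), 0)))

  # truth naming a predictor absent from the traces is an error
  bad <- two_state_spec(n_pores = 1, duration_ns = 50)
  bad$truth$beta <- c(other.state = 1)
  tr1 <- simulate_state_traces(bad, seed = 1)
  expect_error(simulate_flux_counts(
    tr1, interval_scheme(analysis_start = 1000, analysis_end = 1050),
    bad, seed = 1), "absent from traces")
})

test_that("the truth report is plain algebra on the log scale", {
  spec <- two_state_spec()
  rep <- truth_report(spec)
  expect_equal(rep$expected[rep$state == "open"], 4.6, tolerance = 1e-12)
  expect_equal(rep$expected[rep$state == "blocked"], 1.0,
               tolerance = 1e-12)
  expect_true(all(rep$expected > 0))
  full <- truth_report(synthetic_spec())
  expect_equal(full$expected[full$residue == "w48" &
                               full$state == "open"], 4.6)
  expect_equal(nrow(full), sum(lengths(lapply(
    synthetic_spec()$residues, `[[`, "states"))))
})

test_that("the NB generator approaches Poisson as the shape diverges", {
  set.seed(14)
  y <- stats::rnbinom(20000, size = 1e6, mu = 4.6)
  m <- mean(y)
  v <- stats::var(y)
  # SE of a variance estimate under near-Poisson sampling
  se_v <- v * sqrt(2 / (length(y) - 1))
  expect_lt(abs(v - m), 3 * se_v)
})
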