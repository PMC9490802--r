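# The Bayesian negative-binomial multilevel model: log posterior,
# sampler, diagnostics, predictions and relative permeabilities.

test_that("the analytic gradient matches finite differences", {
  set.seed(3)
  n <- 150; k <- 2; J <- 3
  X <- matrix(stats::runif(n * k), n, k,
              dimnames = list(NULL, c("x1", "x2")))
  gi <- sample.int(J, n, TRUE)
  y <- stats::rnbinom(n, size = 8,
                      mu = exp(1.2 + X %*% c(0.5, -1) +
                                 0.3 * stats::rnorm(J)[gi]))
  pr <- list(alpha_df = 3, alpha_scale = 2.5, beta_sd = 2.5,
             sigma_u_df = 3, sigma_u_scale = 2.5,
             alpha_loc = log(mean(y)))
  env <- list(y = y, X = X, k = k, J = J, gi = gi, prior = pr)
  th <- c(1.1, 0.4, -0.8, 0.1, -0.2, 0.15, log(0.25), log(6))
  ga <- aquaflux:::nb_mlm_grad(th, env)
  gn <- vapply(seq_along(th), function(i) {
    e <- replace(rep(0, length(th)), i, 1e-6)
    (aquaflux:::nb_mlm_logpost(th + e, env) -
       aquaflux:::nb_mlm_logpost(th - e, env)) / 2e-6
  }, 0)
  expect_equal(unname(ga), gn, tolerance = 1e-5)
})

test_that("small-scale fits agree with an independent ML fit", {
  spec <- two_state_spec(n_pores = 8, duration_ns = 400)
  traces <- simulate_state_traces(spec, seed = 4)
  sch <- interval_scheme(analysis_start = 1000, analysis_end = 1400)
  ds <- simulate_flux_counts(traces, sch, spec, seed = 4)
  fit <- state_flux_model(data = ds, seed = 2)

  skip_if_not_installed("glmmTMB")
  gm <- glmmTMB::glmmTMB(flux_count ~ gate.blocked + (1 | pore_id),
                         data = ds, family = glmmTMB::nbinom2)
  fe <- glmmTMB::fixef(gm)$cond
  expect_lt(abs(coef(fit)[["alpha"]] - fe[["(Intercept)"]]), 0.1)
  expect_lt(abs(coef(fit)[["b_gate.blocked"]] - fe[["gate.blocked"]]),
            0.1)
  expect_lt(abs(mean(fit$draws[, "phi"]) - glmmTMB::sigma(gm)),
            0.25 * glmmTMB::sigma(gm))
})

test_that("an explicit formula and the dataset default agree", {
  spec <- two_state_spec(n_pores = 4, duration_ns = 120)
  traces <- simulate_state_traces(spec, seed = 5)
  sch <- interval_scheme(analysis_start = 1000, analysis_end = 1120)
  ds <- simulate_flux_counts(traces, sch, spec, seed = 5)
  f1 <- state_flux_model(data = ds, seed = 3, iter = 600, warmup = 300)
  f2 <- state_flux_model(flux_count ~ gate.blocked + (1 | pore_id),
                         data = ds, seed = 3, iter = 600, warmup = 300)
  expect_equal(f1$draws, f2$draws)
  expect_error(state_flux_model(flux_count ~ x + (1 | nope), ds),
               "grouping variable")
  expect_error(state_flux_model(data = data.frame(
    flux_count = rep(0, 10))), "predictor metadata")
})

test_that("degenerate all-zero data are rejected with a diagnostic", {
  d <- data.frame(flux_count = rep(0L, 50), x = stats::runif(50))
  expect_error(state_flux_model(flux_count ~ x, d), "degenerate")
})

test_that("convergence diagnostics flag constructed pathologies", {
  set.seed(10)
  good <- lapply(1:2, function(i)
    matrix(stats::rnorm(2000), ncol = 2,
           dimnames = list(NULL, c("a", "b"))))
  dg <- aquaflux:::mcmc_diagnostics(good)
  expect_true(all(dg$rhat < 1.01))
  expect_true(all(dg$ess > 400))
  expect_true(check_convergence(dg)$pass)

  # chains with disjoint means cannot have mixed
  apart <- list(good[[1]], good[[2]] + 10)
  da <- aquaflux:::mcmc_diagnostics(apart)
  expect_true(all(da$rhat > 1.5))
  expect_false(check_convergence(da)$pass)

  # a constant chain carries no information
  flat <- lapply(1:2, function(i)
    matrix(1, 500, 1, dimnames = list(NULL, "a")))
  df <- aquaflux:::mcmc_diagnostics(flat)
  expect_lt(df$ess, 400)
  expect_false(check_convergence(df)$pass)
})

test_that("per-state predictions honour the encoding identities", {
  spec <- two_state_spec(n_pores = 4, duration_ns = 120)
  traces <- simulate_state_traces(spec, seed = 6)
  sch <- interval_scheme(analysis_start = 1000, analysis_end = 1120)
  ds <- simulate_flux_counts(traces, sch, spec, seed = 6)
  fit <- state_flux_model(data = ds, seed = 4, iter = 600, warmup = 300)

  # zeroed effects collapse every state to exp(alpha)
  null_fit <- fit
  null_fit$draws[, "b_gate.blocked"] <- 0
  p0 <- predict_state_flux(null_fit)
  expect_equal(p0$mean[1], p0$mean[2], tolerance = 1e-12)
  expect_equal(p0$mean[1], mean(exp(fit$draws[, "alpha"])))

  # the reference state equals a prediction with the residue's own
  # predictors zeroed
  p_ref <- predict_state_flux(fit, "gate", "open")
  x0 <- as.data.frame(as.list(replace(fit$covariate_means,
                                      "gate.blocked", 0)),
                      check.names = FALSE)
  p_zero <- predict(fit, x0)
  expect_equal(p_ref$mean, p_zero$mean)
  expect_equal(p_ref$lo95, p_zero$lo95, ignore_attr = TRUE)

  expect_error(predict_state_flux(fit, "nope"), "unknown residue")
  expect_error(predict_state_flux(fit, "gate", "nope"), "unknown state")
  expect_true(all(p_ref$lo95 <= p_ref$mean & p_ref$mean <= p_ref$hi95))
})

test_that("posterior-predictive simulation and residuals are coherent", {
  spec <- two_state_spec(n_pores = 4, duration_ns = 120)
  traces <- simulate_state_traces(spec, seed = 7)
  sch <- interval_scheme(analysis_start = 1000, analysis_end = 1120)
  ds <- simulate_flux_counts(traces, sch, spec, seed = 7)
  fit <- state_flux_model(data = ds, seed = 5, iter = 600, warmup = 300)

  # posterior-predictive mean on training covariates tracks the data
  mu <- posterior_mean_mu(fit, ds)
  expect_lt(abs(mean(mu) - mean(ds$flux_count)),
            3 * stats::sd(ds$flux_count) / sqrt(nrow(ds)))
  sims <- simulate(fit, nsim = 200, seed = 1,
                   newdata = ds[1:20, , drop = FALSE])
  expect_equal(dim(sims), c(20, 200))
  expect_lt(abs(mean(sims) - mean(mu[1:20])), 1.5)

  r <- residuals(fit, ds)
  expect_equal(length(r), nrow(ds))
  expect_lt(abs(mean(r)), 0.2)           # roughly centred
  expect_error(residuals(fit), "supply the dataset")
})

test_that("relative permeabilities are ratios with propagated SEM", {
  wt <- lapply(1:4, function(i)
    flux_series(make_events(seq(1000.5, 2999.5, length.out = 2000)),
                paste0("wt.", i)))
  mut <- lapply(1:4, function(i)
    flux_series(make_events(seq(1000.5, 2999.5, length.out = 2740)),
                paste0("V29E.", i)))
  slow <- lapply(1:4, function(i)
    flux_series(make_events(seq(1000.5, 2999.5, length.out = 1280)),
                paste0("V29K.", i)))
  out <- relative_flux(c(wt, mut, slow))
  expect_equal(out$mean_per_window[out$variant == "wt"], 100)
  expect_equal(out$ratio_to_ref[out$variant == "wt"], 1)
  expect_equal(out$ratio_to_ref[out$variant == "V29E"], 1.37)
  expect_equal(out$ratio_to_ref[out$variant == "V29K"], 0.64)
  # two identical variants: ratio 1 and interval containing 1
  out2 <- relative_flux(c(wt, wt), variants = rep(c("wt", "same"),
                                                  each = 4))
  r <- out2[out2$variant == "same", ]
  expect_equal(r$ratio_to_ref, 1)
  expect_true(r$ratio_to_ref - 2 * r$ratio_sem <= 1 &&
                1 <= r$ratio_to_ref + 2 * r$ratio_sem)
  expect_error(relative_flux(mut), "absent")
})
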