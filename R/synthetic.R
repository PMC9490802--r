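## Synthetic-data generators: gating-state traces (continuous-time Markov
## chains), negative-binomial flux counts with known ground truth, and
## toy 3-D water trajectories with planted permeation events. These stand
## in for undeposited multi-microsecond simulations and make every stage
## of the pipeline testable at desk scale against known truth.

#' Specify a synthetic study
#'
#' Defaults emulate the published study layout: 24 pores (3 variants x 2
#' replicas x 4 chains), 2000 ns of analysed time per pore at a 10 ps
#' frame period, the nine-residue gating registry with stationary
#' occupancies in the wild-type-like regime, and ground-truth flux-model
#' parameters on the published per-state flux scale (open about 4.6
#' waters per 5 ns, strongly blocked states near 1).
#'
#' @param n_pores number of pores.
#' @param duration_ns analysed duration per pore.
#' @param start_ns time of the first frame (default 1000: the analysis
#'   window after discarding equilibration).
#' @param frame_period_ps frame period.
#' @param residues named list; each element has `states` (labels),
#'   `reference` (one label), `stationary` (target occupancies, summing
#'   to 1) and `base_dwell_ns` (mean state dwell). Default: the built-in
#'   registry, see Details.
#' @param truth list with `alpha` (log baseline count per flux window),
#'   `beta` (named vector over non-reference predictor columns),
#'   `sigma_u` (between-pore SD on the log scale) and `phi` (NB shape).
#' @param toy list of toy-trajectory settings: `n_crossers`,
#'   `n_half_crossers`, `n_radial_escapees`, `n_decoys`, `duration_ns`,
#'   `transit_ns`, `r_single_file`, `r_escape`.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pores = 24, duration_ns = 2000,
                           start_ns = 1000, frame_period_ps = 10,
                           residues = NULL, truth = NULL, toy = list()) {
  if (is.null(residues)) residues <- default_synthetic_residues()
  for (nm in names(residues)) {
    r <- residues[[nm]]
    if (abs(sum(r$stationary) - 1) > 1e-8)
      stop("stationary occupancies of '", nm, "' must sum to 1")
    if (any(r$stationary <= 0))
      stop("stationary occupancies of '", nm, "' must be positive")
    if (!r$reference %in% r$states)
      stop("reference state of '", nm, "' not among its states")
  }
  if (is.null(truth)) truth <- default_synthetic_truth(residues)
  toy <- utils::modifyList(list(n_crossers = 10, n_half_crossers = 5,
                                n_radial_escapees = 3, n_decoys = 5,
                                duration_ns = 20, transit_ns = 2,
                                r_single_file = 0.15, r_escape = 0.9),
                           toy)
  structure(list(n_pores = n_pores, duration_ns = duration_ns,
                 start_ns = start_ns, frame_period_ps = frame_period_ps,
                 residues = residues, truth = truth, toy = toy),
            class = "synthetic_spec")
}

## Stationary occupancies chosen in the wild-type-like regime of the
## study (mostly-open pore; blocked states are minority phases), mean
## dwells on the 10 ns scale of temporary flipping events.
default_synthetic_residues <- function() {
  reg <- gating_registry()
  occ <- list(
    w48 = c(blocked = 0.04, restricted = 0.10, open = 0.86),
    f200 = c(near = 0.33, far = 0.67),
    a201 = c(blocking = 0.09, open = 0.91),
    r206 = c(a0_50 = 0.05, a50_115 = 0.07, a115_160 = 0.05,
             a160_210 = 0.126, a210_240 = 0.06, a240_290 = 0.06,
             a290_360 = 0.584),
    m202 = c(in_pore = 0.20, out = 0.80),
    n203 = c(in_pore = 0.07, out = 0.93),
    n68 = c(in_pore = 0.02, out = 0.98),
    h66 = c(in_pore = 0.02, out = 0.98),
    v173 = c(in_pore = 0.05, out = 0.95))
  out <- list()
  for (nm in names(reg)) {
    out[[nm]] <- list(states = reg[[nm]]$labels,
                      reference = reg[[nm]]$reference,
                      stationary = unname(occ[[nm]][reg[[nm]]$labels]),
                      base_dwell_ns = 10)
  }
  out
}

## Ground-truth effects on the published per-state flux scale: beta of a
## non-reference state is the log ratio of its per-window flux to the
## open-state baseline.
default_synthetic_truth <- function(residues) {
  per_state <- list(
    w48 = c(blocked = 1.0, restricted = 3.0, open = 4.6),
    f200 = c(near = 4.3, far = 4.2),
    a201 = c(blocking = 0.4, open = 4.8),
    r206 = c(a0_50 = 7.8, a50_115 = 4.0, a115_160 = 4.8, a160_210 = 1.3,
             a210_240 = 3.2, a240_290 = 2.9, a290_360 = 6.4),
    m202 = c(in_pore = 1.1, out = 5.2),
    n203 = c(in_pore = 1.7, out = 4.3),
    n68 = c(in_pore = 0.6, out = 4.3),
    h66 = c(in_pore = 1.5, out = 4.2),
    v173 = c(in_pore = 2.5, out = 4.3))
  beta <- numeric(0)
  for (nm in names(residues)) {
    r <- residues[[nm]]
    fl <- if (nm %in% names(per_state)) per_state[[nm]] else
      stats::setNames(rep(4.6, length(r$states)), r$states)
    b <- log(fl[setdiff(r$states, r$reference)] / fl[[r$reference]])
    names(b) <- paste0(nm, ".", setdiff(r$states, r$reference))
    beta <- c(beta, b)
  }
  list(alpha = log(4.6), beta = beta, sigma_u = 0.2, phi = 10)
}

## Minimal registry-shaped view of the synthetic residues, sufficient for
## interval_predictors()/residue_map_of().
synthetic_registry <- function(spec) {
  out <- lapply(names(spec$residues), function(nm) {
    r <- spec$residues[[nm]]
    list(id = nm, labels = r$states, reference = r$reference)
  })
  names(out) <- names(spec$residues)
  out
}

#' Simulate gating-state traces
#'
#' Each residue of each pore follows an independent continuous-time
#' Markov chain with exponential dwell times (mean `base_dwell_ns` scaled
#' per state so the embedded uniform jump chain attains the requested
#' stationary occupancies), sampled on the frame grid. Residues are
#' simulated independently; correlations between residues present in
#' real simulations are deliberately out of generator scope.
#'
#' @param spec a [synthetic_spec].
#' @param seed integer seed; traces are reproducible bit-for-bit per
#'   `(seed, spec)`.
#' @return list over pores (named `pore1`, ...), each a named list of
#'   [state_trace] objects per residue.
#' @export
simulate_state_traces <- function(spec, seed = 1) {
  set.seed(seed)
  nfr <- round(spec$duration_ns * 1000 / spec$frame_period_ps)
  tgrid <- (seq_len(nfr) - 1L) * spec$frame_period_ps / 1000
  out <- vector("list", spec$n_pores)
  for (p in seq_len(spec$n_pores)) {
    pore <- list()
    for (nm in names(spec$residues)) {
      r <- spec$residues[[nm]]
      pore[[nm]] <- state_trace(
        sim_ctmc(r, spec$duration_ns, tgrid),
        time_start_ns = spec$start_ns,
        frame_period_ps = spec$frame_period_ps,
        definition_id = nm, pore_id = paste0("pore", p),
        levels = r$states)
    }
    out[[p]] <- pore
  }
  names(out) <- paste0("pore", seq_len(spec$n_pores))
  out
}

## One CTMC realisation sampled on the frame grid. With a uniform
## embedded jump matrix the embedded stationary law is uniform, so the
## time-stationary occupancy of state s is proportional to its mean
## dwell; dwell_s = k * base_dwell * pi_s yields occupancy pi_s.
sim_ctmc <- function(r, duration_ns, tgrid) {
  k <- length(r$states)
  dwell <- k * r$base_dwell_ns * r$stationary
  if (k == 1L) return(factor(rep(r$states, length(tgrid)),
                             levels = r$states))
  jumps <- numeric(0)
  states <- integer(0)
  s <- sample.int(k, 1L, prob = r$stationary)
  t <- 0
  while (t < duration_ns) {
    jumps <- c(jumps, t)
    states <- c(states, s)
    t <- t + stats::rexp(1L, rate = 1 / dwell[s])
    s <- if (k == 2L) 3L - s else
      sample((1:k)[-s], 1L)
  }
  idx <- findInterval(tgrid, jumps)
  factor(r$states[states[idx]], levels = r$states)
}

#' Simulate flux counts from known truth
#'
#' Inverts the statistical model: per pore a group deviation
#' `u_j ~ Normal(0, sigma_u)` is drawn; per paired window the phase
#' fractions of the property window give
#' `mu = exp(alpha + beta.x + u_j)` and the flux count is drawn from the
#' negative binomial with shape `phi`.
#'
#' @param traces output of [simulate_state_traces()].
#' @param scheme an [interval_scheme] covering the traces' time range.
#' @param spec the [synthetic_spec] carrying the truth (or a list with
#'   `alpha`, `beta`, `sigma_u`, `phi` plus `residues`).
#' @param seed integer seed.
#' @param pore_meta optional pore metadata (as in [assemble_dataset()]).
#' @return a `flux_dataset` with attribute `truth` (including the drawn
#'   `u`).
#' @export
simulate_flux_counts <- function(traces, scheme, spec, seed = 1,
                                 pore_meta = NULL) {
  truth <- spec$truth
  reg <- synthetic_registry(spec)
  set.seed(seed + 7L)
  win <- build_windows(scheme)
  if (!nrow(win)) stop("scheme admits no paired window")
  n_pores <- length(traces)
  if (is.null(pore_meta)) pore_meta <- default_pore_meta(n_pores)
  u <- stats::rnorm(n_pores, 0, truth$sigma_u)
  rows <- vector("list", n_pores)
  for (p in seq_len(n_pores)) {
    pred <- interval_predictors(traces[[p]], win, reg,
                                drop_reference = TRUE)
    miss <- setdiff(names(truth$beta), colnames(pred))
    if (length(miss))
      stop("truth names predictor(s) absent from traces: ",
           paste(miss, collapse = ", "))
    eta <- truth$alpha +
      drop(pred[, names(truth$beta), drop = FALSE] %*% truth$beta) + u[p]
    y <- stats::rnbinom(nrow(win), size = truth$phi, mu = exp(eta))
    rows[[p]] <- data.frame(pore_meta[p, , drop = FALSE],
                            interval = seq_len(nrow(win)),
                            t_start_ns = win$t_start, pred,
                            flux_count = y, row.names = NULL,
                            check.names = FALSE)
  }
  ds <- do.call(rbind, rows)
  meta_cols <- c(names(pore_meta), "interval", "t_start_ns", "flux_count")
  attr(ds, "predictors") <- setdiff(names(ds), meta_cols)
  attr(ds, "residue_map") <- residue_map_of(reg)
  attr(ds, "scheme") <- scheme
  attr(ds, "truth") <- c(truth, list(u = u))
  class(ds) <- c("flux_dataset", "data.frame")
  ds
}

default_pore_meta <- function(n_pores) {
  variants <- c("wt", "V29E", "V29K")
  data.frame(
    pore_id = paste0("pore", seq_len(n_pores)),
    variant = variants[((seq_len(n_pores) - 1L) %/% 8L) %% 3L + 1L],
    replica = ((seq_len(n_pores) - 1L) %/% 4L) %% 2L + 1L,
    chain = LETTERS[(seq_len(n_pores) - 1L) %% 4L + 1L])
}

#' Analytic per-state flux expectations of a synthetic truth
#'
#' @param spec a [synthetic_spec].
#' @return data.frame `residue`, `state`, `expected` (waters per flux
#'   window, `exp(alpha + beta)`, `exp(alpha)` for reference states).
#' @export
truth_report <- function(spec) {
  truth <- spec$truth
  rows <- list()
  for (nm in names(spec$residues)) {
    r <- spec$residues[[nm]]
    for (s in r$states) {
      b <- if (s == r$reference) 0 else
        truth$beta[[paste0(nm, ".", s)]]
      rows[[paste(nm, s)]] <- data.frame(
        residue = nm, state = s, expected = exp(truth$alpha + b))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a toy water trajectory with planted permeation events
#'
#' Builds single-atom "waters" moving through the default counting
#' cylinder: `n_crossers` complete axial cap-to-cap crossings at small
#' radius (alternating directions), `n_half_crossers` that enter and
#' retreat, `n_radial_escapees` that traverse the slab at a radius
#' outside the single-file containment limit but inside the cylinder
#' (detected raw, removed by the containment filter), and `n_decoys`
#' wandering in bulk outside the cylinder. This is a counting test
#' fixture with exact ground truth, not a physical water model.
#'
#' @param spec a [synthetic_spec] (its `toy` block is used).
#' @param seed integer seed.
#' @return list with `trajectory` (a [trajectory]), `truth` (data.frame
#'   `water_id`, `direction`, `t_enter_ns`, `t_exit_ns` of the planted
#'   complete crossings) and `cylinder` (the [cylinder_spec]).
#' @export
simulate_toy_trajectory <- function(spec, seed = 1) {
  toy <- spec$toy
  set.seed(seed + 13L)
  cyl <- cylinder_spec()
  half <- cyl$length / 2
  dt <- spec$frame_period_ps / 1000
  nfr <- round(toy$duration_ns / dt) + 1L
  tgrid <- (seq_len(nfr) - 1L) * dt
  zpark <- half + 0.3
  n_tot <- toy$n_crossers + toy$n_half_crossers +
    toy$n_radial_escapees + toy$n_decoys
  coords <- array(NA_real_, c(nfr, n_tot, 3L))
  truth <- list()
  w <- 0L

  ramp_z <- function(dir, t0, t1, zfrom, zto) {
    z <- rep(zfrom, nfr)
    on <- tgrid >= t0 & tgrid <= t1
    z[on] <- zfrom + (zto - zfrom) * (tgrid[on] - t0) / (t1 - t0)
    z[tgrid > t1] <- zto
    z + stats::rnorm(nfr, 0, 0.02)
  }
  put_water <- function(z, radius) {
    ang <- stats::runif(1L, 0, 2 * pi) +
      cumsum(stats::rnorm(nfr, 0, 0.05))
    r <- pmax(0, radius + stats::rnorm(nfr, 0, 0.02))
    cbind(r * cos(ang), r * sin(ang), z)
  }

  for (i in seq_len(toy$n_crossers)) {
    w <- w + 1L
    dir <- if (i %% 2L) 1L else -1L
    t0 <- stats::runif(1L, 0.5, toy$duration_ns - toy$transit_ns - 0.5)
    z <- ramp_z(dir, t0, t0 + toy$transit_ns, -dir * zpark, dir * zpark)
    coords[, w, ] <- put_water(z, toy$r_single_file)
    truth[[w]] <- data.frame(water_id = w, direction = dir,
                             t_enter_ns = t0, t_exit_ns = t0 +
                               toy$transit_ns)
  }
  for (i in seq_len(toy$n_half_crossers)) {
    w <- w + 1L
    t0 <- stats::runif(1L, 0.5, toy$duration_ns / 2)
    zin <- ramp_z(1L, t0, t0 + toy$transit_ns / 2, -zpark, 0)
    zout <- ramp_z(1L, t0 + toy$transit_ns, t0 + 1.5 * toy$transit_ns,
                   0, -zpark)
    z <- ifelse(tgrid < t0 + toy$transit_ns, zin, zout)
    coords[, w, ] <- put_water(z, toy$r_single_file)
  }
  for (i in seq_len(toy$n_radial_escapees)) {
    w <- w + 1L
    dir <- if (i %% 2L) -1L else 1L
    t0 <- stats::runif(1L, 0.5, toy$duration_ns - toy$transit_ns - 0.5)
    z <- ramp_z(dir, t0, t0 + toy$transit_ns, -dir * zpark, dir * zpark)
    coords[, w, ] <- put_water(z, toy$r_escape)
  }
  for (i in seq_len(toy$n_decoys)) {
    w <- w + 1L
    z <- cumsum(stats::rnorm(nfr, 0, 0.05))
    coords[, w, ] <- put_water(z, cyl$radius + 1.5)
  }
  traj <- trajectory(coords, seq_len(n_tot),
                     frame_period_ps = spec$frame_period_ps)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(water_id = integer(), direction = integer(),
               t_enter_ns = numeric(), t_exit_ns = numeric())
  list(trajectory = traj, truth = truth, cylinder = cyl)
}
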