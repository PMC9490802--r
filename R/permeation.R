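## Counting complete water permeation events through a per-protomer
## cylinder, the containment filter for spuriously assigned waters, and
## windowed flux counts.

#' Specify the counting cylinder
#'
#' The counting volume is a cylinder along the membrane normal (z). The
#' convention throughout is that the periplasm sits at negative z, so
#' direction +1 means a below-to-above (periplasm to cytoplasm) crossing.
#'
#' @param length cylinder length in nm (default 2.2).
#' @param radius cylinder radius in nm (default 1.5).
#' @param center fixed cylinder center (nm) when `center_mode = "fixed"`.
#' @param center_mode `"fixed"`, or `"chain_com"` to re-center every frame
#'   at the center of mass of a protein chain (requires `chain` and a
#'   topology when assigning compartments; frames are assumed already
#'   superposed onto the reference).
#' @param chain chain id used by `"chain_com"`.
#' @return object of class `cylinder_spec`.
#' @export
cylinder_spec <- function(length = 2.2, radius = 1.5, center = c(0, 0, 0),
                          center_mode = c("fixed", "chain_com"),
                          chain = NULL) {
  if (length <= 0 || radius <= 0)
    stop("cylinder length and radius must be positive")
  structure(list(length = length, radius = radius, center = center,
                 center_mode = match.arg(center_mode), chain = chain),
            class = "cylinder_spec")
}

#' Assign waters to cylinder compartments
#'
#' Labels every water in every frame as `below` / `above` (outside the
#' axial slab on the respective side), `inside` (within the slab and
#' radially within the cylinder) or `outside_radius` (within the slab but
#' radially beyond the cylinder).
#'
#' @param traj a [trajectory] (already superposed onto the reference when
#'   `center_mode = "chain_com"` is used).
#' @param cylinder a [cylinder_spec].
#' @param topology optional [structure_model] used to identify water
#'   oxygens and chain atoms; when `NULL` every trajectory atom is treated
#'   as a water oxygen (toy-trajectory mode).
#' @param water_residues residue names recognised as water.
#' @return object of class `compartment_traces`: per-water, per-frame
#'   labels plus the radial and axial offsets used.
#' @export
assign_compartments <- function(traj, cylinder, topology = NULL,
                                water_residues = c("SOL", "HOH", "WAT",
                                                   "TIP3")) {
  if (is.null(topology)) {
    water_ids <- traj$atom_id
  } else {
    a <- topology$atoms
    water_ids <- a$atom_id[a$residue_name %in% water_residues &
                             a$element == "O"]
    water_ids <- intersect(water_ids, traj$atom_id)
  }
  if (!length(water_ids)) stop("no water oxygens found in trajectory")
  widx <- match(water_ids, traj$atom_id)
  nf <- n_frames(traj)
  if (cylinder$center_mode == "chain_com") {
    if (is.null(topology) || is.null(cylinder$chain))
      stop("center_mode 'chain_com' requires a topology and a chain id")
    cids <- atom_ids_of(topology, chain_id = cylinder$chain)
    cidx <- match(intersect(cids, traj$atom_id), traj$atom_id)
    if (!length(cidx)) stop("chain '", cylinder$chain, "' not in trajectory")
    cx <- rowMeans(traj$coords[, cidx, 1L, drop = FALSE])
    cy <- rowMeans(traj$coords[, cidx, 2L, drop = FALSE])
    cz <- rowMeans(traj$coords[, cidx, 3L, drop = FALSE])
  } else {
    cx <- rep(cylinder$center[1L], nf)
    cy <- rep(cylinder$center[2L], nf)
    cz <- rep(cylinder$center[3L], nf)
  }
  dx <- traj$coords[, widx, 1L, drop = FALSE][, , 1L] - cx
  dy <- traj$coords[, widx, 2L, drop = FALSE][, , 1L] - cy
  dz <- traj$coords[, widx, 3L, drop = FALSE][, , 1L] - cz
  dim(dx) <- dim(dy) <- dim(dz) <- c(nf, length(widx))
  r <- sqrt(dx^2 + dy^2)
  half <- cylinder$length / 2
  lab <- matrix(2L, nf, length(widx))        # 2 = inside
  lab[dz < -half] <- 1L                      # 1 = below
  lab[dz > half] <- 3L                       # 3 = above
  lab[lab == 2L & r > cylinder$radius] <- 4L # 4 = outside_radius
  structure(list(labels = lab, r = r, z = dz,
                 time_ns = frame_times(traj), water_ids = water_ids,
                 cylinder = cylinder),
            class = "compartment_traces")
}

compartment_levels <- c("below", "inside", "above", "outside_radius")

#' Detect complete permeation events
#'
#' Runs a per-water state machine over the compartment labels. An event is
#' a cap-to-cap traversal: the water visits one axial cap, then one or
#' more `inside` frames, then the opposite cap, with no `outside_radius`
#' frame in between. Touching `outside_radius` voids the ongoing attempt
#' (the machine resets to the last cap visited); revisiting the entry cap
#' restarts the transit clock. Entry time is the first `inside` frame of
#' the successful attempt, exit time the first opposite-cap frame.
#'
#' @param comp a [assign_compartments] result, or a plain label matrix
#'   (frames x waters) of integers 1-4 or of the strings
#'   `below/inside/above/outside_radius` (then `frame_period_ps` supplies
#'   the time base).
#' @param frame_period_ps frame period when `comp` is a bare matrix.
#' @return data.frame of class `permeation_events` with columns
#'   `water_id`, `direction` (+1 below-to-above), `entry_ns`, `exit_ns`,
#'   `transit_ns`, `entry_frame`, `exit_frame`, `max_radial_nm`, sorted by
#'   `exit_ns`. Empty input yields an empty table.
#' @export
detect_permeation_events <- function(comp, frame_period_ps = 10) {
  if (inherits(comp, "compartment_traces")) {
    lab <- comp$labels
    time_ns <- comp$time_ns
    r <- comp$r
    ids <- comp$water_ids
  } else {
    lab <- as.matrix(comp)
    if (is.character(lab))
      lab <- matrix(match(lab, compartment_levels), nrow(lab), ncol(lab))
    time_ns <- (seq_len(nrow(lab)) - 1L) * frame_period_ps / 1000
    r <- NULL
    ids <- seq_len(ncol(lab))
  }
  out <- vector("list", ncol(lab))
  for (w in seq_len(ncol(lab))) {
    lw <- lab[, w]
    last_cap <- 0L       # 0 none, 1 below, 3 above
    entry <- NA_integer_
    ev <- list()
    for (i in seq_along(lw)) {
      s <- lw[i]
      if (s == 2L) {                       # inside
        if (last_cap != 0L && is.na(entry)) entry <- i
      } else if (s == 4L) {                # outside_radius: void attempt
        entry <- NA_integer_
      } else {                             # a cap
        if (!is.na(entry) && last_cap != 0L && s != last_cap) {
          ev[[length(ev) + 1L]] <- c(entry, i, if (s == 3L) 1L else -1L)
        }
        last_cap <- s
        entry <- NA_integer_
      }
    }
    if (length(ev)) {
      m <- do.call(rbind, ev)
      maxr <- if (is.null(r)) NA_real_ else
        vapply(seq_len(nrow(m)),
               function(k) max(r[m[k, 1L]:m[k, 2L], w]), 0)
      out[[w]] <- data.frame(
        water_id = ids[w], direction = m[, 3L],
        entry_ns = time_ns[m[, 1L]], exit_ns = time_ns[m[, 2L]],
        entry_frame = m[, 1L], exit_frame = m[, 2L],
        max_radial_nm = maxr)
    }
  }
  ev <- do.call(rbind, out)
  if (is.null(ev))
    ev <- data.frame(water_id = integer(), direction = integer(),
                     entry_ns = numeric(), exit_ns = numeric(),
                     entry_frame = integer(), exit_frame = integer(),
                     max_radial_nm = numeric())
  ev$transit_ns <- ev$exit_ns - ev$entry_ns
  ev <- ev[order(ev$exit_ns), c("water_id", "direction", "entry_ns",
                                "exit_ns", "transit_ns", "entry_frame",
                                "exit_frame", "max_radial_nm")]
  rownames(ev) <- NULL
  class(ev) <- c("permeation_events", "data.frame")
  ev
}

#' Remove spuriously assigned permeation events
#'
#' The counting cylinder is deliberately generous (1.5 nm radius); waters
#' can slip around the protein while staying inside it and be wrongly
#' counted. This filter removes events whose radial excursion exceeds
#' `r_sf` anywhere in the single-file slab `|z| <= z_sf`, which retains
#' genuinely axial single-file paths only. Removed events are kept in the
#' `"removed"` attribute for reporting.
#'
#' @param events a [detect_permeation_events] table.
#' @param comp the [assign_compartments] result the events came from.
#' @param r_sf radial containment limit in nm (default 0.4).
#' @param z_sf half-width of the single-file slab in nm (default 0.8).
#' @return filtered events with attribute `removed`.
#' @export
filter_spurious_events <- function(events, comp, r_sf = 0.4, z_sf = 0.8) {
  if (r_sf > comp$cylinder$radius)
    stop("containment radius r_sf exceeds the cylinder radius")
  if (!nrow(events)) {
    attr(events, "removed") <- events
    return(events)
  }
  widx <- match(events$water_id, comp$water_ids)
  bad <- vapply(seq_len(nrow(events)), function(k) {
    fr <- events$entry_frame[k]:events$exit_frame[k]
    sl <- abs(comp$z[fr, widx[k]]) <= z_sf
    any(sl) && max(comp$r[fr, widx[k]][sl]) > r_sf
  }, NA)
  kept <- events[!bad, , drop = FALSE]
  attr(kept, "removed") <- events[bad, , drop = FALSE]
  class(kept) <- class(events)
  kept
}

#' Flux series for one pore
#'
#' @param events a [detect_permeation_events] table (will be sorted by
#'   exit time).
#' @param pore_id identifier, conventionally `"variant.replica.chain"`.
#' @return object of class `flux_series`.
#' @export
flux_series <- function(events, pore_id = "pore") {
  events <- events[order(events$exit_ns), , drop = FALSE]
  structure(list(pore_id = pore_id, events = events), class = "flux_series")
}

#' Count permeation events in time windows
#'
#' Each event is timestamped at its exit and assigned to the half-open
#' window `[start, end)` containing that exit, so disjoint windows count
#' each event at most once.
#'
#' @param series a [flux_series] or a [detect_permeation_events] table.
#' @param windows two-column matrix (or list of length-2 vectors) of
#'   window `(start_ns, end_ns)`.
#' @param mode `"total"` (all events) or `"net"` (+1 events minus -1
#'   events).
#' @param allow_overlap set `TRUE` to permit overlapping windows.
#' @return integer vector of counts, one per window.
#' @export
flux_in_windows <- function(series, windows, mode = c("total", "net"),
                            allow_overlap = FALSE) {
  mode <- match.arg(mode)
  ev <- if (inherits(series, "flux_series")) series$events else series
  if (is.list(windows) && !is.matrix(windows))
    windows <- do.call(rbind, windows)
  windows <- matrix(as.numeric(windows), ncol = 2L)
  if (!allow_overlap && nrow(windows) > 1L) {
    o <- order(windows[, 1L])
    if (any(windows[o, 1L][-1L] < windows[o, 2L][-nrow(windows)]))
      stop("overlapping windows; pass allow_overlap = TRUE if intended")
  }
  vapply(seq_len(nrow(windows)), function(k) {
    sel <- ev$exit_ns >= windows[k, 1L] & ev$exit_ns < windows[k, 2L]
    if (mode == "total") sum(sel) else sum(ev$direction[sel])
  }, 0L)
}

#' Transit-time summary of permeation events
#'
#' @param events a [detect_permeation_events] table or [flux_series].
#' @return list with `mean_ns`, `frac_below_1ns`, `frac_below_3ns`.
#' @export
transit_time_stats <- function(events) {
  if (inherits(events, "flux_series")) events <- events$events
  if (!nrow(events))
    stop("transit-time statistics are undefined for zero events")
  tt <- events$transit_ns
  list(mean_ns = mean(tt),
       frac_below_1ns = mean(tt < 1),
       frac_below_3ns = mean(tt < 3))
}

#' Write / read the event table CSV
#'
#' @param events event table (a `pore_id` column is added if absent).
#' @param path file path.
#' @param pore_id pore identifier recorded in the file.
#' @return `path` (write) or the event table (read).
#' @export
write_events_csv <- function(events, path, pore_id = "pore") {
  df <- as.data.frame(events)
  df <- data.frame(pore_id = pore_id,
                   df[c("water_id", "direction", "entry_ns", "exit_ns",
                        "transit_ns", "max_radial_nm")])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
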