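## Secondary structural observables: per-segment C-alpha RMSD, water
## dipole tilt profile along the pore axis, water-residue hydrogen bonds.

#' Per-segment C-alpha RMSD over a trajectory
#'
#' Every frame is superposed onto the reference over `fit_selection`
#' (typically the TM-bundle C-alphas), then the C-alpha RMSD of each named
#' segment is computed; segment values are averaged over frames.
#'
#' @param traj a [trajectory].
#' @param reference a [structure_model].
#' @param segments named list of residue-number vectors (see
#'   [glpf_segments()]).
#' @param fit_selection atom ids used for the fit; default: C-alphas of
#'   the union of all segments.
#' @param chain_id chain evaluated.
#' @return data.frame with `segment`, `mean_rmsd_nm`, `sd_rmsd_nm` (over
#'   frames), `n_frames`.
#' @export
segment_rmsd <- function(traj, reference, segments = glpf_segments(),
                         fit_selection = NULL, chain_id = NULL) {
  ca_ids <- function(resnos) {
    ids <- atom_ids_of(reference, chain_id, resnos, "CA")
    ids[ids %in% traj$atom_id]
  }
  seg_ids <- lapply(segments, ca_ids)
  empty <- !vapply(seg_ids, length, 0L)
  if (any(empty))
    stop("segment(s) unresolvable in trajectory/reference: ",
         paste(names(segments)[empty], collapse = ", "))
  if (is.null(fit_selection))
    fit_selection <- unique(unlist(seg_ids))
  nf <- n_frames(traj)
  acc <- matrix(NA_real_, nf, length(segments),
                dimnames = list(NULL, names(segments)))
  ref_xyz <- lapply(seg_ids, function(ids) coords(reference, ids))
  for (i in seq_len(nf)) {
    sp <- superpose(frame_coords(traj, i), reference, fit_selection)
    fc <- apply_transform(sp, frame_coords(traj, i))
    for (s in seq_along(seg_ids)) {
      m <- fc[match(as.character(seg_ids[[s]]), rownames(fc)), ,
              drop = FALSE]
      acc[i, s] <- sqrt(mean(rowSums((m - ref_xyz[[s]])^2)))
    }
  }
  data.frame(segment = names(segments),
             mean_rmsd_nm = colMeans(acc),
             sd_rmsd_nm = apply(acc, 2L, stats::sd),
             n_frames = nf, row.names = NULL)
}

#' Aggregate per-pore segment RMSDs with SEM
#'
#' @param per_pore list of [segment_rmsd()] tables (one per protomer;
#'   the study design has 8 = 4 chains x 2 replicas).
#' @return data.frame with per-segment mean and SEM across pores.
#' @export
segment_rmsd_sem <- function(per_pore) {
  segs <- per_pore[[1L]]$segment
  m <- vapply(per_pore, function(d) d$mean_rmsd_nm[match(segs, d$segment)],
              numeric(length(segs)))
  m <- matrix(m, nrow = length(segs))
  data.frame(segment = segs,
             mean_rmsd_nm = rowMeans(m),
             sem_rmsd_nm = apply(m, 1L, stats::sd) / sqrt(ncol(m)),
             n_pores = ncol(m), row.names = NULL)
}

#' Water dipole tilt profile along the pore axis
#'
#' For each water (oxygen plus two hydrogens) the dipole direction is the
#' O-to-(H,H midpoint) bisector (charge-weighted when charges are
#' supplied); the tilt is its angle to the +z membrane normal in degrees
#' `[0, 180]`. Values are averaged in z bins of the oxygen position.
#'
#' @param traj a [trajectory] containing the water atoms.
#' @param topology a [structure_model]; waters are residues named in
#'   `water_residues` with one O and two H atoms.
#' @param z_breaks bin edges along z (nm).
#' @param water_residues residue names recognised as water.
#' @param charges optional named numeric (`O`, `H`) partial charges.
#' @return data.frame `z_center_nm`, `mean_tilt_deg`, `sd_tilt_deg`, `n`;
#'   empty bins are reported with `n = 0`.
#' @export
dipole_tilt_profile <- function(traj, topology, z_breaks,
                                water_residues = c("SOL", "HOH", "WAT",
                                                   "TIP3"),
                                charges = NULL) {
  a <- topology$atoms
  wat <- a[a$residue_name %in% water_residues, , drop = FALSE]
  if (!nrow(wat)) stop("no waters found in topology")
  key <- paste(wat$chain_id, wat$residue_number)
  tilt_all <- numeric(0)
  z_all <- numeric(0)
  for (k in unique(key)) {
    w <- wat[key == k, , drop = FALSE]
    oid <- w$atom_id[w$element == "O"]
    hid <- w$atom_id[w$element == "H"]
    if (length(oid) != 1L || length(hid) != 2L) next
    io <- match(oid, traj$atom_id)
    ih <- match(hid, traj$atom_id)
    if (anyNA(c(io, ih))) next
    o <- traj$coords[, io, , drop = TRUE]
    h1 <- traj$coords[, ih[1L], , drop = TRUE]
    h2 <- traj$coords[, ih[2L], , drop = TRUE]
    dim(o) <- dim(h1) <- dim(h2) <- c(n_frames(traj), 3L)
    d <- if (is.null(charges)) (h1 + h2) / 2 - o
         else charges["H"] * (h1 + h2) + charges["O"] * o -
           (charges["O"] + 2 * charges["H"]) * o
    ct <- d[, 3L] / sqrt(rowSums(d^2))
    tilt_all <- c(tilt_all, acos(pmin(1, pmax(-1, ct))) * 180 / pi)
    z_all <- c(z_all, o[, 3L])
  }
  if (!length(tilt_all)) stop("no complete 3-site waters in trajectory")
  bin <- findInterval(z_all, z_breaks, rightmost.closed = FALSE)
  nb <- length(z_breaks) - 1L
  out <- data.frame(z_center_nm = (z_breaks[-1L] + z_breaks[-nb - 1L]) / 2,
                    mean_tilt_deg = NA_real_, sd_tilt_deg = NA_real_,
                    n = 0L)
  for (b in seq_len(nb)) {
    sel <- bin == b
    out$n[b] <- sum(sel)
    if (any(sel)) {
      out$mean_tilt_deg[b] <- mean(tilt_all[sel])
      out$sd_tilt_deg[b] <- stats::sd(tilt_all[sel])
    }
  }
  out
}

#' Water-residue hydrogen-bond counts
#'
#' Counts donor/acceptor pairs between each listed residue's side chain
#' and water satisfying the standard geometric criterion: donor-acceptor
#' distance at most `d_max` and donor-H-acceptor angle at least
#' `180 - angle_max` degrees. Requires hydrogens in the topology (i.e.
#' simulation frames); crystal structures without hydrogens are rejected
#' with a pointer to distance-only analyses.
#'
#' @param traj a [trajectory].
#' @param topology a [structure_model] with hydrogens.
#' @param residues residue numbers to evaluate.
#' @param chain_id chain of the residues.
#' @param d_max donor-acceptor distance cutoff in nm (default 0.35).
#' @param angle_max deviation from linearity in degrees (default 30, i.e.
#'   D-H...A angle at least 150 degrees).
#' @param water_residues residue names recognised as water.
#' @return data.frame `residue_number`, `mean_hbonds`, `sd_hbonds` over
#'   frames, `n_frames`, with the criterion recorded in attributes.
#' @export
water_hbond_counts <- function(traj, topology, residues, chain_id = NULL,
                               d_max = 0.35, angle_max = 30,
                               water_residues = c("SOL", "HOH", "WAT",
                                                  "TIP3")) {
  a <- topology$atoms
  if (!any(a$element == "H"))
    stop("topology has no hydrogens; hydrogen-bond geometry cannot be ",
         "evaluated - use distance-only descriptors instead")
  wat <- a[a$residue_name %in% water_residues, , drop = FALSE]
  nf <- n_frames(traj)
  out <- data.frame(residue_number = residues, mean_hbonds = NA_real_,
                    sd_hbonds = NA_real_, n_frames = nf)
  ai <- function(ids) match(ids, traj$atom_id)
  for (rr in seq_along(residues)) {
    res <- a[a$residue_number == residues[rr] &
               (is.null(chain_id) | a$chain_id %in% chain_id) &
               !(a$atom_name %in% backbone_atoms), , drop = FALSE]
    acc_ids <- res$atom_id[res$element %in% c("N", "O")]
    res_h <- res$atom_id[res$element == "H"]
    counts <- numeric(nf)
    for (i in seq_len(nf)) {
      fc <- frame_coords(traj, i)
      counts[i] <-
        hbond_count_frame(fc, wat, acc_ids, res_h, res, ai, d_max,
                          angle_max)
    }
    out$mean_hbonds[rr] <- mean(counts)
    out$sd_hbonds[rr] <- stats::sd(counts)
  }
  attr(out, "criterion") <- c(d_max_nm = d_max, angle_max_deg = angle_max)
  out
}

hbond_count_frame <- function(fc, wat, acc_ids, res_h, res, ai, d_max,
                              angle_max) {
  pos <- function(id) fc[as.character(id), , drop = FALSE]
  n <- 0L
  wkey <- paste(wat$chain_id, wat$residue_number)
  for (k in unique(wkey)) {
    w <- wat[wkey == k, , drop = FALSE]
    ow <- w$atom_id[w$element == "O"]
    hw <- w$atom_id[w$element == "H"]
    if (length(ow) != 1L) next
    po <- drop(pos(ow))
    # water as donor: O(w)-H(w) ... acceptor(residue N/O)
    for (acc in acc_ids) {
      pa <- drop(pos(acc))
      if (vnorm(pa - po) > d_max) next
      ok <- FALSE
      for (h in hw) {
        ph <- drop(pos(h))
        ang <- angle_deg(po - ph, pa - ph)
        if (ang >= 180 - angle_max) { ok <- TRUE; break }
      }
      if (ok) n <- n + 1L
    }
    # water as acceptor: donor(residue N/O with bonded H) ... O(w)
    for (h in res_h) {
      ph <- drop(pos(h))
      d2 <- res[res$element %in% c("N", "O"), , drop = FALSE]
      if (!nrow(d2)) next
      dmat <- as.matrix(d2[c("x", "y", "z")])
      dd <- sqrt(rowSums(sweep(dmat, 2L, ph)^2))
      j <- which.min(dd)
      if (dd[j] > 0.13) next           # H not bonded to any heavy donor
      pd <- dmat[j, ]
      if (vnorm(pd - po) > d_max) next
      if (angle_deg(pd - ph, po - ph) >= 180 - angle_max) n <- n + 1L
    }
  }
  n
}

angle_deg <- function(u, v) {
  ct <- (u %dot% v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}
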