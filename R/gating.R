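## Residue gating-state descriptors: side-chain torsions and minimal
## side-chain distances, classification into named states, populations.

backbone_atoms <- c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3",
                    "HN", "HA1", "HA2")

#' Side-chain atom ids of a residue
#'
#' Default policy `"heavy"` keeps heavy atoms from C-beta outward
#' (hydrogens and backbone excluded); `"all"` additionally keeps
#' side-chain hydrogens. The crystal structure carries no hydrogens, so
#' thresholds calibrated on it use the heavy policy.
#'
#' @param x a [structure_model].
#' @param residue_number,chain_id residue selector.
#' @param policy `"heavy"` or `"all"`.
#' @return integer atom ids.
#' @export
sidechain_atoms <- function(x, residue_number, chain_id = NULL,
                            policy = c("heavy", "all")) {
  policy <- match.arg(policy)
  a <- x$atoms
  keep <- a$residue_number == residue_number
  if (!is.null(chain_id)) keep <- keep & a$chain_id == chain_id
  a <- a[keep & !(a$atom_name %in% backbone_atoms), , drop = FALSE]
  if (policy == "heavy") a <- a[a$element != "H", , drop = FALSE]
  if (!nrow(a))
    stop("residue ", residue_number,
         " has no side-chain atoms under policy '", policy,
         "' (glycine?)")
  a$atom_id
}

#' Dihedral angle of four atoms in one frame
#'
#' Torsion of the four atom positions in the IUPAC convention (see
#' [torsion()]); the atoms need not be bonded, e.g. the arginine
#' CA-CB-CG-CZ descriptor skips the intermediate side-chain atoms.
#'
#' @param frame n x 3 coordinate matrix with atom-id rownames, a
#'   [structure_model], or a [trajectory] (then a value per frame is
#'   returned).
#' @param atoms four distinct atom ids, in order.
#' @param domain angle domain, `c(-180, 180)` or `c(0, 360)`.
#' @return dihedral(s) in degrees.
#' @export
dihedral_angle <- function(frame, atoms, domain = c(-180, 180)) {
  if (length(unique(atoms)) != 4L) stop("need 4 distinct atom ids")
  if (inherits(frame, "trajectory")) {
    idx <- match(atoms, frame$atom_id)
    if (anyNA(idx)) stop("atom id(s) absent from trajectory")
    return(vapply(seq_len(n_frames(frame)), function(i) {
      m <- frame_coords(frame, i)
      torsion(m[idx[1L], ], m[idx[2L], ], m[idx[3L], ], m[idx[4L], ],
              domain)
    }, 0))
  }
  if (inherits(frame, "structure_model")) frame <- coords(frame)
  idx <- match(as.character(atoms), rownames(frame))
  if (anyNA(idx)) stop("atom id(s) absent from frame")
  torsion(frame[idx[1L], ], frame[idx[2L], ], frame[idx[3L], ],
          frame[idx[4L], ], domain)
}

#' Minimal distance between two residues' side chains
#'
#' Minimum over all pairs of side-chain atoms under the atom policy,
#' using the minimum-image convention when a periodic box is given.
#'
#' @param frame coordinate matrix with atom-id rownames, a
#'   [structure_model], or a [trajectory] (value per frame).
#' @param topology a [structure_model] naming the atoms.
#' @param resA,resB residue numbers.
#' @param chain_id chain the residues live in (default: any).
#' @param policy side-chain atom policy, see [sidechain_atoms()].
#' @param box orthorhombic box lengths (nm) or `NULL`.
#' @return distance(s) in nm.
#' @export
min_sidechain_distance <- function(frame, topology, resA, resB,
                                   chain_id = NULL,
                                   policy = c("heavy", "all"), box = NULL) {
  policy <- match.arg(policy)
  idsA <- sidechain_atoms(topology, resA, chain_id, policy)
  idsB <- sidechain_atoms(topology, resB, chain_id, policy)
  if (inherits(frame, "trajectory")) {
    ia <- match(idsA, frame$atom_id)
    ib <- match(idsB, frame$atom_id)
    if (anyNA(ia) || anyNA(ib))
      stop("side-chain atom(s) absent from trajectory")
    return(vapply(seq_len(n_frames(frame)), function(i) {
      m <- frame_coords(frame, i)
      min_pair_dist(m[ia, , drop = FALSE], m[ib, , drop = FALSE], box)
    }, 0))
  }
  if (inherits(frame, "structure_model")) frame <- coords(frame)
  ia <- match(as.character(idsA), rownames(frame))
  ib <- match(as.character(idsB), rownames(frame))
  if (anyNA(ia) || anyNA(ib)) stop("side-chain atom(s) absent from frame")
  min_pair_dist(frame[ia, , drop = FALSE], frame[ib, , drop = FALSE], box)
}

min_pair_dist <- function(A, B, box = NULL) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    d <- sweep(B, 2L, A[i, ])
    if (!is.null(box)) d <- d - round(sweep(d, 2L, box, "/")) %*% diag(box)
    best <- min(best, min(rowSums(d^2)))
  }
  sqrt(best)
}

#' Define a gating-state descriptor and its partition
#'
#' A state definition names one residue, the geometric metric describing
#' it (a four-atom dihedral or the minimal side-chain distance to a
#' partner residue), and an ordered partition of the metric's domain into
#' half-open `[low, high)` bins with one label each. Exactly one label is
#' the reference (open, crystal-like) state.
#'
#' @param id short identifier, e.g. `"r206"`.
#' @param residue_number residue described.
#' @param residue_name three-letter residue name (informational).
#' @param metric `"dihedral"` or `"min_distance"`.
#' @param atoms for dihedrals: the four atom names, in order.
#' @param partner_residue for distances: the partner residue number.
#' @param breaks ordered bin edges tiling the domain. For dihedrals the
#'   first and last edge must span a full 360-degree domain; for
#'   distances use `c(0, threshold, Inf)`.
#' @param labels one label per bin.
#' @param reference the reference-state label.
#' @param domain angle domain for dihedrals.
#' @return object of class `state_definition`.
#' @export
state_definition <- function(id, residue_number, residue_name = "",
                             metric = c("dihedral", "min_distance"),
                             atoms = NULL, partner_residue = NULL,
                             breaks, labels, reference,
                             domain = c(-180, 180)) {
  metric <- match.arg(metric)
  if (length(labels) != length(breaks) - 1L)
    stop("need one label per bin: ", length(breaks) - 1L, " bins, ",
         length(labels), " labels")
  if (anyDuplicated(labels)) stop("state labels must be unique")
  if (!reference %in% labels)
    stop("reference state '", reference, "' is not among the labels")
  if (is.unsorted(breaks, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  if (metric == "dihedral") {
    if (length(atoms) != 4L) stop("dihedral metric needs 4 atom names")
    if (abs((breaks[length(breaks)] - breaks[1L]) - 360) > 1e-9)
      stop("dihedral bins must tile a 360-degree domain")
  } else {
    if (is.null(partner_residue))
      stop("min_distance metric needs a partner residue")
    if (breaks[1L] != 0 || !is.infinite(breaks[length(breaks)]))
      stop("distance bins must tile (0, Inf)")
  }
  structure(list(id = id, residue_number = residue_number,
                 residue_name = residue_name, metric = metric,
                 atoms = atoms, partner_residue = partner_residue,
                 breaks = breaks, labels = labels, reference = reference,
                 domain = if (metric == "dihedral") domain else NULL),
            class = "state_definition")
}

#' @export
print.state_definition <- function(x, ...) {
  cat("<state_definition> ", x$id, " (", x$residue_name, x$residue_number,
      "): ", x$metric,
      if (x$metric == "dihedral") paste0(" ", paste(x$atoms, collapse = "-"))
      else paste0(" to residue ", x$partner_residue),
      "; states ", paste(x$labels, collapse = "/"),
      " (reference ", x$reference, ")\n", sep = "")
  invisible(x)
}

#' The built-in gating registry for GlpF
#'
#' Nine pore-lining residues with the descriptors and partitions used for
#' state classification. W48 and R206 are described by side-chain
#' dihedrals; the remaining seven by the minimal heavy-atom side-chain
#' distance to a partner residue, split at one threshold with states
#' in-pore (below threshold, strict) / out. The reference state of every
#' residue is the open, crystal-like one.
#'
#' @return named list of [state_definition] objects.
#' @export
gating_registry <- function() {
  reg <- list(
    w48 = state_definition("w48", 48, "TRP", "dihedral",
                           atoms = c("CA", "CB", "CG", "CD1"),
                           breaks = c(-180, 0, 70, 180),
                           labels = c("blocked", "restricted", "open"),
                           reference = "open", domain = c(-180, 180)),
    f200 = state_definition("f200", 200, "PHE", "min_distance",
                            partner_residue = 196,
                            breaks = c(0, 0.37, Inf),
                            labels = c("near", "far"), reference = "far"),
    a201 = state_definition("a201", 201, "ALA", "min_distance",
                            partner_residue = 48,
                            breaks = c(0, 0.35, Inf),
                            labels = c("blocking", "open"),
                            reference = "open"),
    r206 = state_definition("r206", 206, "ARG", "dihedral",
                            atoms = c("CA", "CB", "CG", "CZ"),
                            breaks = c(0, 50, 115, 160, 210, 240, 290, 360),
                            labels = c("a0_50", "a50_115", "a115_160",
                                       "a160_210", "a210_240", "a240_290",
                                       "a290_360"),
                            reference = "a290_360", domain = c(0, 360)),
    m202 = state_definition("m202", 202, "MET", "min_distance",
                            partner_residue = 21, breaks = c(0, 0.4, Inf),
                            labels = c("in_pore", "out"), reference = "out"),
    n203 = state_definition("n203", 203, "ASN", "min_distance",
                            partner_residue = 187, breaks = c(0, 0.3, Inf),
                            labels = c("in_pore", "out"), reference = "out"),
    n68 = state_definition("n68", 68, "ASN", "min_distance",
                           partner_residue = 52, breaks = c(0, 0.45, Inf),
                           labels = c("in_pore", "out"), reference = "out"),
    h66 = state_definition("h66", 66, "HIS", "min_distance",
                           partner_residue = 183, breaks = c(0, 0.35, Inf),
                           labels = c("in_pore", "out"), reference = "out"),
    v173 = state_definition("v173", 173, "VAL", "min_distance",
                            partner_residue = 75, breaks = c(0, 0.4, Inf),
                            labels = c("in_pore", "out"), reference = "out"))
  reg
}

#' Per-frame state trace
#'
#' @param states factor (or character) of per-frame state labels.
#' @param time_start_ns time of the first frame.
#' @param frame_period_ps frame period in ps.
#' @param definition_id id of the generating [state_definition].
#' @param pore_id pore identifier.
#' @param levels state labels (defaults to factor levels of `states`).
#' @return object of class `state_trace`.
#' @export
state_trace <- function(states, time_start_ns = 0, frame_period_ps = 10,
                        definition_id = "state", pore_id = "pore",
                        levels = NULL) {
  if (!is.factor(states))
    states <- factor(states, levels = if (is.null(levels)) unique(states)
                     else levels)
  else if (!is.null(levels)) states <- factor(states, levels = levels)
  if (anyNA(states)) stop("state trace contains unlabelled frames")
  structure(list(states = states, time_start_ns = time_start_ns,
                 frame_period_ps = frame_period_ps,
                 definition_id = definition_id, pore_id = pore_id),
            class = "state_trace")
}

#' @export
print.state_trace <- function(x, ...) {
  cat("<state_trace> ", x$definition_id, " @ ", x$pore_id, ": ",
      length(x$states), " frames, states ",
      paste(levels(x$states), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Frame times of a state trace (ns)
#' @param x a [state_trace].
#' @export
trace_times <- function(x)
  x$time_start_ns + (seq_along(x$states) - 1L) * x$frame_period_ps / 1000

#' Classify a metric series into gating states
#'
#' Each value is assigned to its half-open `[low, high)` bin, so
#' "less than threshold" is strict and boundary values go to the upper
#' bin. Dihedral values are first wrapped into the definition's domain.
#'
#' @param values numeric metric series (degrees or nm).
#' @param definition a [state_definition].
#' @param time_start_ns,frame_period_ps,pore_id time base metadata.
#' @return a [state_trace].
#' @export
classify_states <- function(values, definition, time_start_ns = 0,
                            frame_period_ps = 10, pore_id = "pore") {
  if (definition$metric == "dihedral")
    values <- wrap_angle(values, definition$domain)
  bin <- findInterval(values, definition$breaks, rightmost.closed = FALSE)
  if (any(bin < 1L | bin > length(definition$labels)))
    stop("metric value outside the partition domain")
  state_trace(factor(definition$labels[bin], levels = definition$labels),
              time_start_ns, frame_period_ps, definition$id, pore_id)
}

#' Compute a residue's metric series over a trajectory
#'
#' @param traj a [trajectory].
#' @param topology a [structure_model].
#' @param definition a [state_definition].
#' @param chain_id chain to evaluate.
#' @param policy side-chain atom policy for distance metrics.
#' @param box periodic box or `NULL`.
#' @return numeric series, one value per frame.
#' @export
gating_metric_series <- function(traj, topology, definition,
                                 chain_id = NULL, policy = "heavy",
                                 box = NULL) {
  if (definition$metric == "dihedral") {
    ids <- vapply(definition$atoms, function(nm) {
      id <- atom_ids_of(topology, chain_id, definition$residue_number, nm)
      if (length(id) != 1L)
        stop("atom ", nm, " of residue ", definition$residue_number,
             " not uniquely resolved")
      id
    }, 0L)
    dihedral_angle(traj, ids, definition$domain)
  } else {
    min_sidechain_distance(traj, topology, definition$residue_number,
                           definition$partner_residue, chain_id,
                           policy = policy, box = box)
  }
}

#' State populations over a time range
#'
#' @param trace a [state_trace].
#' @param range length-2 numeric, half-open `[start, end)` in ns;
#'   default: the whole trace.
#' @return named numeric vector of fractions summing to 1.
#' @export
state_populations <- function(trace, range = NULL) {
  t <- trace_times(trace)
  keep <- if (is.null(range)) rep(TRUE, length(t))
          else t >= range[1L] & t < range[2L]
  if (!any(keep)) stop("no frames in the requested range")
  tab <- table(trace$states[keep])
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p
}

#' Serialize / load a gating registry as YAML
#'
#' @param registry named list of [state_definition]s.
#' @param path file path.
#' @return `path` (write) or the registry (read).
#' @export
write_registry <- function(registry, path) {
  ser <- lapply(registry, function(d) {
    out <- d[!vapply(d, is.null, NA)]
    class(out) <- NULL
    out$breaks <- ifelse(is.infinite(out$breaks), ".inf", out$breaks)
    out
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(d) {
    br <- as.numeric(ifelse(d$breaks == ".inf", Inf, d$breaks))
    state_definition(d$id, d$residue_number, d$residue_name, d$metric,
                     atoms = unlist(d$atoms),
                     partner_residue = d$partner_residue,
                     breaks = br, labels = unlist(d$labels),
                     reference = d$reference,
                     domain = if (!is.null(d$domain)) unlist(d$domain)
                              else c(-180, 180))
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}
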