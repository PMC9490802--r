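## Least-squares superposition of trajectory frames onto a reference
## structure (orthogonal Procrustes / Kabsch contract).

#' Superpose a coordinate frame onto a reference structure
#'
#' Finds the proper rotation and translation minimising the mass-unweighted
#' RMSD between the selected atoms of `frame` and of `reference`
#' (typically a C-alpha selection of the transmembrane bundle). The
#' returned transform maps frame coordinates as `x %*% rotation +
#' translation`.
#'
#' @param frame coordinate matrix (n x 3, nm) with atom ids as rownames,
#'   or a [trajectory] together with `frame_index`.
#' @param reference a [structure_model] holding the reference coordinates.
#' @param selection atom ids (present in both frame and reference) used
#'   for the fit; at least 3.
#' @param frame_index frame number when `frame` is a trajectory.
#' @return object of class `superposition`: list with `rotation` (3 x 3,
#'   determinant +1), `translation` (nm), `fit_rmsd` (nm) and `selection`.
#' @export
superpose <- function(frame, reference, selection, frame_index = 1L) {
  if (inherits(frame, "trajectory")) frame <- frame_coords(frame, frame_index)
  if (length(selection) < 3L)
    stop("superposition is underdetermined: selection has fewer than 3 atoms")
  idx <- match(as.character(selection), rownames(frame))
  if (anyNA(idx))
    stop("selection atom(s) absent from frame: ",
         paste(selection[is.na(idx)], collapse = ", "))
  mob <- frame[idx, , drop = FALSE]
  ref <- coords(reference, selection)
  k <- kabsch(mob, ref)
  structure(list(rotation = k$rotation, translation = k$translation,
                 fit_rmsd = k$rmsd, selection = selection),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> fit RMSD ", format(x$fit_rmsd, digits = 4),
      " nm over ", length(x$selection), " atoms\n", sep = "")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param x a `superposition` (or any list with `rotation`/`translation`).
#' @param coords n x 3 matrix, or a [trajectory] (every frame transformed).
#' @return transformed coordinates of the same shape/class.
#' @export
apply_transform <- function(x, coords) {
  if (inherits(coords, "trajectory")) {
    tr <- coords
    for (i in seq_len(n_frames(tr))) {
      m <- frame_coords(tr, i)
      tr$coords[i, , ] <- sweep(m %*% x$rotation, 2L, x$translation, "+")
    }
    return(tr)
  }
  sweep(coords %*% x$rotation, 2L, x$translation, "+")
}

#' Superpose every frame of a trajectory onto a reference
#'
#' Each frame is independently fitted on `selection`; the transformed
#' trajectory and the per-frame fit RMSDs are returned.
#'
#' @inheritParams superpose
#' @param traj a [trajectory].
#' @return list with `trajectory` (fitted) and `fit_rmsd` (numeric per
#'   frame, nm).
#' @export
superpose_trajectory <- function(traj, reference, selection) {
  nf <- n_frames(traj)
  rmsd <- numeric(nf)
  out <- traj
  for (i in seq_len(nf)) {
    sp <- superpose(frame_coords(traj, i), reference, selection)
    out$coords[i, , ] <- apply_transform(sp, frame_coords(traj, i))
    rmsd[i] <- sp$fit_rmsd
  }
  list(trajectory = out, fit_rmsd = rmsd)
}

## Default TM-bundle fit selection: C-alpha atoms of the transmembrane
## helices and half-helices of one GlpF protomer.
#' Transmembrane-bundle residue ranges of GlpF
#'
#' The named helix/half-helix segments of one protomer and their union,
#' used as the default C-alpha fit selection and for per-segment RMSD.
#'
#' @return named list of integer residue-number vectors; component
#'   `tm_bundle` is the union of all helical segments, `L6` the pore loop
#'   carrying F200-N203.
#' @export
glpf_segments <- function() {
  segs <- list(
    TM1 = 7:35, TM2 = 41:63, HH1 = 69:79, TM3 = 83:119,
    TM4 = 145:167, TM5 = 178:196, HH2 = 204:217, TM6 = 232:255)
  segs$L6 <- 197:203
  segs$tm_bundle <- sort(unlist(segs[1:8], use.names = FALSE))
  segs
}
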