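## Trajectory container, the portable CSV trajectory format, and readers.

#' Construct a trajectory
#'
#' Time-ordered coordinate frames for a declared atom subset.
#'
#' @param coords numeric array `(n_frames, n_atoms, 3)` in nm.
#' @param atom_id integer vector of length `n_atoms` naming the atoms
#'   (ids refer to the topology / reference structure).
#' @param frame_period_ps time between saved frames in ps (default 10).
#' @param time_origin_ns time of the first frame in ns (default 0).
#' @param box optional `n_frames x 3` matrix of orthorhombic box lengths
#'   in nm.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(coords, atom_id, frame_period_ps = 10,
                       time_origin_ns = 0, box = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[3L] != 3L)
    stop("'coords' must be an (n_frames, n_atoms, 3) array")
  if (dim(coords)[1L] < 1L) stop("trajectory needs at least one frame")
  if (dim(coords)[2L] != length(atom_id))
    stop("atom count mismatch: coords have ", dim(coords)[2L],
         " atoms, atom_id has ", length(atom_id))
  if (frame_period_ps <= 0) stop("frame_period_ps must be positive")
  if (!is.null(box)) {
    box <- as.matrix(box)
    if (nrow(box) != dim(coords)[1L] || ncol(box) != 3L)
      stop("'box' must be n_frames x 3")
  }
  structure(list(coords = coords, atom_id = as.integer(atom_id),
                 frame_period_ps = frame_period_ps,
                 time_origin_ns = time_origin_ns, box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_frames(x), " frames x ", length(x$atom_id),
      " atoms, dt = ", x$frame_period_ps, " ps, t0 = ",
      x$time_origin_ns, " ns\n", sep = "")
  invisible(x)
}

#' @rdname trajectory
#' @param x a `trajectory`.
#' @export
n_frames <- function(x) dim(x$coords)[1L]

#' Frame times of a trajectory in ns
#' @param x a `trajectory`.
#' @export
frame_times <- function(x)
  x$time_origin_ns + (seq_len(n_frames(x)) - 1L) * x$frame_period_ps / 1000

#' Coordinates of one frame
#' @param x a `trajectory`.
#' @param i frame index (1-based).
#' @return n_atoms x 3 matrix in nm, rownames = atom ids.
#' @export
frame_coords <- function(x, i) {
  m <- x$coords[i, , , drop = TRUE]
  dim(m) <- c(length(x$atom_id), 3L)
  rownames(m) <- x$atom_id
  m
}

#' Concatenate trajectory segments
#'
#' Segments must share atoms and frame period; times must continue
#' monotonically.
#'
#' @param ... `trajectory` objects in time order.
#' @return one `trajectory` with a continuous time base.
#' @export
concat_trajectories <- function(...) {
  segs <- list(...)
  if (length(segs) == 1L && is.list(segs[[1]]) &&
      !inherits(segs[[1]], "trajectory")) segs <- segs[[1]]
  ref <- segs[[1L]]
  for (s in segs[-1L]) {
    if (!identical(s$atom_id, ref$atom_id))
      stop("cannot concatenate: atom sets differ")
    if (s$frame_period_ps != ref$frame_period_ps)
      stop("cannot concatenate: frame periods differ")
  }
  ends <- vapply(segs, function(s) max(frame_times(s)), 0)
  starts <- vapply(segs, function(s) s$time_origin_ns, 0)
  if (any(starts[-1L] <= ends[-length(ends)]))
    stop("cannot concatenate: segment times are not monotone")
  coords <- do.call(function(...) abind3(list(...)), segs)
  trajectory(coords, ref$atom_id, ref$frame_period_ps, ref$time_origin_ns,
             box = if (!is.null(ref$box))
               do.call(rbind, lapply(segs, `[[`, "box")))
}

abind3 <- function(segs) {
  n <- sum(vapply(segs, n_frames, 0L))
  out <- array(NA_real_, c(n, dim(segs[[1L]]$coords)[2L], 3L))
  at <- 0L
  for (s in segs) {
    out[at + seq_len(n_frames(s)), , ] <- s$coords
    at <- at + n_frames(s)
  }
  out
}

#' Write a trajectory in the portable CSV format
#'
#' Plain-text interchange format with header
#' `frame,time_ps,atom_id,x_nm,y_nm,z_nm`, one row per atom per frame,
#' frames in time order. Round-trips losslessly at the written precision.
#'
#' @param x a [trajectory].
#' @param path output file path.
#' @param digits decimal digits written for coordinates (default 6).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(x, path, digits = 6) {
  nf <- n_frames(x)
  na <- length(x$atom_id)
  tps <- rep(frame_times(x) * 1000, each = na)
  df <- data.frame(
    frame = rep(seq_len(nf), each = na),
    time_ps = tps,
    atom_id = rep(x$atom_id, nf),
    x_nm = round(as.vector(t(x$coords[, , 1L])), digits),
    y_nm = round(as.vector(t(x$coords[, , 2L])), digits),
    z_nm = round(as.vector(t(x$coords[, , 3L])), digits))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "time_ps", "atom_id", "x_nm", "y_nm", "z_nm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("portable trajectory '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  frames <- sort(unique(df$frame))
  ids <- df$atom_id[df$frame == frames[1L]]
  na <- length(ids)
  per_frame <- table(df$frame)
  if (any(per_frame != na))
    stop("atom count varies across frames in '", path, "' (expected ",
         na, ", found ", min(per_frame), "-", max(per_frame), ")")
  df <- df[order(df$frame, match(df$atom_id, ids)), ]
  times_ps <- df$time_ps[seq(1L, nrow(df), by = na)]
  if (length(times_ps) > 1L && any(diff(times_ps) <= 0))
    stop("non-monotone frame times in '", path, "'")
  dt <- if (length(times_ps) > 1L) diff(times_ps)[1L] else 10
  nf <- length(frames)
  coords <- array(NA_real_, c(nf, na, 3L))
  coords[, , 1L] <- matrix(df$x_nm, nf, na, byrow = TRUE)
  coords[, , 2L] <- matrix(df$y_nm, nf, na, byrow = TRUE)
  coords[, , 3L] <- matrix(df$z_nm, nf, na, byrow = TRUE)
  trajectory(coords, ids, frame_period_ps = dt,
             time_origin_ns = times_ps[1L] / 1000)
}

#' Read trajectory file(s)
#'
#' Supported formats: the portable CSV trajectory
#' (`frame,time_ps,atom_id,x_nm,y_nm,z_nm`) and binary DCD (read through
#' bio3d, coordinates converted Angstrom to nm, atom ids taken from the
#' topology). Multiple segment files are concatenated in the given order
#' and must be time-continuous.
#'
#' @param paths one or more file paths (time-ordered segments).
#' @param topology optional [structure_model]; when given, the atom count
#'   of every frame is validated against it (CSV) or atom ids are taken
#'   from it (DCD).
#' @param format `"csv"` or `"dcd"`; default guessed from extension.
#' @return a [trajectory].
#' @export
read_trajectory <- function(paths, topology = NULL,
                            format = c("auto", "csv", "dcd")) {
  format <- match.arg(format)
  one <- function(path) {
    fmt <- format
    if (fmt == "auto")
      fmt <- if (tolower(tools::file_ext(path)) == "dcd") "dcd" else "csv"
    tr <- if (fmt == "dcd") read_trajectory_dcd(path, topology)
          else read_trajectory_csv(path)
    if (!is.null(topology)) {
      known <- tr$atom_id %in% topology$atoms$atom_id
      if (!all(known))
        stop("trajectory atom id(s) absent from topology: ",
             paste(utils::head(tr$atom_id[!known]), collapse = ", "))
    }
    tr
  }
  segs <- lapply(paths, one)
  if (length(segs) == 1L) segs[[1L]] else concat_trajectories(segs)
}

read_trajectory_dcd <- function(path, topology) {
  if (is.null(topology))
    stop("reading DCD requires a topology for atom identities")
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  na <- ncol(xyz) / 3L
  if (na != nrow(topology$atoms))
    stop("DCD atom count (", na, ") does not match topology (",
         nrow(topology$atoms), ")")
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nf, na, 3L))
  coords[, , 1L] <- xyz[, seq(1L, by = 3L, length.out = na)] / 10
  coords[, , 2L] <- xyz[, seq(2L, by = 3L, length.out = na)] / 10
  coords[, , 3L] <- xyz[, seq(3L, by = 3L, length.out = na)] / 10
  trajectory(coords, topology$atoms$atom_id)
}
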