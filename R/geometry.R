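## Core 3-D geometry: rigid-body superposition, torsions, internal-coordinate
## atom placement. All lengths in nm, all angles in degrees unless noted.

`%dot%` <- function(a, b) sum(a * b)

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

#' Optimal rigid superposition of two coordinate sets
#'
#' Least-squares (Kabsch) fit of `frame` onto `reference`: finds the proper
#' rotation `R` and translation `t` minimising the mass-unweighted RMSD of
#' `frame %*% R + t` from `reference` over matched rows.
#'
#' @param frame numeric matrix (n x 3), mobile coordinates in nm.
#' @param reference numeric matrix (n x 3), target coordinates in nm; rows
#'   correspond to rows of `frame`.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   and `rmsd` (nm) of the fitted coordinates.
#' @keywords internal
kabsch <- function(frame, reference) {
  if (!is.matrix(frame) || ncol(frame) != 3L)
    stop("'frame' must be an n x 3 matrix")
  if (nrow(frame) != nrow(reference))
    stop("coordinate sets differ in size")
  if (nrow(frame) < 3L)
    stop("superposition is underdetermined with fewer than 3 atoms")
  cf <- colMeans(frame)
  cr <- colMeans(reference)
  A <- sweep(frame, 2L, cf)
  B <- sweep(reference, 2L, cr)
  H <- crossprod(A, B)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)     # row-vector convention: y ~ x %*% R + t
  tvec <- unname(cr - drop(cf %*% R))
  fitted <- sweep(frame %*% R, 2L, tvec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = R, translation = tvec, rmsd = rmsd)
}

#' Torsion angle of four points
#'
#' Dihedral of the four points in the IUPAC sign convention (cis = 0;
#' positive when, looking from the second toward the third point, the far
#' bond is rotated clockwise from the near bond). The points need not be
#' covalently bonded: the value is the torsion of the four positions.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates (nm).
#' @param domain output interval, `c(-180, 180)` or `c(0, 360)`; half-open
#'   on the right.
#' @return angle in degrees within `domain`.
#' @examples
#' torsion(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)) # trans: 180
#' @export
torsion <- function(p1, p2, p3, p4, domain = c(-180, 180)) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("undefined torsion: three consecutive points are colinear")
  m1 <- vcross(n1, b2 / vnorm(b2))
  x <- n1 %dot% n2
  y <- m1 %dot% n2
  wrap_angle(atan2(-y, x) * 180 / pi, domain)
}

#' Wrap an angle into a half-open interval
#'
#' @param theta angle(s) in degrees.
#' @param domain `c(-180, 180)` or `c(0, 360)` (any width-360 interval
#'   works); result lies in `[domain[1], domain[2])`.
#' @return wrapped angle(s).
#' @export
wrap_angle <- function(theta, domain = c(-180, 180)) {
  lo <- domain[1L]
  lo + (theta - lo) %% 360
}

## Place a point D given three predecessors A-B-C, the |C-D| distance, the
## B-C-D angle and the A-B-C-D torsion (natural-extension / NeRF scheme).
## Used by the synthetic reference builder; inverse of torsion().
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- vcross(ab, bc)
  if (vnorm(n) < 1e-10) stop("colinear support points in place_atom")
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  M <- cbind(bc, m, n)
  drop(M %*% d_local) + c
}

## Minimum-image displacement under an orthorhombic box (nm). box = NULL
## means no periodicity.
min_image <- function(d, box = NULL) {
  if (is.null(box)) return(d)
  d - round(d / box) * box
}
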