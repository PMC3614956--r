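# Minimum-image geometry primitives for orthorhombic cells, and proper
# (signed, IUPAC) dihedral angles.

#' Minimum-image displacement
#'
#' Componentwise displacement `p - q` folded into `(-box/2, box/2]`.
#' Vectorized: `p`, `q` may be `n x 3` matrices.
#'
#' @param p,q points (length-3 vectors or `n x 3` matrices), Angstrom.
#' @param box orthorhombic box lengths (length 3).
#' @return displacement(s), same shape as the inputs.
#' @export
min_image_disp <- function(p, q, box) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  if (is.null(dim(q))) q <- matrix(q, ncol = 3L)
  if (any(box <= 0)) stop("box lengths must be > 0", call. = FALSE)
  d <- p - q
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Minimum-image distance between two points
#'
#' Euclidean distance under the orthorhombic minimum-image convention.
#'
#' @inheritParams min_image_disp
#' @return distance(s) in Angstrom.
#' @export
min_image_distance <- function(p, q, box) {
  d <- min_image_disp(p, q, box)
  sqrt(rowSums(d * d))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Proper dihedral angle
#'
#' Signed IUPAC torsion p1-p2-p3-p4 in degrees, in `(-180, 180]`.
#' The cis (eclipsed) arrangement is 0, the trans (anti) arrangement 180.
#'
#' @param p1,p2,p3,p4 length-3 points.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-10 || sqrt(sum(b2^2)) < 1e-10 ||
      sqrt(sum(b3^2)) < 1e-10)
    stop("coincident consecutive points: dihedral undefined", call. = FALSE)
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-14 || sum(n2^2) < 1e-14)
    stop("collinear bond vectors: dihedral undefined", call. = FALSE)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}
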