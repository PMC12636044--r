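#' Geometry primitives: dihedrals, internal-coordinate placement, Kabsch
#' superposition.
#'
#' @name geometry
#' @keywords internal
NULL

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)

#' Dihedral angle of four points
#'
#' Signed torsion a-b-c-d in degrees, in (-180, 180].
#'
#' @param a,b,c,d Numeric 3-vectors (nm).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Place atom D given A, B, C with bond length |CD|, angle B-C-D (deg) and
# dihedral A-B-C-D (deg). Standard internal-coordinate (NeRF) construction.
place_atom <- function(a, b, c, length, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  bc <- unitv(c - b)
  n <- unitv(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(tor),
          -length * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' `mobile` and `reference` point sets with fixed correspondence.
#' Reflections are corrected by flipping the sign of the smallest singular
#' direction, so the returned rotation always has determinant +1.
#'
#' @param mobile,reference n x 3 coordinate matrices (nm), n >= 3.
#' @param weights Optional non-negative per-point weights.
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (nm) and `transform(x)`, a function applying the fit to new
#'   coordinates.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3 || nrow(reference) != n)
    abort("need matching point sets with at least 3 points")
  w <- weights %||% rep(1, n)
  if (any(w < 0) || sum(w) <= 0) abort("weights must be non-negative, not all zero")
  w <- w / sum(w)
  mu_m <- colSums(mobile * w)
  mu_r <- colSums(reference * w)
  mc <- sweep(mobile, 2, mu_m)
  rc <- sweep(reference, 2, mu_r)
  h <- t(mc * w) %*% rc
  sv <- svd(h)
  if (sv$d[2] < 1e-12) abort("degenerate (rank-deficient) point set")
  s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  rot <- sv$v %*% s %*% t(sv$u)
  fitted <- mc %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - rc)^2)))
  trans <- mu_r - as.vector(rot %*% mu_m)
  list(rotation = rot, translation = trans, rmsd = rmsd,
       transform = function(x) sweep(as.matrix(x) %*% t(rot), 2, trans, `+`))
}

# Principal axis of a point cloud, oriented from the first to the last point.
principal_axis <- function(coords) {
  cc <- sweep(coords, 2, colMeans(coords))
  ax <- svd(cc, nu = 0, nv = 1)$v[, 1]
  if (sum(ax * (coords[nrow(coords), ] - coords[1, ])) < 0) ax <- -ax
  ax
}
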