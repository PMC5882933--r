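## Internal 3D geometry helpers (vector ops, internal-coordinate placement).

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector in geometry construction")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Returns the position `d` such that |d-c| = `bond`, the angle b-c-d equals
#' `angle` and the dihedral a-b-c-d equals `torsion` (degrees).
#'
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Remaining two tetrahedral directions at a center whose two existing
# neighbors lie along unit vectors u1, u2. Returns a 2 x 3 matrix.
tetrahedral_pair <- function(u1, u2) {
  b <- -vunit(u1 + u2)
  p <- vunit(vcross(u1, u2))
  half <- 54.735 * pi / 180  # half the tetrahedral angle
  rbind(cos(half) * b + sin(half) * p,
        cos(half) * b - sin(half) * p)
}

# Squared-distance matrix between two coordinate matrices (n x 3, m x 3)
cross_dist2 <- function(A, B) {
  an <- rowSums(A * A)
  bn <- rowSums(B * B)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}
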