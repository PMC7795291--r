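#' Physical constants used throughout the package
#'
#' Boltzmann constant in kcal/(mol K) and the Coulomb conversion constant
#' in kcal A / (mol e^2), following AMBER conventions.  Units are fixed
#' package-wide: Angstrom, degrees, kcal/mol, elementary charge, ps.
#'
#' @format Named numeric vector with elements `kB` and `coulomb`.
#' @export
pepconf_constants <- c(kB = 0.0019872041, coulomb = 332.0636)

#' Wrap angles to the canonical interval [-180, 180)
#'
#' All angular quantities in the package live on the half-open interval
#' \eqn{[-180, 180)} degrees.  The wrap is `x - 360 * floor((x + 180)/360)`,
#' which is idempotent and maps +180 to -180.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, in `[-180, 180)`.
#' @examples
#' wrap_angle(c(190, -180, 180, 725))
#' @export
wrap_angle <- function(x) {
  stopifnot(is.numeric(x))
  w <- x - 360 * floor((x + 180) / 360)
  # guard against floating-point landing exactly on +180
  w[w >= 180] <- -180
  w
}

#' Signed torsion angle of four points
#'
#' Computes the dihedral angle p1-p2-p3-p4 with the IUPAC sign convention
#' (positive clockwise when viewed from p2 toward p3), returned in degrees
#' on \eqn{[-180, 180)}.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return scalar angle in degrees.
#' @examples
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(0, 1, 1))  # -90
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sqrt(sum(b2^2)) < 1e-12)
    stop("undefined torsion: middle bond has zero length")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("undefined torsion: collinear consecutive bonds")
  m <- cross3(n1, b2 / sqrt(sum(b2^2)))
  wrap_angle(atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Vectorised torsion over frame stacks: each argument is an n x 3 matrix.
torsion_rows <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
              b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
              b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
              b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
              b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  nb2 <- sqrt(rowSums(b2^2))
  u2 <- b2 / nb2
  m <- cbind(n1[, 2] * u2[, 3] - n1[, 3] * u2[, 2],
             n1[, 3] * u2[, 1] - n1[, 1] * u2[, 3],
             n1[, 1] * u2[, 2] - n1[, 2] * u2[, 1])
  wrap_angle(atan2(rowSums(m * n2), rowSums(n1 * n2)) * 180 / pi)
}
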