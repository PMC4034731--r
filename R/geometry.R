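# Shared geometric primitives: quasi-uniform sphere points, Shrake-Rupley
# solvent-accessible surface area, Kabsch superposition, dihedral angles.

# golden-spiral quasi-uniform points on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom is wrapped in a quasi-uniform shell of test points at radius
#' r_vdw + probe; a point is exposed iff it lies outside every neighbour's
#' expanded sphere. Per-atom area is the exposed fraction of
#' 4*pi*(r_vdw+probe)^2.
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param radii per-atom van der Waals radii (Angstrom).
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points test points per atom.
#' @return list with `atom_area` (Angstrom^2 per atom) and `total`.
#' @export
shrake_rupley <- function(xyz, radii, probe = 1.4, n_points = 960) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(length(radii) == n)
  if (anyNA(radii)) stop("missing vdW radius")
  R <- radii + probe
  pts <- sphere_points(n_points)
  area <- numeric(n)
  for (i in seq_len(n)) {
    shell <- sweep(pts * R[i], 2, xyz[i, ], "+")
    # neighbours whose expanded sphere can reach atom i's shell
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ], "-")^2)
    nb <- which(d2 < (R + R[i])^2 & seq_len(n) != i)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- (shell[, 1] - xyz[j, 1])^2 + (shell[, 2] - xyz[j, 2])^2 +
            (shell[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj > R[j]^2
      if (!any(exposed)) break
    }
    area[i] <- mean(exposed) * 4 * pi * R[i]^2
  }
  list(atom_area = area, total = sum(area))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation of `mobile` onto `reference` over the
#' given atom rows; a proper rotation (det = +1) is enforced. RMSD is the
#' unweighted root-mean-square deviation over the fitted rows after
#' superposition.
#'
#' @param mobile,reference n x 3 coordinate matrices.
#' @param idx rows used for fitting (default all).
#' @return list with `R` (3x3 rotation), `t` (translation), `rmsd` (Angstrom)
#'   and `transform(xyz)` applying the map to arbitrary coordinates.
#' @export
superpose <- function(mobile, reference, idx = seq_len(nrow(mobile))) {
  A <- as.matrix(mobile)[idx, , drop = FALSE]
  B <- as.matrix(reference)[idx, , drop = FALSE]
  if (nrow(A) < 3) stop("superposition needs at least 3 atoms")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (all(svd(A0)$d[2:3] < 1e-10)) stop("degenerate (collinear) geometry")
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cb - as.vector(Rm %*% ca)
  fitted <- sweep(A %*% t(Rm), 2, tvec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(R = Rm, t = tvec, rmsd = rmsd,
       transform = function(xyz) sweep(as.matrix(xyz) %*% t(Rm), 2, tvec, "+"))
}

# RMSD without fitting
raw_rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

#' Signed dihedral angle
#'
#' @param p 4 x 3 matrix of positions.
#' @return angle in degrees in (-180, 180]; `NA` if the middle bond is
#'   degenerate (collinear atoms).
#' @export
dihedral <- function(p) {
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)
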