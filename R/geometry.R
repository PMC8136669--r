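#' Standard backbone covalent geometry
#'
#' Bond lengths and bond angles used to materialize backbones from dihedral
#' angles. Defaults are Engh--Huber-style ideal values; all builds in the
#' package go through one editable geometry object so that sensitivity to the
#' constants can be probed.
#'
#' @param bond_lengths Named numeric vector with entries `N-CA`, `CA-C`,
#'   `C-N` in Angstrom.
#' @param bond_angles Named numeric vector with entries `N-CA-C`, `CA-C-N`,
#'   `C-N-CA` in degrees.
#' @param default_omega Peptide-bond torsion assumed when none is supplied
#'   (degrees; 180 = trans).
#' @return An object of class `backbone_geometry`.
#' @examples
#' g <- default_geometry()
#' g$bond_lengths
#' @export
default_geometry <- function(bond_lengths = c("N-CA" = 1.458,
                                              "CA-C" = 1.525,
                                              "C-N"  = 1.329),
                             bond_angles = c("N-CA-C" = 111.2,
                                             "CA-C-N" = 117.2,
                                             "C-N-CA" = 121.7),
                             default_omega = 180) {
  stopifnot(all(c("N-CA", "CA-C", "C-N") %in% names(bond_lengths)),
            all(c("N-CA-C", "CA-C-N", "C-N-CA") %in% names(bond_angles)))
  if (any(bond_lengths <= 0))
    stop("bond lengths must be positive")
  if (any(bond_angles <= 0 | bond_angles >= 180))
    stop("bond angles must lie in (0, 180) degrees")
  structure(list(bond_lengths = bond_lengths,
                 bond_angles = bond_angles,
                 default_omega = default_omega),
            class = "backbone_geometry")
}

# packed (lengths, angles) vector consumed by the compiled builder
geometry_pack <- function(g) {
  c(g$bond_lengths[c("N-CA", "CA-C", "C-N")],
    g$bond_angles[c("N-CA-C", "CA-C-N", "C-N-CA")])
}

#' Wrap angles into (-180, 180]
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles reduced modulo 360 into the interval (-180, 180].
#' @examples
#' wrap_angle(c(190, -181, 360, 180))
#' @export
wrap_angle <- function(x) {
  a <- (x + 180) %% 360 - 180
  a[a <= -180 & !is.na(a)] <- 180
  a
}

#' Dihedral-angle representation of a backbone fragment
#'
#' An M-residue fragment is fixed (up to rigid motion, under standard
#' covalent geometry) by its 2(M-1) phi/psi torsions in the order
#' psi_1, phi_2, psi_2, ..., phi_M, plus M-1 peptide-bond omega torsions.
#'
#' @param phi_psi Numeric vector of length 2(M-1), degrees, ordered
#'   psi_1, phi_2, psi_2, ..., phi_M.
#' @param omega Optional numeric vector of M-1 peptide torsions (degrees);
#'   `NULL` means all-trans (180).
#' @return An object of class `dihedral_vector` with elements `M`,
#'   `phi_psi`, `omega`. Angles are wrapped into (-180, 180].
#' @examples
#' helix_dihedrals()
#' @export
dihedral_vector <- function(phi_psi, omega = NULL) {
  phi_psi <- as.numeric(phi_psi)
  if (length(phi_psi) < 2 || length(phi_psi) %% 2 != 0)
    stop("phi_psi must have even length 2(M-1) with M >= 2")
  M <- length(phi_psi) / 2 + 1
  if (is.null(omega)) omega <- rep(180, M - 1)
  if (length(omega) != M - 1)
    stop("omega must have M-1 entries")
  if (anyNA(phi_psi) || anyNA(omega))
    stop("angles must be finite")
  structure(list(M = M,
                 phi_psi = wrap_angle(phi_psi),
                 omega = wrap_angle(as.numeric(omega))),
            class = "dihedral_vector")
}

#' @export
print.dihedral_vector <- function(x, ...) {
  cat("Dihedral vector, M =", x$M, "residues\n")
  cat("  phi/psi:", paste(sprintf("%.1f", x$phi_psi), collapse = " "), "\n")
  if (any(x$omega != 180))
    cat("  omega:  ", paste(sprintf("%.1f", x$omega), collapse = " "), "\n")
  invisible(x)
}

#' Ideal alpha-helical dihedrals
#'
#' @param M Residue count.
#' @param phi,psi Backbone torsions applied uniformly (degrees).
#' @return A [dihedral_vector()] for the canonical helix.
#' @export
helix_dihedrals <- function(M = 5, phi = -57, psi = -47) {
  dihedral_vector(rep(c(psi, phi), M - 1))
}

#' Build Cartesian backbone coordinates from dihedral angles
#'
#' Sequential internal-coordinate construction (NeRF): each atom is placed
#' from the previous three using the bond length, bond angle and torsion.
#' The first three atoms sit in a canonical frame (N1 at the origin, CA1 on
#' +x, C1 in the xy-plane).
#'
#' @param d A [dihedral_vector()].
#' @param geometry A [default_geometry()] object.
#' @return A `backbone_fragment`: numeric 3M x 3 matrix of N, CA, C
#'   coordinates (Angstrom), rows cycling N, CA, C per residue.
#' @examples
#' f <- build_backbone(helix_dihedrals())
#' dim(f)
#' @export
build_backbone <- function(d, geometry = default_geometry()) {
  if (!inherits(d, "dihedral_vector"))
    stop("d must be a dihedral_vector")
  X <- cpp_build_backbone(d$phi_psi, d$omega, geometry_pack(geometry))
  as_backbone_fragment(X)
}

as_backbone_fragment <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) %% 3 != 0 || ncol(X) != 3)
    stop("a backbone fragment needs 3M rows of x/y/z coordinates")
  M <- nrow(X) / 3
  dimnames(X) <- list(rep(c("N", "CA", "C"), M), c("x", "y", "z"))
  structure(X, class = c("backbone_fragment", "matrix", "array"))
}

fragment_residues <- function(f) nrow(f) / 3

torsion_angle <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18)
    stop("degenerate geometry: three consecutive atoms are collinear")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Extract phi/psi and omega torsions from backbone coordinates
#'
#' Inverse of [build_backbone()]: computes the IUPAC-signed torsions from
#' consecutive atom quadruples and wraps them into (-180, 180].
#'
#' @param f A `backbone_fragment` (3M x 3 coordinates, M >= 2).
#' @return A [dihedral_vector()].
#' @examples
#' d <- helix_dihedrals()
#' extract_dihedrals(build_backbone(d))
#' @export
extract_dihedrals <- function(f) {
  f <- unclass(f)
  if (nrow(f) < 6) stop("invalid fragment: need at least 2 residues")
  M <- nrow(f) / 3
  pp <- numeric(2 * (M - 1))
  om <- numeric(M - 1)
  for (i in seq_len(M - 1)) {
    b <- 3 * (i - 1)
    pp[2 * i - 1] <- torsion_angle(f[b + 1, ], f[b + 2, ], f[b + 3, ], f[b + 4, ])  # psi_i
    om[i]         <- torsion_angle(f[b + 2, ], f[b + 3, ], f[b + 4, ], f[b + 5, ])  # omega_i
    pp[2 * i]     <- torsion_angle(f[b + 3, ], f[b + 4, ], f[b + 5, ], f[b + 6, ])  # phi_(i+1)
  }
  dihedral_vector(pp, om)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Returns the rotation and translation that minimize the mean-square
#' deviation of `f1` onto `f2` after centroid alignment. The rotation comes
#' from the SVD of the cross-covariance with the determinant sign fix, so a
#' proper rotation (never a reflection) is always returned, including for
#' rank-deficient (e.g. collinear) configurations.
#'
#' @param f1,f2 Coordinate matrices with equal numbers of rows.
#' @return A list with `rotation` (3 x 3), `translation` (length-3) such
#'   that `f1 %*% rotation + translation` superposes onto `f2` (rows as
#'   points), and the residual `rmsd` in Angstrom.
#' @examples
#' f <- build_backbone(helix_dihedrals())
#' kabsch_superpose(f, f)$rmsd
#' @export
kabsch_superpose <- function(f1, f2) {
  P <- unclass(as.matrix(f1)); Q <- unclass(as.matrix(f2))
  if (nrow(P) != nrow(Q)) stop("fragments have different atom counts")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  ss <- sum(Pc^2) + sum(Qc^2) - 2 * (s$d[1] + s$d[2] + d * s$d[3])
  list(rotation = R,
       translation = as.numeric(cq - cp %*% R),
       rmsd = sqrt(max(ss, 0) / nrow(P)))
}

#' Kabsch-optimal backbone RMSD
#'
#' Root-mean-square deviation over all 3M backbone atoms at the optimal
#' rigid superposition: the minimum over all spatial co-localizations of the
#' two fragments.
#'
#' @param f1,f2 `backbone_fragment` objects (or plain coordinate matrices)
#'   with equal atom counts.
#' @return RMSD in Angstrom (non-negative, symmetric in its arguments).
#' @examples
#' backbone_rmsd(build_backbone(helix_dihedrals()),
#'               build_backbone(dihedral_vector(rep(c(130, -110), 4))))
#' @export
backbone_rmsd <- function(f1, f2) {
  P <- unclass(as.matrix(f1)); Q <- unclass(as.matrix(f2))
  if (nrow(P) != nrow(Q)) stop("fragments have different atom counts")
  cpp_rmsd(P, Q)
}

#' Angular RMSD (RMSDA) between two dihedral vectors
#'
#' Root-mean-square of the circularly wrapped differences over the 2(M-1)
#' phi/psi torsions. Peptide-bond omega torsions are not scored, so two
#' fragments differing only by a cis/trans flip have RMSDA 0.
#'
#' @param d1,d2 [dihedral_vector()] objects with equal residue counts.
#' @return RMSDA in degrees.
#' @examples
#' rmsda(helix_dihedrals(), helix_dihedrals(phi = -17))
#' @export
rmsda <- function(d1, d2) {
  if (!inherits(d1, "dihedral_vector") || !inherits(d2, "dihedral_vector"))
    stop("rmsda expects dihedral_vector inputs")
  if (d1$M != d2$M) stop("fragments have different residue counts")
  delta <- wrap_angle(d1$phi_psi - d2$phi_psi)
  sqrt(mean(delta^2))
}
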