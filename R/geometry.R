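# Internal backbone geometry: torsion angles and internal-coordinate chain
# building (natural extension reference frames). All coordinates in Angstrom,
# all angles in degrees.

# Canonical backbone covalent geometry (Engh & Huber averages, rounded).
.BOND_N_CA <- 1.458
.BOND_CA_C <- 1.525
.BOND_C_N  <- 1.329
.BOND_C_O  <- 1.231
.ANGLE_N_CA_C <- 111.2
.ANGLE_CA_C_N <- 116.2
.ANGLE_C_N_CA <- 121.7
.ANGLE_CA_C_O <- 120.8

#' @noRd
deg2rad <- function(x) x * pi / 180

#' @noRd
rad2deg <- function(x) x * 180 / pi

#' Signed torsion angle for quadruples of points
#'
#' Rows of the four matrices are matched quadruples; returns degrees in
#' [-180, 180).
#' @noRd
torsion_angle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b2 <- p4 - p3
  b1n <- b1 / sqrt(rowSums(b1^2))
  v <- b0 - rowSums(b0 * b1n) * b1n
  w <- b2 - rowSums(b2 * b1n) * b1n
  x <- rowSums(v * w)
  cr <- cbind(
    b1n[, 2] * v[, 3] - b1n[, 3] * v[, 2],
    b1n[, 3] * v[, 1] - b1n[, 1] * v[, 3],
    b1n[, 1] * v[, 2] - b1n[, 2] * v[, 1]
  )
  y <- rowSums(cr * w)
  ang <- rad2deg(atan2(y, x))
  ang[ang >= 180] <- ang[ang >= 180] - 360
  # degenerate (collinear) quadruples have vanishing perpendicular parts
  degen <- rowSums(v^2) < 1e-10 | rowSums(w^2) < 1e-10
  ang[degen] <- NA_real_
  ang
}

#' Place one atom from three predecessors by internal coordinates
#'
#' d is placed so that |c-d| = bond, angle(b,c,d) = angle and
#' torsion(a,b,c,d) = torsion.
#' @noRd
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(
    ab[2] * bc[3] - ab[3] * bc[2],
    ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  )
  n <- n / sqrt(sum(n^2))
  m <- c(
    n[2] * bc[3] - n[3] * bc[2],
    n[3] * bc[1] - n[1] * bc[3],
    n[1] * bc[2] - n[2] * bc[1]
  )
  d2 <- bond * c(-cos(ang), cos(tor) * sin(ang), sin(tor) * sin(ang))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal backbone chain from phi/psi torsions
#'
#' Returns a list of n x 3 matrices (N, CA, C, O) for `n` residues built with
#' the given per-residue phi/psi (recycled), omega fixed trans (180).
#' Carbonyl O is placed in the peptide plane opposite the next N.
#' @noRd
build_chain <- function(n_res, phi, psi) {
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  N <- CA <- C <- O <- matrix(NA_real_, n_res, 3)
  # seed frame for residue 1
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BOND_N_CA, 0, 0)
  ang <- deg2rad(.ANGLE_N_CA_C)
  C[1, ] <- CA[1, ] + .BOND_CA_C * c(-cos(ang), sin(ang), 0)
  if (n_res > 1) {
    for (i in seq_len(n_res - 1)) {
      N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                               .BOND_C_N, .ANGLE_CA_C_N, psi[i])
      CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ],
                                .BOND_N_CA, .ANGLE_C_N_CA, 180)
      C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ],
                               .BOND_CA_C, .ANGLE_N_CA_C, phi[i + 1])
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                           .BOND_C_O, .ANGLE_CA_C_O, psi[i] - 180)
    }
  }
  # last O: same construction with a nominal psi
  O[n_res, ] <- place_atom(N[n_res, ], CA[n_res, ], C[n_res, ],
                           .BOND_C_O, .ANGLE_CA_C_O, psi[n_res] - 180)
  list(N = N, CA = CA, C = C, O = O)
}

#' Rotation matrix sending orthonormal frame F1 (columns) onto F2
#' @noRd
frame_rotation <- function(f_from, f_to) f_to %*% t(f_from)

#' Orthonormalize a 3-column frame by Gram-Schmidt
#' @noRd
orthonormal_frame <- function(u, v) {
  u <- u / sqrt(sum(u^2))
  v <- v - sum(u * v) * u
  v <- v / sqrt(sum(v^2))
  w <- c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
  cbind(u, v, w)
}
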