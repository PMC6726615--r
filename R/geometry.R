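# Internal geometry kernels shared by the fixture builder, the restrained
# refiner and the structure utilities.  All coordinates are Angstrom.

# row-wise cross product of n x 3 matrices
vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

vnorm <- function(a) sqrt(rowSums(a * a))

vunit <- function(a) a / pmax(vnorm(a), 1e-12)

# signed dihedral angle (radians, (-pi, pi]) for row-matched quadruplets
# p1..p4 given as n x 3 matrices
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(rowSums(m1 * n2), rowSums(n1 * n2))
}

# analytic gradient of the dihedral wrt the four points; returns a list of
# four n x 3 matrices.  Standard rigid-rotation decomposition.
dihedral_grad <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  nb2 <- pmax(vnorm(b2), 1e-12)
  g1 <- n1 * (nb2 / pmax(rowSums(n1 * n1), 1e-12))
  g4 <- -n2 * (nb2 / pmax(rowSums(n2 * n2), 1e-12))
  c12 <- rowSums(b1 * b2) / nb2^2
  c32 <- rowSums(b3 * b2) / nb2^2
  g2 <- -g1 * (c12 + 1) + g4 * c32
  g3 <- -(g1 + g2 + g4)
  list(g1, g2, g3, g4)
}

# NeRF: place a new atom at bond length r from c, bond angle theta at c
# (with respect to b-c), and torsion phi about the b-c axis relative to a.
place_atom <- function(a, b, c, r, theta, phi) {
  bc <- (c - b); bc <- bc / sqrt(sum(bc^2))
  ab <- (b - a)
  n <- vcross(matrix(ab, 1), matrix(bc, 1))[1, ]
  n <- n / max(sqrt(sum(n^2)), 1e-12)
  m <- vcross(matrix(n, 1), matrix(bc, 1))[1, ]
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi),
         -r * sin(theta) * sin(phi))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# ideal backbone geometry (standard stereochemistry values)
IDEAL <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521,
  a_n_ca_c = 111.0 * pi / 180, a_ca_c_n = 116.6 * pi / 180,
  a_c_n_ca = 121.7 * pi / 180, a_ca_c_o = 120.8 * pi / 180,
  a_n_ca_cb = 110.4 * pi / 180,
  # torsion of CB about the N-CA axis relative to C: fixes L-chirality
  t_c_n_ca_cb = 122.6 * pi / 180,
  omega_trans = pi
)

# construct a fold_model from per-residue phi/psi (radians).  Builds N,
# CA, C by NeRF with trans peptide bonds, then O and CB.  phi[1] and the
# final psi only orient terminal O placement.
backbone_from_torsions <- function(phi, psi, sequence) {
  L <- length(phi)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(IDEAL$b_n_ca, 0, 0)
  C[1, ] <- place_atom(c(0, 1, 0), N[1, ], CA[1, ], IDEAL$b_ca_c,
                       IDEAL$a_n_ca_c, phi[1])
  for (i in seq_len(L - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], IDEAL$b_c_n,
                             IDEAL$a_ca_c_n, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], IDEAL$b_n_ca,
                              IDEAL$a_c_n_ca, IDEAL$omega_trans)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ],
                             IDEAL$b_ca_c, IDEAL$a_n_ca_c, phi[i + 1])
  }
  for (i in seq_len(L)) {
    # carbonyl O: anti to the next N about the CA-C axis
    psi_i <- if (i < L) psi[i] else if (!is.na(psi[L])) psi[L] else 0
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], IDEAL$b_c_o,
                         IDEAL$a_ca_c_o, psi_i + pi)
    CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ], IDEAL$b_ca_cb,
                          IDEAL$a_n_ca_cb, IDEAL$t_c_n_ca_cb)
  }
  fold_model(sequence, N = N, CA = CA, C = C, O = O, CB = CB)
}

# phi/psi (radians) of a model; NA at undefined termini
backbone_torsions <- function(m) {
  L <- m$length
  phi <- psi <- rep(NA_real_, L)
  N <- m$xyz$N; CA <- m$xyz$CA; C <- m$xyz$C
  if (L >= 2) {
    phi[2:L] <- dihedral(C[1:(L - 1), , drop = FALSE],
                         N[2:L, , drop = FALSE],
                         CA[2:L, , drop = FALSE],
                         C[2:L, , drop = FALSE])
    psi[1:(L - 1)] <- dihedral(N[1:(L - 1), , drop = FALSE],
                               CA[1:(L - 1), , drop = FALSE],
                               C[1:(L - 1), , drop = FALSE],
                               N[2:L, , drop = FALSE])
  }
  list(phi = phi, psi = psi)
}

# rebuild N/C/O/CB around a bare CA trace by local-frame heuristics; the
# stiff bonded-geometry terms of the refiner idealize the result.
backbone_from_ca_trace <- function(ca, sequence) {
  L <- nrow(ca)
  prev_u <- rbind(ca[1, ] - ca[2, ], ca[-L, , drop = FALSE] -
                    ca[-1, , drop = FALSE])
  next_u <- rbind(ca[-1, , drop = FALSE] - ca[-L, , drop = FALSE],
                  ca[L, ] - ca[L - 1, ])
  prev_u <- vunit(prev_u); next_u <- vunit(next_u)
  perp <- vcross(prev_u, next_u)
  deg <- vnorm(perp) < 1e-6          # collinear neighbours: pick any normal
  if (any(deg)) {
    alt <- matrix(rep(c(0, 0, 1), each = L), L, 3)
    perp[deg, ] <- vcross(prev_u[deg, , drop = FALSE],
                          alt[deg, , drop = FALSE])
  }
  perp <- vunit(perp)
  N <- ca + IDEAL$b_n_ca * vunit(prev_u + 0.5 * perp)
  C <- ca + IDEAL$b_ca_c * vunit(next_u + 0.5 * perp)
  O <- C + IDEAL$b_c_o * vunit(vunit(C - ca) - next_u + perp)
  CB <- ca + IDEAL$b_ca_cb * vunit(-(vunit(N - ca) + vunit(C - ca)) +
                                     1.2 * vcross(vunit(N - ca),
                                                  vunit(C - ca)))
  fold_model(sequence, N = N, CA = ca, C = C, O = O, CB = CB)
}
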