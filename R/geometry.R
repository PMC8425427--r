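# Small geometry helpers: internal-coordinate chain building and rotations.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D given positions of A, B, C, the C-D bond length, the B-C-D
# bond angle (degrees) and the A-B-C-D torsion (degrees). Standard NeRF
# construction used to build ideal backbones.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + cbind(bc, m, n) %*% d2
}

# Rotation matrix for a rotation of `theta_deg` degrees about unit axis u.
rotation_about_axis <- function(u, theta_deg) {
  u <- u / sqrt(sum(u^2))
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# Near-uniform points on the upper hemisphere (z >= 0) by a Fibonacci
# lattice; used as the C2-axis sample.
fibonacci_hemisphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- i / n                      # uniform in [0, 1)
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Ideal backbone trace (N, CA, C, O per residue) from phi/psi angles.
# Returns a list of per-residue 4x3 coordinate matrices.
build_backbone <- function(n_res, phi = -57, psi = -47, omega = 180) {
  stopifnot(n_res >= 2)
  b_n_ca <- 1.458; b_ca_c <- 1.525; b_c_n <- 1.329; b_c_o <- 1.231
  a_n_ca_c <- 111.2; a_ca_c_n <- 116.2; a_c_n_ca <- 121.7; a_ca_c_o <- 120.5
  res <- vector("list", n_res)
  N <- c(0, 0, 0)
  CA <- c(b_n_ca, 0, 0)
  C <- CA + c(-cos(a_n_ca_c * pi / 180), sin(a_n_ca_c * pi / 180), 0) * b_ca_c
  for (i in seq_len(n_res)) {
    if (i > 1) {
      Np <- res[[i - 1]]["N", ]; CAp <- res[[i - 1]]["CA", ]
      Cp <- res[[i - 1]]["C", ]
      N <- as.numeric(place_atom(Np, CAp, Cp, b_c_n, a_ca_c_n, psi))
      CA <- as.numeric(place_atom(CAp, Cp, N, b_n_ca, a_c_n_ca, omega))
      C <- as.numeric(place_atom(Cp, N, CA, b_ca_c, a_n_ca_c, phi))
    }
    res[[i]] <- rbind(N = N, CA = CA, C = C, O = c(NA, NA, NA))
  }
  # carbonyl O: in the peptide plane, anti to the next N (or to CA for the
  # C-terminal residue)
  for (i in seq_len(n_res)) {
    Ni <- res[[i]]["N", ]; CAi <- res[[i]]["CA", ]; Ci <- res[[i]]["C", ]
    ref <- if (i < n_res) res[[i + 1]]["N", ] else Ni
    O <- as.numeric(place_atom(ref, CAi, Ci, b_c_o, a_ca_c_o, 180))
    res[[i]]["O", ] <- O
  }
  res
}
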