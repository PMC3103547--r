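# Internal 3D geometry helpers: NeRF atom placement, torsion measurement,
# ideal backbone generation from phi/psi/omega.

DEG2RAD <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) v / vnorm(v)

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D given positions A (dihedral ref), B (angle ref), C (parent):
# |CD| = bond, angle(D,C,B) = ang, torsion(A,B,C,D) = dih. Degrees in.
place_atom <- function(A, B, C, bond, ang, dih) {
  ang <- ang * DEG2RAD
  dih <- dih * DEG2RAD
  bc <- unitv(C - B)
  n <- unitv(vcross(B - A, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Signed torsion angle A-B-C-D in degrees, in the same sign convention as
# place_atom, so measure-then-rebuild is the identity.
torsion <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  -atan2(sum(m1 * n2), sum(n1 * n2)) / DEG2RAD
}

# Rotate points (n x 3) about the axis through p0 along (unit) u by theta deg.
rotate_about_axis <- function(pts, p0, u, theta) {
  th <- theta * DEG2RAD
  u <- unitv(u)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(pts, 2, p0) %*% t(R), 2, p0, `+`)
}

# Ideal peptide geometry (A / degrees).
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.0, ang_ca_c_n = 117.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.5)

# Build backbone N/CA/C/O coordinates for n residues from phi/psi (and omega,
# default trans) torsions. Returns a list of n lists with named 3-vectors.
build_backbone <- function(phi, psi, omega = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  if (is.null(omega)) omega <- rep(180, n)
  g <- BB_GEOM
  res <- vector("list", n)
  # seed first residue in a canonical frame
  N1 <- c(0, 0, 0)
  CA1 <- c(g$n_ca, 0, 0)
  C1 <- place_atom(c(-1, 1, 0), N1, CA1, g$ca_c, g$ang_n_ca_c, 60)
  res[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n - 1)) {
    Np <- res[[i]]$N; CAp <- res[[i]]$CA; Cp <- res[[i]]$C
    Ni <- place_atom(Np, CAp, Cp, g$c_n, g$ang_ca_c_n, psi[i])
    CAi <- place_atom(CAp, Cp, Ni, g$n_ca, g$ang_c_n_ca, omega[i])
    Ci <- place_atom(Cp, Ni, CAi, g$ca_c, g$ang_n_ca_c, phi[i + 1])
    res[[i + 1]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  # carbonyl O: anti to the following N about the CA-C axis, i.e. at psi+180
  for (i in seq_len(n)) {
    res[[i]]$O <- place_atom(res[[i]]$N, res[[i]]$CA, res[[i]]$C, g$c_o,
                             g$ang_ca_c_o, psi[i] + 180)
  }
  res
}

# Build side-chain heavy atoms for residue `aa` given backbone coordinates
# (named list with N, CA, C) and chi angles. Returns a named list of
# 3-vectors in build order, plus elements attribute.
build_sidechain <- function(aa, bb, chi = numeric(0)) {
  topo <- SIDECHAIN_TOPOLOGY[[aa]]
  if (is.null(topo)) stop("unknown residue type: ", aa)
  pos <- list(N = bb$N, CA = bb$CA, C = bb$C)
  out <- list()
  els <- character(0)
  for (row in topo) {
    dih <- if (is.na(row$chi)) row$dih else {
      if (length(chi) < row$chi || is.na(chi[row$chi]))
        stop(aa, " needs chi", row$chi, " but it was not supplied")
      chi[row$chi] + row$dih
    }
    p <- place_atom(pos[[row$dref]], pos[[row$aref]], pos[[row$parent]],
                    row$b, row$ang, dih)
    pos[[row$name]] <- p
    out[[row$name]] <- p
    els <- c(els, row$el)
  }
  attr(out, "elements") <- els
  out
}
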