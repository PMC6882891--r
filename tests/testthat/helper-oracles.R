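# Independent numerical oracles used by the test suite. These deliberately
# take different routes than the package implementation:
#  - fd_tes_oracle: axisymmetric finite-volume discretization of
#    div(sigma grad V) = 0 with Neumann cap sources (vs. Legendre series)
#  - sarvas_quadrature_oracle: Geselowitz surface integral with a
#    spherical-harmonic surface potential (vs. closed-form dipole field)

# Finite-volume solver for an antipodal electrode pair (anode at +z,
# cathode at -z) with spherical-cap current patches of half-angle
# `cap_angle`, on a layered sphere. Returns cell centers (r, theta) and
# potentials, plus an interpolator onto arbitrary (r, theta) points.
fd_tes_oracle <- function(head, current = 5e-4, cap_angle = 0.26,
                          cells_per_m = 1250, min_cells = 4L, ntheta = 360L) {
  radii <- head$shell_radii
  sig_shell <- head$shell_conductivities
  rb <- 0
  cell_sigma_shell <- integer(0)
  lower <- 0
  for (s in seq_along(radii)) {
    nc <- max(min_cells, ceiling((radii[s] - lower) * cells_per_m))
    rb <- c(rb, seq(lower, radii[s], length.out = nc + 1)[-1])
    cell_sigma_shell <- c(cell_sigma_shell, rep(s, nc))
    lower <- radii[s]
  }
  nr <- length(rb) - 1L
  rc <- (rb[-1] + rb[-length(rb)]) / 2
  sig <- sig_shell[cell_sigma_shell]
  tb <- seq(0, pi, length.out = ntheta + 1L)
  tc <- (tb[-1] + tb[-length(tb)]) / 2
  idx <- function(i, j) i + (j - 1L) * nr
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(a, b, g) {
    ii <<- c(ii, a, b, a, b); jj <<- c(jj, a, b, b, a)
    vv <<- c(vv, g, g, -g, -g)
  }
  # radial conductances
  for (i in seq_len(nr - 1L)) {
    s_face <- rb[i + 1L]
    d1 <- s_face - rc[i]; d2 <- rc[i + 1L] - s_face
    omega <- 2 * pi * (cos(tb[-length(tb)]) - cos(tb[-1]))
    g <- s_face^2 * omega / (d1 / sig[i] + d2 / sig[i + 1L])
    add(idx(i, seq_len(ntheta)), idx(i + 1L, seq_len(ntheta)), g)
  }
  # angular conductances
  for (j in seq_len(ntheta - 1L)) {
    tf <- tb[j + 1L]
    dth <- tc[j + 1L] - tc[j]
    g <- sig * pi * sin(tf) * (rb[-1]^2 - rb[-length(rb)]^2) / (rc * dth)
    add(idx(seq_len(nr), j), idx(seq_len(nr), j + 1L), g)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nr * ntheta, nr * ntheta))
  b <- numeric(nr * ntheta)
  cap_overlap <- function(lo, hi) {
    l <- pmax(tb[-length(tb)], lo); h <- pmin(tb[-1], hi)
    ifelse(h > l, 2 * pi * (cos(l) - cos(h)), 0)
  }
  om_cap <- 2 * pi * (1 - cos(cap_angle))
  b[idx(nr, seq_len(ntheta))] <- b[idx(nr, seq_len(ntheta))] +
    current * cap_overlap(0, cap_angle) / om_cap -
    current * cap_overlap(pi - cap_angle, pi) / om_cap
  # gauge: pin the first cell
  A[1, ] <- 0; A[1, 1] <- 1; b[1] <- 0
  V <- as.vector(Matrix::solve(A, b))
  interp <- function(r, theta) {
    fi <- findInterval(r, rc, all.inside = TRUE)
    fj <- findInterval(theta, tc, all.inside = TRUE)
    wr <- pmin(1, pmax(0, (r - rc[fi]) / (rc[fi + 1L] - rc[fi])))
    wt <- pmin(1, pmax(0, (theta - tc[fj]) / (tc[fj + 1L] - tc[fj])))
    v00 <- V[idx(fi, fj)]; v10 <- V[idx(fi + 1L, fj)]
    v01 <- V[idx(fi, fj + 1L)]; v11 <- V[idx(fi + 1L, fj + 1L)]
    (1 - wr) * (1 - wt) * v00 + wr * (1 - wt) * v10 +
      (1 - wr) * wt * v01 + wr * wt * v11
  }
  list(rc = rc, tc = tc, V = V, interp = interp)
}

# Geselowitz surface-integral oracle for the external magnetic field of a
# current dipole q at position r0 inside a homogeneous conducting sphere
# of radius R (the external field of any spherically symmetric conductor
# equals the homogeneous case). Surface potential is obtained by
# correcting the infinite-medium dipole potential with an interior
# harmonic series fitted to the insulating Neumann boundary condition.
sarvas_quadrature_oracle <- function(r0, q, rs, R, sigma = 0.33,
                                     lmax = 40L, nth = 120L, nph = 240L) {
  gl <- pracma::gaussLegendre(nth, -1, 1)
  u <- gl$x; wu <- gl$w
  phi <- (seq_len(nph) - 0.5) * 2 * pi / nph
  wphi <- 2 * pi / nph
  st <- sqrt(1 - u^2)
  X <- R * outer(st, cos(phi)); Y <- R * outer(st, sin(phi)); Z <- R * matrix(u, nth, nph)
  pts <- cbind(as.vector(X), as.vector(Y), as.vector(Z))
  wq <- as.vector(outer(wu, rep(wphi, nph))) * R^2       # dS weights
  d <- sweep(pts, 2, r0)
  dn <- sqrt(rowSums(d^2))
  qd <- as.vector(d %*% q)
  v_inf <- qd / (4 * pi * sigma * dn^3)
  # radial derivative of v_inf on the surface
  grad_v <- (matrix(q, nrow(pts), 3, byrow = TRUE) / dn^3 - 3 * qd * d / dn^5) /
    (4 * pi * sigma)
  rhat <- pts / R
  g <- -rowSums(grad_v * rhat)          # required dV_c/dr at R
  # project g on unnormalized associated Legendre x cos/sin(m phi) basis
  v_c <- numeric(nrow(pts))
  cth <- rep(u, nph)
  for (l in 1:lmax) {
    P <- pracma::legendre(l, u)          # (l+1) x nth, rows m = 0..l
    for (m in 0:l) {
      Pm <- rep(P[m + 1, ], nph)
      nrm <- 2 * pi / (if (m == 0) 1 else 2) * 2 / (2 * l + 1) *
        exp(lgamma(l + m + 1) - lgamma(l - m + 1))
      for (trig in if (m == 0) "c" else c("c", "s")) {
        ang <- if (trig == "c") cos(m * rep(phi, each = nth)) else sin(m * rep(phi, each = nth))
        basis <- Pm * ang
        coef <- sum(wq * g * basis) / (nrm * R^2)   # <g, Y>/<Y, Y> on unit sphere
        v_c <- v_c + coef / (l * R^(l - 1)) * R^l * basis
      }
    }
  }
  v_surf <- v_inf + v_c
  # Geselowitz: B = B_primary - mu0 sigma/4pi * surface integral
  mu0_4pi <- 1e-7
  ds <- matrix(rs, nrow(pts), 3, byrow = TRUE) - pts
  dsn <- sqrt(rowSums(ds^2))
  kern <- cbind(rhat[, 2] * ds[, 3] - rhat[, 3] * ds[, 2],
                rhat[, 3] * ds[, 1] - rhat[, 1] * ds[, 3],
                rhat[, 1] * ds[, 2] - rhat[, 2] * ds[, 1]) / dsn^3
  b_vol <- -mu0_4pi * sigma * colSums(wq * v_surf * kern)
  dp <- rs - r0
  dpn <- sqrt(sum(dp^2))
  b_prim <- mu0_4pi * c(q[2] * dp[3] - q[3] * dp[2],
                        q[3] * dp[1] - q[1] * dp[3],
                        q[1] * dp[2] - q[2] * dp[1]) / dpn^3
  b_prim + b_vol
}
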