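#' Concentric-shell spherical head model
#'
#' Constructs an analytic volume-conductor model of the head as a set of
#' concentric spherical shells (innermost = brain analog, outermost = scalp),
#' each with its own isotropic conductivity, plus two embedded spherical
#' "eyeball" regions used by the peripheral (non-brain) control analysis.
#'
#' The default geometry is a 4-shell head (brain, CSF, skull, skin) with
#' standard literature conductivities and a 9 cm scalp radius. Coordinates
#' are head-centered Cartesian RAS (x right, y anterior, z superior), in
#' meters.
#'
#' @param shell_radii Strictly increasing outer radii of the shells (m).
#' @param shell_conductivities One positive conductivity per shell (S/m).
#' @param center Head center (3-vector, m).
#' @param eye_centers 2 x 3 matrix of eye-ball centers (m, relative to
#'   `center`). Both eye balls must lie entirely inside the scalp sphere.
#' @param eye_radius Eye-ball radius (m).
#' @return An object of class `head_model`.
#' @examples
#' h <- head_model()
#' h$shell_radii
#' @export
head_model <- function(shell_radii = c(0.080, 0.082, 0.087, 0.090),
                       shell_conductivities = c(0.33, 1.79, 0.01, 0.43),
                       center = c(0, 0, 0),
                       eye_centers = rbind(c(-0.028, 0.070, -0.014),
                                           c( 0.028, 0.070, -0.014)),
                       eye_radius = 0.012) {
  shell_radii <- as.numeric(shell_radii)
  shell_conductivities <- as.numeric(shell_conductivities)
  if (length(shell_radii) != length(shell_conductivities))
    stop("one conductivity per shell is required")
  if (any(diff(shell_radii) <= 0) || any(shell_radii <= 0))
    stop("shell radii must be positive and strictly increasing")
  if (any(shell_conductivities <= 0))
    stop("shell conductivities must be positive")
  eye_centers <- matrix(as.numeric(eye_centers), ncol = 3)
  R <- max(shell_radii)
  if (any(sqrt(rowSums(eye_centers^2)) + eye_radius > R))
    stop("eye regions must lie entirely within the scalp shell volume")
  structure(list(center = as.numeric(center),
                 shell_radii = shell_radii,
                 shell_conductivities = shell_conductivities,
                 eye_centers = eye_centers,
                 eye_radius = eye_radius),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat("<head_model> ", length(x$shell_radii), " shells, scalp radius ",
      max(x$shell_radii), " m\n", sep = "")
  cat("  radii (m):        ", paste(signif(x$shell_radii, 4), collapse = ", "), "\n")
  cat("  conductivity (S/m):", paste(signif(x$shell_conductivities, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Stimulation electrode pair
#'
#' An anode/cathode pair of point-like current electrodes on the scalp
#' surface. Positions are given as directions from the head center and are
#' scaled onto the outer shell. Sign convention: `current` amperes are
#' injected at the anode and withdrawn at the cathode.
#'
#' The default montage is the Cz--Oz analog (vertex anode, occipital
#' cathode) at 0.5 mA, i.e. 1 mA peak-to-peak sinusoidal stimulation.
#'
#' @param anode,cathode 3-vectors giving electrode directions from the head
#'   center (any norm; scaled to the scalp radius).
#' @param current Injected current (A); anode = `+current`.
#' @param head A [head_model()] defining the scalp radius.
#' @return Object of class `electrode_pair` with positions on the scalp.
#' @export
electrode_pair <- function(anode = c(0, 0, 1), cathode = c(0, -1, 0),
                           current = 5e-4, head = head_model()) {
  R <- max(head$shell_radii)
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n == 0) stop("electrode direction must be non-zero")
    v / n
  }
  if (!is.finite(current)) stop("current must be finite")
  structure(list(anode_pos = unit(as.numeric(anode)) * R,
                 cathode_pos = unit(as.numeric(cathode)) * R,
                 current = current),
            class = "electrode_pair")
}

#' Regular voxel grid with compartment labels
#'
#' Builds a regular, head-centered voxel grid covering the conductor and
#' labels every voxel center by shell membership
#' (`brain | csf | skull | skin | outside`), with the eye-ball regions
#' overriding the shell label (`eye`). Voxel centers are placed at
#' `origin + (index - 1) * spacing` on each axis; the default origin is
#' chosen symmetric about the head center so that no center falls exactly
#' on it.
#'
#' @param head A [head_model()].
#' @param spacing Voxel edge length (m).
#' @param dims Optional integer triple; defaults to the smallest even count
#'   covering the scalp sphere.
#' @return Object of class `voxel_grid` with fields `origin`, `spacing`,
#'   `dims`, `labels` (character vector, column-major voxel order) and
#'   `coords` (n x 3 matrix of voxel centers).
#' @export
voxel_grid <- function(head, spacing = 0.01, dims = NULL) {
  if (spacing <= 0) stop("spacing must be positive")
  R <- max(head$shell_radii)
  if (is.null(dims)) {
    n <- 2L * as.integer(ceiling(R / spacing))
    dims <- rep(n, 3L)
  }
  dims <- as.integer(dims)
  origin <- head$center - (dims / 2 - 0.5) * spacing
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 1L) * spacing)
  coords <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                                  KEEP.OUT.ATTRS = FALSE))
  colnames(coords) <- c("x", "y", "z")
  labels <- label_compartments(head, coords)
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 labels = labels, coords = coords),
            class = "voxel_grid")
}

#' Label points by head compartment
#'
#' @param head A [head_model()].
#' @param points n x 3 matrix of positions (m).
#' @return Character vector: `brain`, `csf`, `skull`, `skin`, `eye` or
#'   `outside`. Eye membership overrides the shell label.
#' @export
label_compartments <- function(head, points) {
  points <- rbind(points)
  rel <- sweep(points, 2, head$center)
  r <- sqrt(rowSums(rel^2))
  nm <- c("brain", "csf", "skull", "skin")[seq_along(head$shell_radii)]
  if (length(head$shell_radii) > 4)
    nm <- c(nm, paste0("shell", 5:length(head$shell_radii)))
  idx <- findInterval(r, head$shell_radii, left.open = TRUE) + 1L
  lab <- ifelse(idx > length(head$shell_radii), "outside", nm[idx])
  for (e in seq_len(nrow(head$eye_centers))) {
    d <- sweep(rel, 2, head$eye_centers[e, ])
    lab[rowSums(d^2) <= head$eye_radius^2] <- "eye"
  }
  lab
}

#' Synthetic magnetometer helmet array
#'
#' Places `n` magnetometers on a helmet-shaped spherical cap outside the
#' scalp using a Fibonacci lattice, with radial (surface-normal)
#' orientations. The default emulates a whole-head MEG helmet at 11 cm
#' radius covering the upper ~70% of the sphere.
#'
#' @param n Number of sensors.
#' @param radius Helmet radius (m); must exceed the scalp radius.
#' @param zmin Lowest sensor height as a fraction of the radius.
#' @param head A [head_model()] (for the scalp-radius check and centering).
#' @return Object of class `sensor_array` with `positions` (n x 3) and
#'   `orientations` (n x 3, unit rows).
#' @export
sensor_array <- function(n = 64, radius = 0.11, zmin = -0.45,
                         head = head_model()) {
  if (radius <= max(head$shell_radii))
    stop("sensors must lie strictly outside the scalp")
  i <- seq_len(n) - 0.5
  z <- zmin + (1 - zmin) * (i / n)        # fractions of radius in [zmin, 1)
  phi <- pi * (1 + sqrt(5)) * i
  s <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(s * cos(phi), s * sin(phi), z)
  pos <- sweep(dirs * radius, 2, head$center, "+")
  structure(list(positions = pos, orientations = dirs),
            class = "sensor_array")
}

# ---------------------------------------------------------------------------
# Legendre machinery (vectorized recurrences; needed to high degree L)

# P_l(x) and P_l'(x) for l = 1..L, returned as length(x) x L matrices.
legendre_table <- function(L, x) {
  n <- length(x)
  P <- matrix(0, n, L)
  dP <- matrix(0, n, L)
  p_prev <- rep(1, n)   # P_0
  p_cur <- x            # P_1
  d_prev <- rep(0, n)   # P_0'
  d_cur <- rep(1, n)    # P_1'
  P[, 1] <- p_cur
  dP[, 1] <- d_cur
  if (L >= 2) {
    for (l in 1:(L - 1)) {
      p_next <- ((2 * l + 1) * x * p_cur - l * p_prev) / (l + 1)
      d_next <- d_prev + (2 * l + 1) * p_cur   # P'_{l+1} = P'_{l-1} + (2l+1) P_l
      P[, l + 1] <- p_next
      dP[, l + 1] <- d_next
      p_prev <- p_cur; p_cur <- p_next
      d_prev <- d_cur; d_cur <- d_next
    }
  }
  list(P = P, dP = dP)
}

# Spherical-cap smoothing weights w_l for a uniform current patch of
# half-angle `cap_angle` (rad); w_l -> 1 as the cap shrinks to a point.
cap_weights <- function(L, cap_angle) {
  if (is.null(cap_angle) || cap_angle <= 0) return(rep(1, L))
  c0 <- cos(cap_angle)
  tab <- legendre_table(L + 1, c0)$P        # P_1..P_{L+1}(c0)
  Pl <- c(1, tab[1, ])                      # P_0..P_{L+1}
  l <- seq_len(L)
  (Pl[l] - Pl[l + 2]) / ((2 * l + 1) * (1 - c0))
}

# Per-shell series coefficients for a unit point-current source on the
# outer surface of the layered sphere. Radii are normalized by the scalp
# radius; returns a (nshell x L) pair of matrices so that, with
# rho = r / R and u = cos(angle to the electrode),
#   V(r, u) = I * sum_l w_l * (a[s,l] rho^l + b[s,l] rho^-(l+1)) P_l(u).
shell_series_coeffs <- function(head, L) {
  R <- max(head$shell_radii)
  rho <- head$shell_radii / R
  sig <- head$shell_conductivities
  N <- length(sig)
  a <- matrix(0, N, L)
  b <- matrix(0, N, L)
  for (l in seq_len(L)) {
    av <- numeric(N); bv <- numeric(N)
    av[1] <- 1
    if (N >= 2) {
      for (j in 1:(N - 1)) {
        x <- rho[j]
        V <- av[j] * x^l + bv[j] * x^(-(l + 1))
        Fj <- sig[j] * (l * av[j] * x^(l - 1) - (l + 1) * bv[j] * x^(-(l + 2)))
        # closed-form 2x2 continuity solve (determinant -sigma (2l+1)/x^2,
        # stable at arbitrary order where the naive solve is singular)
        s2 <- sig[j + 1]
        av[j + 1] <- ((l + 1) * x^(-l) * V + x^(1 - l) * Fj / s2) / (2 * l + 1)
        bv[j + 1] <- (l * x^(l + 1) * V - x^(l + 2) * Fj / s2) / (2 * l + 1)
      }
    }
    scale <- ((2 * l + 1) / (4 * pi * R)) /
      (sig[N] * (l * av[N] - (l + 1) * bv[N]))
    a[, l] <- av * scale
    b[, l] <- bv * scale
  }
  list(a = a, b = b)
}

# Series evaluation shared by tes_potential / tes_efield.
# Returns list(V, E) where E is n x 3 (E may be NULL when want_field=FALSE).
tes_series_eval <- function(head, pair, points, L, cap_angle, want_field,
                            warn_tol = 1e-3) {
  points <- rbind(points)
  R <- max(head$shell_radii)
  rel <- sweep(points, 2, head$center)
  r <- sqrt(rowSums(rel^2))
  if (any(r > R * (1 + 1e-12)))
    stop("all evaluation points must lie inside the conductor")
  shell <- pmin(findInterval(r, head$shell_radii, left.open = TRUE) + 1L,
                length(head$shell_radii))
  co <- shell_series_coeffs(head, L)
  w <- cap_weights(L, cap_angle)
  n <- nrow(points)
  rho <- r / R
  eps <- 1e-12
  rho_safe <- pmax(rho, eps)
  lseq <- seq_len(L)
  # radial profiles c_l(r) and c_l'(r) per point (n x L)
  log_rho <- log(rho_safe)
  pow_pos <- exp(outer(log_rho, lseq))            # rho^l
  pow_neg <- exp(outer(log_rho, -(lseq + 1)))     # rho^-(l+1)
  pow_neg[shell == 1L, ] <- 0                     # b == 0 in innermost shell anyway
  A <- co$a[shell, , drop = FALSE]
  B <- co$b[shell, , drop = FALSE]
  Cl <- A * pow_pos + B * pow_neg                 # n x L
  V <- numeric(n); E <- NULL
  if (want_field) {
    dCl <- (A * sweep(pow_pos, 2, lseq, "*") / rho_safe -
            B * sweep(pow_neg, 2, lseq + 1, "*") / rho_safe) / R
    E <- matrix(0, n, 3)
  }
  tail_num <- 0; tail_den <- 0
  for (side in c(1, -1)) {
    epos <- if (side > 0) pair$anode_pos else pair$cathode_pos
    ehat <- (epos - head$center) / R
    u <- as.vector(rel %*% ehat) / pmax(r, eps)
    u <- pmin(1, pmax(-1, u))
    leg <- legendre_table(L, u)
    terms <- Cl * leg$P * rep(w, each = n)        # n x L
    V <- V + side * rowSums(terms)
    tail_num <- tail_num + mean(abs(terms[, L]))
    tail_den <- tail_den + mean(abs(rowSums(terms))) + 1e-300
    if (want_field) {
      rad <- rowSums(dCl * leg$P * rep(w, each = n))       # dV/dr
      tan_c <- rowSums(Cl * leg$dP * rep(w, each = n)) / pmax(r, eps)
      rhat <- rel / pmax(r, eps)
      # E = -(dV/dr) rhat + tan_c * (u rhat - ehat)
      E <- E + side * (-rad * rhat +
                       tan_c * (u * rhat - matrix(ehat, n, 3, byrow = TRUE)))
    }
  }
  conv_ratio <- tail_num / tail_den
  if (is.finite(conv_ratio) && conv_ratio > warn_tol)
    warning(sprintf(
      "series truncation order L = %d may be insufficient (tail ratio %.2g)",
      L, conv_ratio))
  V <- V * pair$current
  if (want_field) E <- E * pair$current
  list(V = V, E = E, convergence_ratio = conv_ratio)
}

#' Quasi-static tES potential on a layered sphere
#'
#' Evaluates the electric potential generated by an anode/cathode pair of
#' surface current electrodes on a concentric-shell spherical conductor,
#' using a Legendre-series expansion with per-shell transfer coefficients
#' and superposition of the two electrodes. An optional spherical-cap
#' kernel spreads each point electrode over a patch of the given
#' half-angle, approximating rectangular rubber electrodes.
#'
#' @param head A [head_model()].
#' @param pair An [electrode_pair()].
#' @param points n x 3 matrix of evaluation points, inside the conductor.
#' @param L Series truncation order. A warning is emitted when the series
#'   tail is not negligible at this order.
#' @param cap_angle Electrode patch half-angle (rad), or `NULL` for point
#'   electrodes.
#' @return Numeric vector of potentials (V), with attribute
#'   `convergence_ratio`.
#' @export
tes_potential <- function(head, pair, points, L = 60, cap_angle = 0.26) {
  out <- tes_series_eval(head, pair, points, L, cap_angle, want_field = FALSE)
  structure(out$V, convergence_ratio = out$convergence_ratio)
}

#' tES electric field on a voxel grid
#'
#' Evaluates `E = -grad V` analytically (term-wise series differentiation)
#' at every voxel center inside the conductor, and returns per-voxel field
#' vectors and magnitudes. Voxels labeled `outside` carry a zero field.
#'
#' @inheritParams tes_potential
#' @param grid A [voxel_grid()] covering the conductor.
#' @return Object of class `efield_map`: `grid`, `vectors` (n x 3, V/m),
#'   `magnitude` (length-n, V/m).
#' @export
tes_efield <- function(head, pair, grid, L = 60, cap_angle = 0.26) {
  inside <- grid$labels != "outside"
  vecs <- matrix(0, nrow(grid$coords), 3)
  if (any(inside)) {
    out <- tes_series_eval(head, pair, grid$coords[inside, , drop = FALSE],
                           L, cap_angle, want_field = TRUE)
    vecs[inside, ] <- out$E
  }
  structure(list(grid = grid, vectors = vecs,
                 magnitude = sqrt(rowSums(vecs^2))),
            class = "efield_map")
}

#' Single-sphere closed-form tES potential
#'
#' Closed-form potential of a point current pair on a homogeneous sphere
#' (used as a degenerate-limit identity for the layered solver).
#'
#' @inheritParams tes_potential
#' @param sigma Conductivity of the homogeneous sphere (S/m).
#' @return Potential vector (V).
#' @export
tes_potential_homogeneous <- function(head, pair, points, sigma) {
  points <- rbind(points)
  R <- max(head$shell_radii)
  rel <- sweep(points, 2, head$center)
  r <- sqrt(rowSums(rel^2))
  t <- r / R
  V <- numeric(nrow(points))
  for (side in c(1, -1)) {
    epos <- if (side > 0) pair$anode_pos else pair$cathode_pos
    ehat <- (epos - head$center) / R
    u <- ifelse(r > 0, as.vector(rel %*% ehat) / pmax(r, 1e-300), 1)
    s <- sqrt(pmax(1 - 2 * t * u + t^2, 1e-300))
    V <- V + side * (2 / s - 2 + log(2 / (1 - t * u + s)))
  }
  V * pair$current / (4 * pi * sigma * R)
}

# ---------------------------------------------------------------------------
# MEG forward model

#' MEG leadfield in a spherical conductor
#'
#' Magnetic field of a current dipole inside a spherically symmetric
#' conductor, evaluated with the closed-form solution for the external
#' field and projected onto each magnetometer's orientation. Columns are
#' the fields of unit dipoles along the three Cartesian axes at each brain
#' voxel; purely radial dipoles are magnetically silent, so the radial
#' combination of each voxel's columns is numerically null.
#'
#' @param head A [head_model()] (only the center is used; the external
#'   field of a spherically symmetric conductor is independent of the
#'   conductivity profile).
#' @param grid A [voxel_grid()]; the leadfield is computed for voxels
#'   labeled `brain`.
#' @param sensors A [sensor_array()]; all sensors must lie strictly outside
#'   the scalp.
#' @return Object of class `leadfield`: `matrix` (n_sensors x 3*n_vox,
#'   T per A m), `vox_idx` (grid indices of the brain voxels), `grid`,
#'   `sensors`.
#' @export
meg_leadfield <- function(head, grid, sensors) {
  R <- max(head$shell_radii)
  spos <- sweep(sensors$positions, 2, head$center)
  if (any(sqrt(rowSums(spos^2)) <= R))
    stop("all sensors must lie strictly outside the conductor")
  vox_idx <- which(grid$labels == "brain")
  r0 <- sweep(grid$coords[vox_idx, , drop = FALSE], 2, head$center)
  nv <- nrow(r0)
  ns <- nrow(spos)
  Lmat <- matrix(0, ns, 3L * nv)
  for (s in seq_len(ns)) {
    B <- dipole_field_sphere(r0, spos[s, ])
    # B is nv x 3 x 3 (dipole axis, field component); project on orientation
    o <- sensors$orientations[s, ]
    Lmat[s, ] <- as.vector(t(B[, , 1] * o[1] + B[, , 2] * o[2] + B[, , 3] * o[3]))
  }
  structure(list(matrix = Lmat, vox_idx = vox_idx, grid = grid,
                 sensors = sensors),
            class = "leadfield")
}

# Closed-form external magnetic field of unit current dipoles along x/y/z
# at positions r0 (nv x 3) inside a spherical conductor centered at the
# origin, evaluated at the single exterior point rs (3-vector).
# Returns an nv x 3 x 3 array: [voxel, dipole axis, field component].
dipole_field_sphere <- function(r0, rs) {
  mu0_4pi <- 1e-7
  nv <- nrow(r0)
  rsn <- sqrt(sum(rs^2))
  a_vec <- matrix(rs, nv, 3, byrow = TRUE) - r0
  a <- sqrt(rowSums(a_vec^2))
  r0_dot_rs <- as.vector(r0 %*% rs)
  adotr <- rsn^2 - r0_dot_rs
  Fv <- a * (rsn * a + rsn^2 - r0_dot_rs)
  c1 <- a^2 / rsn + adotr / a + 2 * a + 2 * rsn
  c2 <- a + 2 * rsn + adotr / a
  gradF <- c1 * matrix(rs, nv, 3, byrow = TRUE) - c2 * r0
  out <- array(0, c(nv, 3, 3))
  qxr0 <- list(cbind(0, -r0[, 3], r0[, 2]),     # e_x x r0
               cbind(r0[, 3], 0, -r0[, 1]),     # e_y x r0
               cbind(-r0[, 2], r0[, 1], 0))     # e_z x r0
  for (k in 1:3) {
    qr <- qxr0[[k]]
    qr_dot_rs <- as.vector(qr %*% rs)
    out[, k, ] <- mu0_4pi / Fv^2 * (Fv * qr - qr_dot_rs * gradF)
  }
  out
}

# Leadfield columns of one dipole location (3 columns) for a set of points,
# used by the simulator for source/background dipoles without a full grid.
point_leadfield <- function(head, points, sensors) {
  pts <- rbind(points)
  spos <- sweep(sensors$positions, 2, head$center)
  rel <- sweep(pts, 2, head$center)
  ns <- nrow(spos)
  np <- nrow(pts)
  Lmat <- matrix(0, ns, 3L * np)
  for (s in seq_len(ns)) {
    B <- dipole_field_sphere(rel, spos[s, ])
    o <- sensors$orientations[s, ]
    Lmat[s, ] <- as.vector(t(B[, , 1] * o[1] + B[, , 2] * o[2] + B[, , 3] * o[3]))
  }
  Lmat
}

#' Quasi-uniform point sample of a head compartment
#'
#' Deterministic golden-angle sampling of points inside a thin shell
#' compartment (radial layers of Fibonacci spheres) or inside the
#' eye balls. Used to evaluate peripheral field strengths at adequate
#' density where a regular voxel grid would under-sample thin shells.
#'
#' @param head A [head_model()].
#' @param compartment `"skin"`, `"skull"`, `"csf"`, `"brain"` or `"eye"`.
#' @param n Approximate number of points.
#' @param n_layers Radial layers for shell compartments.
#' @return n x 3 matrix of points (m).
#' @export
compartment_points <- function(head, compartment, n = 3000, n_layers = 4) {
  fib_sphere <- function(m, rot = 0) {
    i <- seq_len(m) - 0.5
    z <- 1 - 2 * i / m
    phi <- pi * (1 + sqrt(5)) * i + rot
    s <- sqrt(pmax(0, 1 - z^2))
    cbind(s * cos(phi), s * sin(phi), z)
  }
  if (compartment == "eye") {
    ne <- nrow(head$eye_centers)
    m <- ceiling(n / ne)
    i <- seq_len(m) - 0.5
    rr <- head$eye_radius * 0.98 * (i / m)^(1 / 3)
    dirs <- fib_sphere(m)
    pts <- do.call(rbind, lapply(seq_len(ne), function(e)
      sweep(dirs * rr, 2, head$center + head$eye_centers[e, ], "+")))
    return(pts)
  }
  idx <- match(compartment, c("brain", "csf", "skull", "skin"))
  if (is.na(idx)) stop("unknown compartment: ", compartment)
  r_lo <- if (idx == 1) 0 else head$shell_radii[idx - 1]
  r_hi <- head$shell_radii[idx]
  pad <- (r_hi - r_lo) * 0.05
  layers <- seq(r_lo + pad, r_hi - pad, length.out = n_layers)
  m <- ceiling(n / n_layers)
  pts <- do.call(rbind, lapply(seq_along(layers), function(k)
    sweep(fib_sphere(m, rot = k) * layers[k], 2, head$center, "+")))
  pts
}

#' tES field magnitude at arbitrary points
#'
#' Evaluates the field magnitude at a point set (inside the conductor)
#' without building a voxel grid; used for thin-compartment sampling.
#'
#' @inheritParams tes_potential
#' @return Numeric vector of magnitudes (V/m).
#' @export
tes_efield_points <- function(head, pair, points, L = 60, cap_angle = 0.26) {
  out <- tes_series_eval(head, pair, points, L, cap_angle, want_field = TRUE)
  sqrt(rowSums(out$E^2))
}
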