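test_that("head model constructor enforces its invariants", {
  expect_error(head_model(shell_radii = c(0.09, 0.08, 0.087, 0.09)),
               "strictly increasing")
  expect_error(head_model(shell_conductivities = c(0.33, -1, 0.01, 0.43)),
               "positive")
  expect_error(head_model(eye_centers = rbind(c(0, 0.085, 0), c(0, -0.085, 0))),
               "within the scalp")
  h <- head_model()
  expect_length(h$shell_radii, 4)
  expect_true(all(diff(h$shell_radii) > 0))
})

test_that("voxel grid labels follow shell membership with eye override", {
  h <- head_model()
  g <- voxel_grid(h, spacing = 0.01)
  r <- sqrt(rowSums(g$coords^2))
  expect_true(all(g$labels[r < h$shell_radii[1] * 0.99 &
                             g$labels != "eye"] == "brain"))
  expect_true(all(g$labels[r > max(h$shell_radii) * 1.01] == "outside"))
  # a point at an eye center is labeled eye although its radius says brain/skull
  lab <- label_compartments(h, rbind(h$eye_centers[1, ]))
  expect_identical(lab, "eye")
  expect_true(any(g$labels == "eye"))
})

test_that("tES potential is linear, antisymmetric under electrode swap and zero at zero current", {
  h <- head_model()
  set.seed(1)
  pts <- matrix(rnorm(60), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(20, 0.01, 0.07)
  p0 <- electrode_pair(current = 0, head = h)
  expect_equal(as.numeric(tes_potential(h, p0, pts)), rep(0, 20))
  p1 <- electrode_pair(c(0, 0, 1), c(0, -1, 0), 5e-4, h)
  p2 <- electrode_pair(c(0, -1, 0), c(0, 0, 1), 5e-4, h)
  v1 <- tes_potential(h, p1, pts)
  v2 <- tes_potential(h, p2, pts)
  expect_equal(as.numeric(v1), -as.numeric(v2))
  p3 <- electrode_pair(c(0, 0, 1), c(0, -1, 0), 1e-3, h)
  expect_equal(2 * as.numeric(v1), as.numeric(tes_potential(h, p3, pts)))
  expect_error(tes_potential(h, p1, rbind(c(0.2, 0, 0))), "inside")
})

test_that("equal-conductivity shells reproduce the single-sphere closed form", {
  h <- head_model(shell_radii = c(0.08, 0.082, 0.087, 0.09),
                  shell_conductivities = rep(0.33, 4))
  p <- electrode_pair(c(0, 0, 1), c(0, -1, 0), 5e-4, h)
  set.seed(2)
  pts <- matrix(rnorm(150), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(50, 0.005, 0.075)
  v_series <- as.numeric(tes_potential(h, p, pts, L = 60, cap_angle = NULL))
  v_closed <- tes_potential_homogeneous(h, p, pts, 0.33)
  expect_lt(max(abs(v_series - v_closed)) / max(abs(v_closed)), 1e-6)
})

test_that("potential is continuous across shell boundaries", {
  h <- head_model()
  p <- electrode_pair(head = h)
  eps <- 1e-7
  dirs <- rbind(c(0, 0.3, 0.95), c(0.5, -0.5, 0.7), c(-0.6, 0.6, 0.5))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (rb in h$shell_radii[1:3]) {
    inner <- dirs * (rb - eps)
    outer_p <- dirs * (rb + eps)
    vi <- as.numeric(tes_potential(h, p, inner))
    vo <- as.numeric(tes_potential(h, p, outer_p))
    expect_lt(max(abs(vi - vo)) / max(abs(vi)), 1e-3)
  }
})

test_that("doubling the current doubles the field magnitude everywhere", {
  h <- head_model()
  g <- voxel_grid(h, spacing = 0.02)
  e1 <- tes_efield(h, electrode_pair(current = 5e-4, head = h), g)
  e2 <- tes_efield(h, electrode_pair(current = 1e-3, head = h), g)
  expect_equal(e2$magnitude, 2 * e1$magnitude, tolerance = 1e-12)
  expect_equal(e1$magnitude, sqrt(rowSums(e1$vectors^2)))
  expect_true(all(e1$magnitude[g$labels == "outside"] == 0))
})

test_that("injected current is conserved across the mid-plane between electrodes", {
  h <- head_model()
  pair <- electrode_pair(c(0, 0, 1), c(0, 0, -1), 5e-4, h)
  gq <- pracma::gaussLegendre(200, 0, max(h$shell_radii))
  pts <- cbind(gq$x, 0, 0)
  out <- tacsdose:::tes_series_eval(h, pair, pts, L = 60, cap_angle = 0.26,
                                    want_field = TRUE)
  sig <- h$shell_conductivities[pmin(findInterval(gq$x, h$shell_radii,
                                                  left.open = TRUE) + 1L, 4)]
  flux <- sum(gq$w * sig * out$E[, 3] * 2 * pi * gq$x)
  expect_lt(abs(abs(flux) / pair$current - 1), 0.01)
})

test_that("MEG leadfield is silent for radial dipoles and linear in moment", {
  h <- head_model()
  sens <- sensor_array(32, head = h)
  pos <- c(0.02, -0.03, 0.04)
  L3 <- tacsdose:::point_leadfield(h, pos, sens)
  rad <- pos / sqrt(sum(pos^2))
  tang <- c(-rad[2], rad[1], 0)
  tang <- tang / sqrt(sum(tang^2))
  b_rad <- as.vector(L3 %*% rad)
  b_tan <- as.vector(L3 %*% tang)
  expect_lt(max(abs(b_rad)), 1e-10 * max(abs(b_tan)))
  expect_equal(as.vector(L3 %*% rep(0, 3)), rep(0, nrow(sens$positions)))
  expect_error(meg_leadfield(h, voxel_grid(h, 0.02),
                             sensor_array(8, radius = 0.12, head = h)), NA)
  expect_error(sensor_array(8, radius = 0.05, head = h), "outside")
})

test_that("closed-form dipole field matches the Geselowitz quadrature oracle", {
  h <- head_model()
  r0 <- c(0.02, -0.03, 0.045)
  q <- c(1e-8, 2e-9, 0)
  q <- q - sum(q * r0) / sum(r0^2) * r0       # tangential moment
  for (rs in list(c(0.04, -0.06, 0.09), c(-0.08, 0.02, 0.08))) {
    b_o <- sarvas_quadrature_oracle(r0, q, rs, R = max(h$shell_radii))
    B <- tacsdose:::dipole_field_sphere(rbind(r0), rs)
    b_c <- as.vector(B[1, 1, ] * q[1] + B[1, 2, ] * q[2] + B[1, 3, ] * q[3])
    expect_lt(sqrt(sum((b_c - b_o)^2) / sum(b_o^2)), 0.02)
  }
})

test_that("compartment point samples land in their compartment", {
  h <- head_model()
  for (comp in c("brain", "skin", "eye")) {
    pts <- compartment_points(h, comp, 500)
    expect_true(all(label_compartments(h, pts) %in%
                      c(comp, "eye")))  # eye balls override shell labels
  }
  expect_error(compartment_points(h, "bone", 10), "unknown compartment")
})
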