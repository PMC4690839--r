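make_landmarks <- function(pts, prefix = "L") {
  landmark_set(pts, paste0(prefix, seq_len(nrow(pts))))
}

test_that("Horn registration recovers applied rigid transforms", {
  set.seed(42)
  S <- matrix(stats::rnorm(30, sd = 0.05), 10, 3)
  rownames(S) <- paste0("L", 1:10)

  # identical sets: identity, zero residual
  id <- horn_register(S, S)
  expect_transform_equal(id$T, diag(4), 1e-12)
  expect_lt(id$rms_mm, 1e-9)

  # known 30-degree rotation about Z plus translation
  R <- rot_z(30 * pi / 180)
  tr <- c(0.010, -0.005, 0.002)
  Tt <- sweep(S %*% t(R), 2, tr, "+")
  rownames(Tt) <- rownames(S)
  h <- horn_register(S, Tt)
  expect_lt(max(abs(tf_rot(h$T) - R)), 1e-9)
  expect_lt(max(abs(tf_origin(h$T) - tr)), 1e-9)
  expect_lt(h$rms_mm, 1e-9)   # mm

  # property: random transforms recovered over many draws
  for (seed in 1:8) {
    T0 <- random_rigid_transform(seed)
    Tt2 <- tf_apply(T0, S); rownames(Tt2) <- rownames(S)
    h2 <- horn_register(S, Tt2)
    expect_transform_equal(h2$T, T0, 1e-9)
  }
})

test_that("Horn registration rejects degenerate sets, never reflects", {
  P <- cbind(seq(0, 0.1, length.out = 5), 0, 0)
  rownames(P) <- paste0("L", 1:5)
  expect_error(horn_register(P, P), "degenerate|collinear")

  # near-planar set: still a proper rotation (det +1)
  set.seed(11)
  Q <- cbind(stats::rnorm(8, sd = 0.05), stats::rnorm(8, sd = 0.05),
             stats::rnorm(8, sd = 1e-5))
  rownames(Q) <- paste0("L", 1:8)
  T0 <- random_rigid_transform(3)
  Qt <- tf_apply(T0, Q); rownames(Qt) <- rownames(Q)
  h <- horn_register(Q, Qt)
  expect_equal(det(tf_rot(h$T)), 1, tolerance = 1e-9)
  expect_transform_equal(h$T, T0, 1e-6)

  expect_error(horn_register(P[1:2, ], P[1:2, ]), "at least 3")
})

sample_cylinder <- function(n, radius, arc_deg, half_len, seed = 1, sd = 0) {
  set.seed(seed)
  ang <- stats::runif(n, -arc_deg / 2, arc_deg / 2) * pi / 180
  z <- stats::runif(n, -half_len, half_len)
  P <- cbind(radius * sin(ang), radius * cos(ang), z)
  if (sd > 0) P <- P + matrix(stats::rnorm(3 * n, 0, sd), ncol = 3)
  P
}

test_that("cylinder fit recovers generating parameters", {
  P <- sample_cylinder(200, 0.020, 60, 0.015)
  cyl <- fit_cylinder(P)
  expect_lt(abs(cyl$radius - 0.020), 1e-6)
  axis_err <- acos(min(1, abs(sum(cyl$direction * c(0, 0, 1)))))
  expect_lt(axis_err, 1e-4)

  # 0.2 mm isotropic noise: radius within 2%
  Pn <- sample_cylinder(200, 0.020, 60, 0.015, seed = 1, sd = 2e-4)
  cyln <- fit_cylinder(Pn)
  expect_lt(abs(cyln$radius - 0.020) / 0.020, 0.02)

  # rigid motion of the cloud leaves radius and residual unchanged
  T0 <- random_rigid_transform(5)
  cylm <- fit_cylinder(tf_apply(T0, Pn))
  expect_equal(cylm$radius, cyln$radius, tolerance = 1e-6)
  expect_equal(cylm$rms_mm, cyln$rms_mm, tolerance = 1e-6)

  expect_error(fit_cylinder(cbind(stats::rnorm(50), stats::rnorm(50), 0)),
               "planar|ill-conditioned")
  expect_error(fit_cylinder(P[1:4, ]), "at least 6")
})

test_that("marker-based ankle frame follows the published recipe", {
  lat <- c(0, 0, 0.04); med <- c(0, 0, -0.04); knee <- c(0, 0.4, 0)
  fr <- ankle_frame_cga(lat, med, knee)
  expect_equal(fr$origin, c(0, 0, 0))
  expect_transform_equal(fr$axes, diag(3), 1e-12)

  # equivariance under a rigid motion of all landmarks
  T0 <- random_rigid_transform(8)
  fr2 <- ankle_frame_cga(tf_apply(T0, lat), tf_apply(T0, med), tf_apply(T0, knee))
  expect_transform_equal(fr2$axes, tf_rot(T0) %*% fr$axes, 1e-9)
  expect_equal(fr2$origin, tf_apply(T0, fr$origin), tolerance = 1e-9)

  expect_error(ankle_frame_cga(lat, lat, knee), "coincide")
  expect_error(ankle_frame_cga(lat, med, c(0, 0, 0.2)), "collinear")
})

test_that("cylinder-based ankle frame substitutes the dome axis for the malleoli", {
  cyl <- structure(list(point = c(0, 0, 0), direction = c(0, 0, 1),
                        radius = 0.02, extent = c(-0.012, 0.012)),
                   class = "cylinder3d")
  fr <- ankle_frame_mr(cyl, c(0, 0.4, 0))
  expect_transform_equal(fr$axes, diag(3), 1e-12)
  expect_equal(fr$origin, c(0, 0, 0))

  # a dome axis rotated 10 degrees in the transverse plane (about the
  # vertical axis) versus the malleolar line carries through the recipe
  # exactly; frontal-plane tilt is projected out by the orthonormalization
  R10 <- rot_y(10 * pi / 180)
  cyl_t <- structure(list(point = c(0, 0, 0), direction = as.numeric(R10 %*% c(0, 0, 1)),
                          radius = 0.02, extent = c(-0.012, 0.012)),
                     class = "cylinder3d")
  fr_mr <- ankle_frame_mr(cyl_t, c(0, 0.4, 0))
  fr_cga <- ankle_frame_cga(c(0, 0, 0.04), c(0, 0, -0.04), c(0, 0.4, 0))
  d <- frame_difference(fr_mr, fr_cga)
  expect_equal(d$angle_deg, 10, tolerance = 1e-6)
  expect_equal(d$offset_mm, 0, tolerance = 1e-9)
  # frontal-plane (about-anterior) tilt alone leaves the frame unchanged
  cyl_x <- cyl_t
  cyl_x$direction <- as.numeric(rot_x(10 * pi / 180) %*% c(0, 0, 1))
  dx <- frame_difference(ankle_frame_mr(cyl_x, c(0, 0.4, 0)), fr_cga)
  expect_lt(dx$angle_deg, 1e-6)

  cyl_d <- cyl; cyl_d$extent <- c(0.01, 0.01)
  expect_error(ankle_frame_mr(cyl_d, c(0, 0.4, 0)), "degenerate")
  expect_error(ankle_frame_mr(cyl), "knee")
})

test_that("frame difference is the relative rotation angle and origin offset", {
  f1 <- anatomical_frame(c(0, 0, 0), diag(3))
  expect_equal(frame_difference(f1, f1), list(angle_deg = 0, offset_mm = 0))
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1))) {
    f2 <- anatomical_frame(c(0.001, 0, 0), axis_angle(ax, 15 * pi / 180))
    expect_equal(frame_difference(f1, f2)$angle_deg, 15, tolerance = 1e-9)
    expect_equal(frame_difference(f1, f2)$offset_mm, 1, tolerance = 1e-9)
  }
})

test_that("generic points map through per-segment Horn transforms", {
  m <- get_template()
  gen <- model_landmark_world(m)
  hind <- which(gen$segment == "hindfoot")
  pts <- matrix(c(0.01, -0.02, 0.005, -0.03, -0.04, 0.01), 2, 3, byrow = TRUE)

  # identical landmarks: points unchanged
  res <- map_generic_points(gen, gen, pts, "hindfoot")
  expect_lt(max(abs(res$points - pts)), 1e-9)
  expect_lt(res$rms_mm[["hindfoot"]], 1e-9)

  # rigidly displaced patient: points displaced identically
  T0 <- random_rigid_transform(21)
  pat <- transform_landmarks(T0, gen)
  res2 <- map_generic_points(gen, pat, pts, "hindfoot")
  expect_lt(max(abs(res2$points - tf_apply(T0, pts))), 1e-8)
  expect_transform_equal(res2$transforms$hindfoot$T, T0, 1e-8)
})
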