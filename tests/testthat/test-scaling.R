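const_static <- function(pts, n = 20, rate = 100, labels = rownames(pts)) {
  data <- array(0, c(n, nrow(pts), 3))
  for (f in seq_len(n)) data[f, , ] <- pts
  gait_trial(marker_trajectories(data, labels, rate), kind = "static")
}

test_that("static trials average per marker over visible frames", {
  pts <- rbind(A = c(1, 2, 3), B = c(0, 0, 0))
  tr <- const_static(pts)
  s <- average_static_trial(tr)
  expect_equal(lm_point(s$points, "A"), c(1, 2, 3))

  # alternating marker averages to the midpoint
  data <- array(0, c(10, 1, 3))
  data[, 1, 3] <- rep(c(0, 2), 5)
  s2 <- average_static_trial(marker_trajectories(data, "C", 100))
  expect_equal(lm_point(s2$points, "C"), c(0, 0, 1))

  # marker visible in only 10% of frames is rejected by name
  data3 <- array(1, c(10, 2, 3))
  data3[2:10, 2, ] <- NA
  mt <- marker_trajectories(data3, c("OK", "GAPPY"), 100)
  expect_error(average_static_trial(mt), "GAPPY")
})

test_that("scale factors are patient/generic distance ratios", {
  m <- get_template()
  gen <- model_marker_world(m)
  # identical distances: all factors one
  s1 <- compute_scale_factors(gen, average_static_trial(const_static(gen$points)))
  expect_equal(unname(c(s1$pelvis, s1$femur, s1$shank)), rep(1, 5),
               tolerance = 1e-12)
  # homogeneous doubling: all factors two
  s2 <- compute_scale_factors(gen,
    average_static_trial(const_static(2 * gen$points)))
  expect_equal(unname(c(s2$pelvis, s2$femur, s2$shank)), rep(2, 5),
               tolerance = 1e-12)
})

test_that("a 0.40 m femur against a 0.432 m generic gives factor 0.9259", {
  m <- get_template()
  gen <- model_marker_world(m)
  pts <- gen$points
  # scale the knee-epicondyle markers about the greater trochanter so the
  # GT-to-mid-epicondyle distance becomes exactly 0.432, then 0.40
  gt <- pts["RGTR", ]
  mid_epi <- (pts["RKNE", ] + pts["RKNM", ]) / 2
  for (mk in c("RKNE", "RKNM"))
    pts[mk, ] <- gt + (pts[mk, ] - gt) * 0.432 / sqrt(sum((mid_epi - gt)^2))
  gen432 <- landmark_set(pts, rownames(pts))
  pts2 <- pts
  for (mk in c("RKNE", "RKNM"))
    pts2[mk, ] <- gt + (pts[mk, ] - gt) * 0.40 / 0.432
  s <- compute_scale_factors(gen432,
    average_static_trial(const_static(pts2)))
  expect_equal(s$femur, 0.40 / 0.432, tolerance = 1e-9)
  expect_equal(s$femur, 0.9259, tolerance = 1e-4)
})

test_that("scaling transforms segment geometry as specified", {
  m <- get_template()
  unit <- structure(list(pelvis = c(1, 1, 1), femur = 1, shank = 1),
                    class = "scale_factors")
  m1 <- apply_scaling(m, unit)
  expect_identical(m1$muscles, m$muscles)
  expect_identical(m1$markers, m$markers)
  expect_equal(m1$joints$hip$location, m$joints$hip$location)

  dbl <- structure(list(pelvis = c(1, 1, 1), femur = 2, shank = 1),
                   class = "scale_factors")
  m2 <- apply_scaling(m, dbl)
  expect_equal(m2$joints$knee$location, 2 * m$joints$knee$location)
  expect_equal(m2$muscles$vas_int$points[[1]]$p,
               2 * m$muscles$vas_int$points[[1]]$p)
  # non-femur geometry untouched
  expect_equal(m2$muscles$soleus$points[[1]]$p, m$muscles$soleus$points[[1]]$p)

  aniso <- structure(list(pelvis = c(1, 2, 1), femur = 1, shank = 1),
                     class = "scale_factors")
  m3 <- apply_scaling(m, aniso)
  expect_equal(m3$markers$RASI$p, m$markers$RASI$p * c(1, 2, 1))
  expect_equal(m3$joints$hip$location, m$joints$hip$location * c(1, 2, 1))
})

test_that("foot-to-MRI registration recovers the applied offset", {
  m <- get_template()
  mk <- model_marker_world(m)
  six <- mri_replica_markers()
  static <- average_static_trial(const_static(mk$points))
  mri <- mk[six]
  r0 <- register_foot_to_mri(static, mri)
  expect_transform_equal(r0$T, diag(4), 1e-9)

  T0 <- random_rigid_transform(17)
  r1 <- register_foot_to_mri(static, transform_landmarks(T0, mri))
  expect_transform_equal(r1$T, T0, 1e-9)

  expect_error(register_foot_to_mri(static, mri[1:2]), "at least 3")
})

test_that("femur rotation optimizer matches a dense grid search", {
  axis_point <- c(0, -0.42, 0)
  axis_dir <- c(0, 0, 1)
  gt <- c(-0.01, -0.02, 0.06)
  # coincident points: zero angle
  r0 <- optimize_femur_rotation(gt, gt, axis_point, axis_dir)
  expect_lt(abs(r0$angle), 1e-8)

  # known 15-degree displacement about the axis
  th_true <- 15 * pi / 180
  target <- axis_point + as.numeric(axis_angle(axis_dir, th_true) %*% (gt - axis_point))
  r1 <- optimize_femur_rotation(gt, target, axis_point, axis_dir)
  expect_equal(r1$angle, th_true, tolerance = 1e-6)

  # oracle: dense 1e-4 rad grid
  grid <- seq(-pi, pi, by = 1e-4)
  d2 <- vapply(grid, function(th) {
    p <- axis_point + as.numeric(axis_angle(axis_dir, th) %*% (gt - axis_point))
    sum((p - target)^2)
  }, numeric(1))
  expect_equal(r1$angle, grid[which.min(d2)], tolerance = 1e-4)

  expect_error(optimize_femur_rotation(axis_point + c(0, 0, 0.1), gt,
                                       axis_point, axis_dir), "on the knee axis")
})

test_that("assembling an undeformed synthetic patient returns the template", {
  tmpl <- get_template()
  hy <- assemble_patient_model(tmpl, get_identity_patient()$patient)
  for (mn in names(tmpl$muscles))
    for (k in seq_along(tmpl$muscles[[mn]]$points))
      expect_lt(max(abs(hy$muscles[[mn]]$points[[k]]$p -
                        tmpl$muscles[[mn]]$points[[k]]$p)), 1e-9)
  expect_lt(max(abs(hy$joints$ankle$location - tmpl$joints$ankle$location)), 1e-9)
  expect_lt(max(abs(hy$joints$ankle$orientation - diag(3))), 1e-9)
  for (mk in names(tmpl$markers))
    expect_lt(max(abs(hy$markers[[mk]]$p - tmpl$markers[[mk]]$p)), 1e-9)
  prov <- provenance(hy)
  expect_true(all(prov$rms_mm[grepl("register", prov$stage)] < 1e-6, na.rm = TRUE))
})

test_that("per-segment rigid deformations are recovered by their stages", {
  tmpl <- get_template()
  Ts <- list(hindfoot = make_transform(rot_y(0.05), c(0.002, 0.001, -0.003)),
             forefoot = make_transform(rot_z(-0.04), c(-0.001, 0.002, 0.001)))
  sp <- make_synthetic_patient(synthetic_foot_params(
    stature_scale = 1, mass_kg = 75, height_m = 1.75, segment_transforms = Ts))
  hy <- assemble_patient_model(tmpl, sp$patient)
  prov <- attr(hy, "provenance")
  stage_of <- function(name)
    prov[[which(vapply(prov, `[[`, character(1), "stage") == name)]]
  # each deformed segment is recovered exactly (zero residual), and its
  # transform equals the generating deformation composed with the common
  # reference-to-standing displacement (taken from the undeformed shank)
  stand <- stage_of("register_shank")$transform
  for (sn in names(Ts)) {
    st <- stage_of(paste0("register_", sn))
    expect_lt(st$rms_mm, 1e-6)
    expect_transform_equal(st$transform, Ts[[sn]] %*% stand, 1e-8)
  }
  # direct check: the hindfoot stage transform maps generic reference
  # landmarks onto the deformed patient landmarks
  gen <- model_landmark_world(tmpl)
  hind <- which(gen$segment == "hindfoot")
  st_h <- prov[[which(vapply(prov, `[[`, character(1), "stage") ==
                        "register_hindfoot")]]
  mapped <- tf_apply(st_h$transform, gen$points[hind, ])
  pat <- sp$patient$landmarks
  target <- pat$points[match(rownames(gen$points)[hind], rownames(pat$points)), ]
  expect_lt(max(abs(mapped - target)), 1e-8)
})

test_that("missing patient inputs fail with a stage label", {
  p <- get_identity_patient()$patient
  p$mri_markers <- NULL
  expect_error(assemble_patient_model(get_template(), p), "stage 'inputs'")
  p2 <- get_identity_patient()$patient
  p2$dome_points <- p2$dome_points[, 1:2]
  expect_error(assemble_patient_model(get_template(), p2), "stage '")
})
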