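test_that("packaged template reproduces the published model structure", {
  m <- get_template()
  expect_equal(n_dof(m), 17L)
  per_joint <- table(m$dof_table$joint)
  expect_equal(as.integer(per_joint[c("ground_pelvis", "hip", "knee", "ankle",
                                      "midfoot", "mtp")]),
               c(6L, 3L, 1L, 3L, 3L, 1L))
  expect_length(m$muscles, 54)
  expect_length(unique(vapply(m$muscles, `[[`, character(1), "muscle")), 39)
  expect_equal(sum(vapply(m$muscles, function(x) isTRUE(x$crosses_ankle),
                          logical(1))), 16)
  expect_length(m$ligaments, 7)
  expect_true(all(!vapply(m$ligaments, function(l) isTRUE(l$active), logical(1))))
  dict <- default_landmark_dictionaries()
  expect_equal(vapply(dict[c("hindfoot", "talus", "forefoot", "toes")],
                      length, integer(1)),
               c(hindfoot = 10L, talus = 6L, forefoot = 15L, toes = 17L))
})

test_that("template validation rejects malformed configurations", {
  cfg <- default_template_config()
  cfg$muscles[[1]]$points[[1]]$segment <- "tibia2"
  err <- tryCatch(build_template(cfg), error = conditionMessage)
  expect_match(err, "tibia2")
  expect_match(err, cfg$muscles[[1]]$name)

  cfg2 <- default_template_config()
  cfg2$segments[[8]] <- cfg2$segments[[1]]   # duplicate pelvis
  expect_error(build_template(cfg2), "duplicate segment")

  cfg3 <- default_template_config()
  cfg3$joints$extra <- cfg3$joints[[7]]      # second parent for toes
  cfg3$joints$extra$name <- "mtp2"
  expect_error(build_template(cfg3), "not a tree")
})

test_that("forward kinematics of the zero state is the reference pose", {
  m <- get_template()
  poses <- forward_kinematics(m, kinematic_state(m))
  # reference pose: identity rotations, translations composed down the chain
  expect_transform_equal(poses$pelvis, diag(4), 1e-15)
  expect_transform_equal(tf_rot(poses$toes), diag(3), 1e-15)
  expect_equal(tf_origin(poses$femur), c(0.030, -0.080, 0.090))
  expect_equal(tf_origin(poses$hindfoot), c(0.030, -0.900, 0.090))
})

test_that("only the distal subtree moves with ankle flexion", {
  m <- get_template()
  q0 <- kinematic_state(m)
  q1 <- kinematic_state(m, c(ankle_flexion = 0.1))
  p0 <- forward_kinematics(m, q0)
  p1 <- forward_kinematics(m, q1)
  for (s in c("pelvis", "femur", "shank"))
    expect_transform_equal(p0[[s]], p1[[s]], 1e-15)
  for (s in c("hindfoot", "talus", "forefoot", "toes"))
    expect_gt(max(abs(p0[[s]] - p1[[s]])), 1e-4)
})

test_that("forward kinematics matches an independent matrix-chain oracle", {
  m <- get_template()
  set.seed(7)
  q <- stats::rnorm(n_dof(m), sd = 0.3)
  poses <- forward_kinematics(m, q)
  # oracle: compose plain 4x4 products joint by joint, written independently
  oracle <- list(ground = diag(4))
  qi <- 0
  for (jn in m$joint_order) {
    j <- m$joints[[jn]]
    T <- oracle[[j$parent]]
    T4 <- diag(4); T4[1:3, 1:3] <- j$orientation; T4[1:3, 4] <- j$location
    T <- T %*% T4
    for (d in j$dofs) {
      qi <- qi + 1
      M <- diag(4)
      if (d$type == "rot") {
        u <- d$axis / sqrt(sum(d$axis^2))
        K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
        M[1:3, 1:3] <- diag(3) + sin(q[qi]) * K + (1 - cos(q[qi])) * K %*% K
      } else {
        M[1:3, 4] <- d$axis * q[qi]
      }
      T <- T %*% M
    }
    oracle[[j$child]] <- T
  }
  for (s in names(m$segments))
    expect_transform_equal(poses[[s]], oracle[[s]], 1e-12)
})

test_that("knee coupling hook applies polynomial derived motion", {
  cfg <- default_template_config()
  cfg$joints[[3]]$coupling <- make_polynomial_coupling(tx = c(0, 0.01),
                                                       ty = c(0, 0, 0.002))
  m <- build_template(cfg)
  q <- kinematic_state(m, c(knee_flexion = 0.5))
  p <- forward_kinematics(m, q)
  p0 <- forward_kinematics(get_template(), q)
  shift <- tf_origin(p$shank) - tf_origin(p0$shank)
  # derived translation (0.005, 0.0005, 0) expressed in the rotated knee frame
  R <- axis_angle(c(0, 0, 1), 0.5)
  expect_equal(shift, as.numeric(R %*% c(0.01 * 0.5, 0.002 * 0.25, 0)),
               tolerance = 1e-12)
})

test_that("muscle path lengths behave geometrically", {
  m <- get_template()
  q0 <- kinematic_state(m)
  # rigid invariance: moving the whole model (pelvis dofs) preserves lengths
  q1 <- kinematic_state(m, c(pelvis_tx = 0.3, pelvis_ty = -0.1, pelvis_tz = 0.2,
                             pelvis_tilt = 0.4, pelvis_list = -0.2,
                             pelvis_rotation = 0.7))
  for (mn in c("soleus", "per_long", "rect_fem", "flex_hal_long")) {
    l0 <- world_muscle_path(m, q0, mn)$length
    l1 <- world_muscle_path(m, q1, mn)$length
    expect_equal(l0, l1, tolerance = 1e-12)
  }
  # a posterior-routed plantarflexor lengthens monotonically with dorsiflexion
  angles <- seq(-0.4, 0.3, by = 0.05)
  lens <- vapply(angles, function(a)
    world_muscle_path(m, kinematic_state(m, c(ankle_flexion = a)),
                      "soleus")$length, numeric(1))
  expect_true(all(diff(lens) > 0))
  expect_error(world_muscle_path(m, q0, "no_such_muscle"), "unknown muscle")
})

test_that("constructed right-angle path has the expected length", {
  cfg <- default_template_config()
  cfg$muscles[[length(cfg$muscles) + 1]] <-
    list(name = "right_angle", muscle = "right_angle", fmax = 1,
         crosses_ankle = FALSE,
         points = list(list(segment = "pelvis", p = c(0, 0, 0)),
                       list(segment = "pelvis", p = c(0.3, 0, 0)),
                       list(segment = "pelvis", p = c(0.3, 0.4, 0))))
  m <- build_template(cfg)
  expect_equal(world_muscle_path(m, kinematic_state(m), "right_angle")$length,
               0.7, tolerance = 1e-15)
})

test_that("locked coordinates hold their value in the state vector", {
  m <- set_locked(get_template(), c("ankle_rotation", "midfoot_flexion"),
                  values = c(0.1, -0.05))
  q <- kinematic_state(m, c(ankle_rotation = 99, hip_flexion = 0.2))
  expect_equal(unname(q["ankle_rotation"]), 0.1)
  expect_equal(unname(q["midfoot_flexion"]), -0.05)
  expect_equal(unname(q["hip_flexion"]), 0.2)
  expect_equal(n_dof(m, unlocked_only = TRUE), 15L)
})
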