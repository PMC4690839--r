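test_that("inverse kinematics reproduces a static pose exactly", {
  m <- set_locked(get_template(), simulation_locked_dofs())
  q_true <- kinematic_state(m, c(pelvis_ty = 0.9, hip_flexion = 0.3,
                                 knee_flexion = -0.2, ankle_flexion = 0.1))
  mk <- model_marker_world(m, q_true)
  data <- array(0, c(2, length(names(mk)), 3))
  for (f in 1:2) data[f, , ] <- mk$points
  mt <- marker_trajectories(data, names(mk), 100)
  ik <- inverse_kinematics(m, mt)
  expect_lt(max(abs(ik$q[1, ] - q_true)), 1e-7)
  expect_lt(max(ik$residual_rms_mm), 1e-4)
})

test_that("inverse kinematics recovers the generating gait angles", {
  walk <- get_walk()
  ml <- set_locked(get_model(), simulation_locked_dofs())
  frames <- seq(25, 85, by = 15)
  ik <- inverse_kinematics(ml, walk$trial$markers, frames = frames)
  expect_lt(max(abs(ik$q - walk$truth$q[frames, ])), 1e-6)
})

test_that("marker noise degrades inverse kinematics gracefully", {
  walk <- get_walk()
  ml <- set_locked(get_model(), simulation_locked_dofs())
  mk <- walk$trial$markers
  set.seed(99)
  mk$data <- mk$data + array(stats::rnorm(length(mk$data), 0, 1e-3), dim(mk$data))
  frames <- c(35, 55, 75)
  ik <- inverse_kinematics(ml, mk, frames = frames)
  ang <- setdiff(colnames(ik$q), c("pelvis_tx", "pelvis_ty", "pelvis_tz"))
  # empirical regression bound for 1 mm isotropic noise on this marker set
  expect_lt(max(abs(ik$q[, ang] - walk$truth$q[frames, ang])), 0.08)
  expect_lt(max(ik$residual_rms_mm), 3)
})

test_that("GRF assignment follows the centre of pressure rules", {
  walk <- get_walk()
  model <- get_model()
  ml <- set_locked(model, simulation_locked_dofs())
  run <- get_run_1seg()
  states <- run$states
  l1 <- run$loads
  expect_true(all(l1$segment == "hindfoot"))

  l2 <- assign_grf(walk$trial, ml, states, "2SEG")
  sw <- which(l2$segment == "toes")
  expect_gt(length(sw), 0)
  # latched: no switching back
  expect_equal(sw, min(sw):nrow(l2))
  frac <- (min(sw) - 1) / (nrow(l2) - 1)
  expect_equal(frac, walk$truth$cop_cross_frac, tolerance = 0.02)
  # total external wrench identical under both assumptions
  expect_equal(as.matrix(l1[, 4:12]), as.matrix(l2[, 4:12]))

  # COP always posterior of the axis: two-segment equals one-segment
  tr_post <- walk$trial
  tr_post$grf$cop[, 1] <- tr_post$grf$cop[, 1] - 0.5
  l3 <- assign_grf(tr_post, ml, states, "2SEG")
  expect_true(all(l3$segment == "hindfoot"))
})

test_that("quasi-static inverse dynamics satisfies standing equilibrium", {
  m <- set_locked(get_template(), simulation_locked_dofs())
  bw <- m$patient$body_weight_N
  q <- kinematic_state(m, c(pelvis_ty = 0.9))
  poses <- forward_kinematics(m, q)
  ankle <- tf_origin(poses$hindfoot)
  states <- toy_states(m, list(q))
  loads <- toy_loads(states, "hindfoot", c(0, bw, 0), c(ankle[1], 0, ankle[3]))
  id <- inverse_dynamics(m, states, loads)
  # near zero: only the small foot-weight moment about the ankle remains
  expect_lt(abs(id$tau[1, "ankle_flexion"]), 1)
  foot_w <- 9.81 * sum(vapply(m$segments[c("talus", "hindfoot", "forefoot", "toes")],
                              `[[`, numeric(1), "mass"))
  expect_equal(id$ankle_force[1, 2], -(bw - foot_w), tolerance = 1e-9)
})

test_that("planar free-body moment matches the hand computation", {
  toy <- toy_ankle_model(foot_mass = 0)
  bw <- 700
  states <- toy_states(toy, list(NULL))
  loads <- toy_loads(states, "hindfoot", c(0, 1.2 * bw, 0), c(0.12, -0.08, 0))
  id <- inverse_dynamics(toy, states, loads)
  # balancing moment = 1.2 BW x 0.12 m = 0.144 BW N m (plantarflexion)
  expect_equal(unname(id$tau[1, "ankle_flexion"]), -0.144 * bw,
               tolerance = 1e-9)
})

test_that("quasi-static and full dynamics agree on slow gait", {
  model <- get_model()
  slow <- make_walking_trial(synthetic_gait_params(stance_s = 1.4, seed = 31),
                             model)
  ml <- set_locked(model, simulation_locked_dofs())
  ev <- slow$trial$events
  mt <- slow$trial$markers$time
  frames <- which(mt >= ev$foot_strike & mt <= ev$foot_off)
  ik <- inverse_kinematics(ml, slow$trial$markers, frames = frames)
  loads <- assign_grf(slow$trial, ml, ik, "1SEG")
  id_q <- inverse_dynamics(ml, ik, loads, "quasi_static")
  id_f <- inverse_dynamics(ml, ik, loads, "full")
  mid <- seq(10, length(frames) - 10)
  num <- max(abs(id_f$tau[mid, "ankle_flexion"] - id_q$tau[mid, "ankle_flexion"]))
  den <- max(abs(id_q$tau[mid, "ankle_flexion"]))
  expect_lt(num / den, 0.05)
})

test_that("tendon-excursion moment arms match hinge geometry", {
  for (arm in c(0.03, 0.05)) {
    toy <- toy_ankle_model(arm = arm)
    R <- moment_arms(toy, kinematic_state(toy))
    expect_equal(R["achilles", "ankle_flexion"], -arm, tolerance = 1e-4)
  }
  # reflecting the path across the joint flips the sign
  toy_r <- toy_ankle_model(arm = 0.04, reflect = TRUE)
  R <- moment_arms(toy_r, kinematic_state(toy_r))
  expect_equal(R["achilles", "ankle_flexion"], 0.04, tolerance = 1e-4)
})

test_that("muscles have zero moment arm about joints they do not span", {
  m <- get_template()
  R <- moment_arms(m, kinematic_state(m),
                   muscles = c("soleus", "glut_max1", "vas_int", "flex_hal_long"),
                   dofs = c("hip_flexion", "knee_flexion", "ankle_flexion",
                            "mtp_flexion"))
  expect_equal(R["soleus", "hip_flexion"], 0)
  expect_equal(R["soleus", "knee_flexion"], 0)
  expect_equal(R["soleus", "mtp_flexion"], 0)
  expect_equal(R["glut_max1", "knee_flexion"], 0)
  expect_equal(R["glut_max1", "ankle_flexion"], 0)
  expect_equal(R["vas_int", "ankle_flexion"], 0)
  # the knee coordinate is extension-positive about +Z: extensors have
  # positive arms
  expect_gt(R["vas_int", "knee_flexion"], 0)
  expect_true(all(R["flex_hal_long", c("knee_flexion", "hip_flexion")] == 0))
  expect_true(R["flex_hal_long", "mtp_flexion"] != 0)
})

test_that("static optimization solves analytic single-muscle cases", {
  # tau 0 -> all zero
  Rm <- matrix(c(-0.05), 1, 1, dimnames = list("m1", "d"))
  s0 <- static_optimization(Rm, c(d = 0), c(m1 = 1000), "d", reserves = "off")
  expect_equal(unname(s0$activations[1, 1]), 0)

  # single muscle, r = 0.05 m, fmax = 1000 N, tau = 25 N m -> a = 0.5
  s1 <- static_optimization(matrix(0.05, 1, 1, dimnames = list("m1", "d")),
                            c(d = 25), c(m1 = 1000), "d", reserves = "off")
  expect_equal(unname(s1$activations[1, 1]), 0.5, tolerance = 1e-9)
  expect_equal(unname(s1$forces[1, 1]), 500, tolerance = 1e-6)
})

test_that("static optimization matches a dense brute-force minimizer", {
  # two plantarflexors, r1 = 2 r2, equal fmax
  r <- c(0.06, 0.03); fm <- c(1500, 1500); tau <- 50
  Rm <- matrix(r, 2, 1, dimnames = list(c("m1", "m2"), "d"))
  sol <- static_optimization(Rm, c(d = tau), stats::setNames(fm, c("m1", "m2")),
                             "d", reserves = "off")
  a1 <- seq(0, 1, by = 1e-5)
  a2 <- (tau - a1 * r[1] * fm[1]) / (r[2] * fm[2])
  obj <- ifelse(a2 >= 0 & a2 <= 1, a1^2 + a2^2, Inf)
  best <- which.min(obj)
  expect_lt(max(abs(sol$activations[1, ] - c(a1[best], a2[best]))), 1e-3)
  # constraint satisfied to 1e-6 N m
  expect_lt(abs(sum(sol$activations[1, ] * fm * r) - tau), 1e-6)

  # three-muscle case against a coarse grid
  r3 <- c(0.05, 0.03, 0.02); fm3 <- c(2000, 1000, 800); tau3 <- 40
  Rm3 <- matrix(r3, 3, 1, dimnames = list(paste0("m", 1:3), "d"))
  sol3 <- static_optimization(Rm3, c(d = tau3),
                              stats::setNames(fm3, paste0("m", 1:3)), "d",
                              reserves = "off")
  g <- seq(0, 1, by = 1e-3)
  best_obj <- Inf; best_a <- NULL
  for (x1 in g) for (x2 in g) {
    x3 <- (tau3 - x1 * r3[1] * fm3[1] - x2 * r3[2] * fm3[2]) / (r3[3] * fm3[3])
    if (x3 >= 0 && x3 <= 1) {
      o <- x1^2 + x2^2 + x3^2
      if (o < best_obj) { best_obj <- o; best_a <- c(x1, x2, x3) }
    }
  }
  expect_lte(sum(sol3$activations[1, ]^2), best_obj + 1e-9)
  expect_lt(max(abs(sol3$activations[1, ] - best_a)), 2e-3)
})

test_that("infeasibility is reported with the violated coordinate", {
  # a dorsiflexion demand no plantarflexor can meet
  Rm <- matrix(c(-0.05, -0.03), 2, 1,
               dimnames = list(c("m1", "m2"), "ankle_inversion"))
  err <- tryCatch(
    static_optimization(Rm, c(ankle_inversion = 30),
                        c(m1 = 1000, m2 = 800), "ankle_inversion",
                        reserves = "off"),
    error = conditionMessage)
  expect_match(err, "infeasible")
  expect_match(err, "ankle_inversion")
  # with reserves the same problem solves, the reserve carrying the moment
  sol <- static_optimization(Rm, c(ankle_inversion = 30),
                             c(m1 = 1000, m2 = 800), "ankle_inversion",
                             reserves = "on")
  expect_true(sol$reserves_used)
  expect_equal(unname(sol$reserves[1, 1]), 30, tolerance = 0.2)
})

test_that("pipeline static optimization satisfies all moment constraints", {
  run <- get_run_1seg()
  R <- run$moment_arm_array
  fm <- muscle_fmax(run$model)[dimnames(R)[[1]]]
  for (i in seq(1, dim(R)[3], by = 7)) {
    lhs <- as.numeric(t(R[, , i] * fm) %*%
                        run$muscle_state$activations[i, dimnames(R)[[1]]])
    expect_lt(max(abs(lhs - run$id$tau[i, run$free_dofs])), 1e-6)
  }
  a <- run$muscle_state$activations
  expect_true(all(a >= -1e-12 & a <= 1 + 1e-12))
})

test_that("joint reaction reduces to the free body without muscles", {
  m <- set_locked(get_template(), simulation_locked_dofs())
  bw <- m$patient$body_weight_N
  q <- kinematic_state(m, c(pelvis_ty = 0.9))
  poses <- forward_kinematics(m, q)
  ankle <- tf_origin(poses$hindfoot)
  states <- toy_states(m, list(q))
  loads <- toy_loads(states, "hindfoot", c(0, bw, 0), c(ankle[1], 0, ankle[3]))
  id <- inverse_dynamics(m, states, loads)
  ms <- list(forces = matrix(0, 1, length(m$muscles),
                             dimnames = list(NULL, names(m$muscles))))
  jrf <- joint_reaction(m, states, ms, id)
  foot_w <- 9.81 * sum(vapply(m$segments[c("talus", "hindfoot", "forefoot", "toes")],
                              `[[`, numeric(1), "mass"))
  expect_equal(jrf$mag_bw[1], 100 * (bw - foot_w) / bw, tolerance = 1e-6)
})

test_that("planar toy joint reaction matches the hand free-body oracle", {
  toy <- toy_ankle_model(fmax = 5000, arm = 0.04, foot_mass = 1)
  bw <- toy$patient$body_weight_N
  states <- toy_states(toy, list(NULL))
  loads <- toy_loads(states, "hindfoot", c(0, 1.2 * bw, 0), c(0.12, -0.08, 0))
  id <- inverse_dynamics(toy, states, loads)
  R <- moment_arms(toy, states$q[1, ])
  ms <- static_optimization(array(R, c(1, 1, 1), dimnames = list("achilles", "ankle_flexion", NULL)),
                            id$tau[, "ankle_flexion", drop = FALSE],
                            c(achilles = 5000), "ankle_flexion", reserves = "off")
  # hand oracle: F_m = 1.2 BW x 0.12 / 0.04 = 3.6 BW (plus the small
  # foot-weight correction the simplified diagram neglects)
  expect_equal(unname(ms$forces[1, 1]) / bw, 3.6, tolerance = 5e-3)
  jrf <- joint_reaction(toy, states, ms, id)
  expect_gt(jrf$mag_bw[1] / 100, 4.7)
  expect_lt(jrf$mag_bw[1] / 100, 4.8)

  # magnitude is invariant to the frame the components are expressed in
  jrf_rot <- joint_reaction(toy, states, ms, id,
                            frame_axes = axis_angle(c(1, 1, 0), 0.7))
  expect_equal(jrf_rot$mag_bw, jrf$mag_bw, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(jrf_rot$jy, jrf$jy)))
})

test_that("joint reaction scales linearly with the ground reaction", {
  toy <- toy_ankle_model(fmax = 20000, foot_mass = 0)
  bw <- toy$patient$body_weight_N
  states <- toy_states(toy, list(NULL))
  jrf_at <- function(mult) {
    loads <- toy_loads(states, "hindfoot", c(0, mult * bw, 0), c(0.12, -0.08, 0))
    id <- inverse_dynamics(toy, states, loads)
    R <- moment_arms(toy, states$q[1, ])
    ms <- static_optimization(array(R, c(1, 1, 1), dimnames = list("achilles", "ankle_flexion", NULL)),
                              id$tau[, "ankle_flexion", drop = FALSE],
                              c(achilles = 20000), "ankle_flexion", reserves = "off")
    attr(joint_reaction(toy, states, ms, id), "world")[1, ]
  }
  j0 <- jrf_at(0)          # weight-only terms, unaffected by the GRF
  j1 <- jrf_at(1.2)
  j2 <- jrf_at(2.4)
  # subtracting the weight contribution, doubling the GRF doubles the JRF
  expect_lt(max(abs((j2 - j0) - 2 * (j1 - j0))), 1e-8)
})

test_that("the foot free body balances at every stance frame", {
  run <- get_run_1seg()
  model <- run$model
  n <- length(run$states$time)
  g <- 9.81
  foot_segs <- c("talus", "hindfoot", "forefoot", "toes")
  for (i in seq(1, n, by = 9)) {
    poses <- forward_kinematics(model, run$states$q[i, ])
    geom <- mskfoot:::ankle_crossing_geometry(model, poses)
    Fm <- c(0, 0, 0)
    for (mn in names(geom))
      Fm <- Fm + run$muscle_state$forces[i, mn] * geom[[mn]]$dir
    grf <- c(run$loads$fx[i], run$loads$fy[i], run$loads$fz[i])
    W <- c(0, -g * sum(vapply(model$segments[foot_segs], `[[`, numeric(1), "mass")), 0)
    jrf_world <- attr(run$jrf, "world")[i, ]
    expect_lt(max(abs(jrf_world + Fm + grf + W)), 1e-6)
  }
})
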