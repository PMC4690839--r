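# Shared fixtures. Heavy objects (assembled default patient, walking trial,
# pipeline runs) are built once per session and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

get_template <- function() fixture("template", build_template)

get_patient <- function() fixture("patient", function()
  make_synthetic_patient(synthetic_foot_params()))

get_model <- function() fixture("model", function()
  assemble_patient_model(get_template(), get_patient()$patient))

get_walk <- function() fixture("walk", function()
  make_walking_trial(synthetic_gait_params(), get_model()))

get_run_1seg <- function() fixture("run_1seg", function()
  run_pipeline(get_model(), get_walk()$trial,
               pipeline_config(mode = "1SEG", axes = "MR", reserves = "off")))

get_run_2seg <- function() fixture("run_2seg", function()
  run_pipeline(get_model(), get_walk()$trial,
               pipeline_config(mode = "2SEG", axes = "MR", reserves = "off")))

# identity patient: same anatomy as the template, no noise, no offsets
get_identity_patient <- function() fixture("identity_patient", function()
  make_synthetic_patient(synthetic_foot_params(stature_scale = 1, mass_kg = 75,
                                               height_m = 1.75)))

random_rigid_transform <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  make_transform(axis_angle(ax, stats::runif(1, -pi, pi)),
                 stats::rnorm(3, sd = 0.05))
}

# planar single-muscle ankle toy: shank fixed to ground, one hinge ankle,
# an Achilles-like muscle running vertically 0.04 m posterior of the joint
toy_ankle_model <- function(fmax = 5000, arm = 0.04, foot_mass = 1,
                            reflect = FALSE) {
  sgn <- if (reflect) 1 else -1
  cfg <- list(
    name = "planar ankle toy",
    segments = list(
      list(name = "shank", mass = 0, com = c(0, 0.2, 0), inertia = diag(3) * 1e-4),
      list(name = "hindfoot", mass = foot_mass, com = c(0.03, -0.05, 0),
           inertia = diag(3) * 1e-4)),
    joints = list(
      list(name = "shank_ground", parent = "ground", child = "shank",
           location = c(0, 0.9, 0), orientation = diag(3), dofs = list()),
      list(name = "ankle", parent = "shank", child = "hindfoot",
           location = c(0, -0.9, 0), orientation = diag(3),
           dofs = list(list(name = "ankle_flexion", type = "rot",
                            axis = c(0, 0, 1), locked = FALSE, lock_value = 0)))),
    muscles = list(list(
      name = "achilles", muscle = "achilles", fmax = fmax, crosses_ankle = TRUE,
      points = list(list(segment = "shank", p = c(sgn * arm, -0.60, 0)),
                    list(segment = "hindfoot", p = c(sgn * arm, -0.05, 0))))),
    ligaments = list(), markers = list(), landmarks = list(),
    patient = list(mass_kg = 700 / 9.81, height_m = 1.7))
  build_template(cfg)
}

# hand-built state/load containers for driving the dynamics directly
toy_states <- function(model, q_list, dt = 0.01) {
  q <- do.call(rbind, lapply(q_list, function(qq) kinematic_state(model, qq)))
  list(q = q, time = (seq_len(nrow(q)) - 1) * dt, frames = seq_len(nrow(q)),
       residual_rms_mm = rep(0, nrow(q)))
}

toy_loads <- function(states, segment, force, cop, moment = c(0, 0, 0)) {
  n <- length(states$time)
  out <- data.frame(frame = states$frames, time = states$time,
                    segment = rep(segment, n),
                    fx = force[1], fy = force[2], fz = force[3],
                    px = cop[1], py = cop[2], pz = cop[3],
                    mx = moment[1], my = moment[2], mz = moment[3])
  class(out) <- c("external_loads", "data.frame")
  out
}

expect_transform_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
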