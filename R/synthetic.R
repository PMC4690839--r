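# Synthetic patient generator: parametric foot/shank geometry with known
# ground truth (dome cylinder, per-segment transforms), virtually palpated
# landmark sets, MRI marker replicas, a standing trial and walking trials
# with a double-hump GRF and heel-to-toe centre-of-pressure progression.
# Every generator is seed-deterministic and returns its generating values
# for parameter-recovery tests.

local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthetic foot parameters
#'
#' The defaults emulate a juvenile patient: the generic adult template
#' shrunk to a stature ratio of 0.83 with the mid-range mass and height of
#' a 9-16 year-old cohort (51.6 kg, 1.45 m). The talar dome is sampled
#' from a known cylinder (radius = scaled template dome radius).
#'
#' @param stature_scale uniform geometric scale applied to the template
#' @param mass_kg,height_m patient metadata
#' @param dome_radius cylinder radius (m); default scales the template's
#' @param dome_arc_deg arc of the sampled dome patch (degrees, in (10, 160])
#' @param n_dome number of dome sample points
#' @param dome_noise_m isotropic noise on dome samples (m)
#' @param landmark_noise_m isotropic noise on palpated landmarks (m)
#' @param segment_transforms named list of 4x4 rigid transforms applied to
#'   individual segments' emitted geometry (ground truth for recovery tests)
#' @param mri_offset 4x4 rigid transform from the standing lab frame to the
#'   MRI frame
#' @param seed RNG seed
#' @return parameter list of class `synthetic_foot_params`
#' @export
synthetic_foot_params <- function(stature_scale = 0.83, mass_kg = 51.6,
                                  height_m = 1.45, dome_radius = NULL,
                                  dome_arc_deg = 80, n_dome = 200,
                                  dome_noise_m = 0, landmark_noise_m = 0,
                                  segment_transforms = list(),
                                  mri_offset = diag(4), seed = 1) {
  if (dome_arc_deg <= 10 || dome_arc_deg > 160)
    stop("dome arc must be in (10, 160] degrees")
  structure(list(stature_scale = stature_scale, mass_kg = mass_kg,
                 height_m = height_m, dome_radius = dome_radius,
                 dome_arc_deg = dome_arc_deg, n_dome = n_dome,
                 dome_noise_m = dome_noise_m, landmark_noise_m = landmark_noise_m,
                 segment_transforms = segment_transforms,
                 mri_offset = mri_offset, seed = seed),
            class = "synthetic_foot_params")
}

# uniform geometric scaling of a whole model (the synthetic patient's true
# anatomy); distinct from apply_scaling, which is the pipeline's estimate
scale_model_uniform <- function(model, s, meta = NULL) {
  for (sn in names(model$segments))
    model$segments[[sn]]$com <- model$segments[[sn]]$com * s
  for (jn in names(model$joints))
    model$joints[[jn]]$location <- model$joints[[jn]]$location * s
  for (mn in names(model$muscles))
    model$muscles[[mn]]$points <- lapply(model$muscles[[mn]]$points, function(pt) {
      pt$p <- pt$p * s; pt })
  for (ln in seq_along(model$ligaments))
    model$ligaments[[ln]]$points <- lapply(model$ligaments[[ln]]$points, function(pt) {
      pt$p <- pt$p * s; pt })
  for (mk in names(model$markers)) model$markers[[mk]]$p <- model$markers[[mk]]$p * s
  for (lm in names(model$landmarks)) model$landmarks[[lm]]$p <- model$landmarks[[lm]]$p * s
  if (!is.null(model$dome)) {
    model$dome$centre <- model$dome$centre * s
    model$dome$radius <- model$dome$radius * s
    model$dome$half_length <- model$dome$half_length * s
  }
  if (!is.null(meta)) model$patient <- meta
  rebuild_model_tables(model)
}

# pelvis height (m) that puts the lowest foot marker on the ground
standing_height <- function(model) {
  mk <- model_marker_world(model)
  -min(mk$points[, 2])
}

#' Generate a synthetic foot: geometry, landmarks, dome samples, meshes
#'
#' Builds the patient's "true" anatomy (a uniformly scaled template,
#' optionally deformed by known per-segment rigid transforms), poses it
#' standing, and emits everything an MRI segmentation session would:
#' per-segment landmark sets, the six radio-opaque marker replicas, a talar
#' dome point cloud sampled from the known cylinder, and point meshes —
#' all in the MRI frame (standing lab frame composed with `mri_offset`).
#'
#' @param params a [synthetic_foot_params()]
#' @param template template `msk_model`
#' @return list of class `synthetic_foot`: `truth_model`, `landmarks`,
#'   `dome_points`, `mri_markers`, `meshes`, `stand_q`, `truth` (generating
#'   cylinder in MRI space, transforms, params)
#' @export
make_synthetic_foot <- function(params = synthetic_foot_params(),
                                template = build_template()) {
  truth <- scale_model_uniform(template, params$stature_scale,
                               patient_meta(params$mass_kg, params$height_m))
  if (!is.null(params$dome_radius)) truth$dome$radius <- params$dome_radius

  q_stand <- kinematic_state(truth)
  q_stand["pelvis_ty"] <- standing_height(truth)
  poses <- forward_kinematics(truth, q_stand)
  seg_T <- function(sn) params$segment_transforms[[sn]] %||% diag(4)
  to_mri <- function(sn, pts) tf_apply(params$mri_offset %*% seg_T(sn), pts)

  local_seed(params$seed, {
    lmw <- model_landmark_world(truth, poses = poses)
    lpts <- lmw$points
    for (i in seq_len(nrow(lpts)))
      lpts[i, ] <- to_mri(lmw$segment[i], lpts[i, ])
    if (params$landmark_noise_m > 0)
      lpts <- lpts + matrix(stats::rnorm(length(lpts), 0, params$landmark_noise_m),
                            ncol = 3)
    landmarks <- landmark_set(lpts, names(lmw), lmw$segment, "mri")

    # dome patch sampled from the true cylinder (talus frame; arc about +Y)
    d <- truth$dome
    # random angular positions on a regular axial grid spanning the full
    # extent, so the patch determines the cylinder's axial midpoint exactly
    ang <- stats::runif(params$n_dome, -d$arc_deg / 2, d$arc_deg / 2) * pi / 180
    zz <- seq(-d$half_length, d$half_length, length.out = params$n_dome)
    local_pts <- cbind(d$centre[1] + d$radius * sin(ang),
                       d$centre[2] + d$radius * cos(ang),
                       d$centre[3] + zz)
    dome_world <- tf_apply(poses$talus, local_pts)
    dome_mri <- to_mri("talus", dome_world)
    if (params$dome_noise_m > 0)
      dome_mri <- dome_mri + matrix(stats::rnorm(length(dome_mri), 0,
                                                 params$dome_noise_m), ncol = 3)

    mkw <- model_marker_world(truth, poses = poses)
    six <- mri_replica_markers()
    mpts <- mkw$points[six, , drop = FALSE]
    for (i in seq_along(six))
      mpts[i, ] <- to_mri(mkw$segment[match(six[i], names(mkw))], mpts[i, ])
    mri_markers <- landmark_set(mpts, six, source = "mri")

    meshes <- list(talus = list(vertices = dome_mri, faces = NULL))
    for (sn in c("hindfoot", "forefoot", "toes", "shank")) {
      idx <- landmarks$segment == sn
      meshes[[sn]] <- list(vertices = landmarks$points[idx, , drop = FALSE],
                           faces = NULL)
    }

    axis_mri <- unit(as.numeric((params$mri_offset %*% seg_T("talus"))[1:3, 1:3] %*%
                                  poses$talus[1:3, 1:3] %*% d$axis))
    centre_mri <- to_mri("talus", tf_apply(poses$talus, d$centre))
    structure(list(
      truth_model = truth, landmarks = landmarks, dome_points = dome_mri,
      mri_markers = mri_markers, meshes = meshes, stand_q = q_stand,
      truth = list(cylinder = list(point = centre_mri, direction = axis_mri,
                                   radius = d$radius),
                   segment_transforms = params$segment_transforms,
                   mri_offset = params$mri_offset, params = params)),
      class = "synthetic_foot")
  })
}

#' Synthetic static (standing) trial with MRI marker replicas
#'
#' Markers of the true model in the standing pose, sampled over time with
#' optional noise. The six replicated foot markers are also returned in
#' MRI coordinates under the foot's known rigid offset.
#'
#' @param foot a `synthetic_foot`
#' @param n_frames,rate trial length and rate
#' @param marker_noise_m isotropic marker noise (m)
#' @param seed RNG seed
#' @return list with `trial` (static `gait_trial`), `mri_markers`, `pose`
#' @export
make_static_trial <- function(foot, n_frames = 100, rate = 100,
                              marker_noise_m = 0, seed = 2) {
  truth <- foot$truth_model
  mkw <- model_marker_world(truth, q = foot$stand_q)
  n_mk <- length(names(mkw))
  local_seed(seed, {
    data <- array(0, c(n_frames, n_mk, 3))
    for (f in seq_len(n_frames))
      data[f, , ] <- mkw$points +
        if (marker_noise_m > 0)
          matrix(stats::rnorm(3 * n_mk, 0, marker_noise_m), n_mk, 3) else 0
    mt <- marker_trajectories(data, names(mkw), rate)
    list(trial = gait_trial(mt, kind = "static"),
         mri_markers = foot$mri_markers, pose = foot$stand_q)
  })
}

#' Bundle a full synthetic patient for model assembly
#'
#' Convenience wrapper: generates the foot geometry and the static trial
#' and returns the `patient` input list expected by
#' [assemble_patient_model()], together with the ground truth.
#'
#' @param params a [synthetic_foot_params()]
#' @param template template `msk_model`
#' @param static_noise_m marker noise in the static trial
#' @return list with `patient` (inputs for assembly), `foot` (the
#'   `synthetic_foot` with its ground truth)
#' @export
make_synthetic_patient <- function(params = synthetic_foot_params(),
                                   template = build_template(),
                                   static_noise_m = 0) {
  foot <- make_synthetic_foot(params, template)
  st <- make_static_trial(foot, marker_noise_m = static_noise_m,
                          seed = params$seed + 1)
  list(patient = list(landmarks = foot$landmarks,
                      dome_points = foot$dome_points,
                      static = st$trial,
                      mri_markers = foot$mri_markers,
                      meta = patient_meta(params$mass_kg, params$height_m)),
       foot = foot)
}

#' Synthetic gait parameters
#'
#' Defaults: 100 Hz markers, 1 kHz force plate, 0.7 s stance, double-hump
#' vertical GRF with peaks of 1.1 and 1.2 body weight and a 0.8 BW
#' mid-stance valley, centre of pressure progressing heel to toe and
#' crossing the metatarsophalangeal axis at 70% stance.
#'
#' @param rate marker rate (Hz)
#' @param grf_rate force-plate rate (Hz)
#' @param stance_s stance duration (s)
#' @param pad_s zero-load padding before and after stance (s)
#' @param hump1_bw,valley_bw,hump2_bw vertical GRF profile (body weights)
#' @param cop_cross_frac stance fraction at which the COP crosses the MTP
#'   axis
#' @param marker_noise_m isotropic marker noise (m)
#' @param free_moment_Nm peak vertical free moment (N m)
#' @param seed RNG seed
#' @return parameter list of class `synthetic_gait_params`
#' @export
synthetic_gait_params <- function(rate = 100, grf_rate = 1000, stance_s = 0.7,
                                  pad_s = 0.2, hump1_bw = 1.1, valley_bw = 0.8,
                                  hump2_bw = 1.2, cop_cross_frac = 0.7,
                                  marker_noise_m = 0, free_moment_Nm = 3,
                                  seed = 3) {
  stopifnot(hump1_bw > 0, hump2_bw > 0, cop_cross_frac > 0, cop_cross_frac < 1)
  structure(list(rate = rate, grf_rate = grf_rate, stance_s = stance_s,
                 pad_s = pad_s, hump1_bw = hump1_bw, valley_bw = valley_bw,
                 hump2_bw = hump2_bw, cop_cross_frac = cop_cross_frac,
                 marker_noise_m = marker_noise_m, free_moment_Nm = free_moment_Nm,
                 seed = seed),
            class = "synthetic_gait_params")
}

# smooth trajectory through (stance-fraction, value) control points,
# clamped outside [0, 1]
traj_fun <- function(s_ctrl, v_ctrl) {
  f <- stats::splinefun(s_ctrl, v_ctrl, method = "natural")
  function(s) f(pmin(pmax(s, 0), 1))
}

#' Synthetic walking trial
#'
#' Generates smooth gait-like joint-angle trajectories (sums of splines
#' over plausible ranges, ankle about -18 to +10 degrees), runs them
#' through forward kinematics to obtain marker trajectories (plus optional
#' noise), and builds a double-hump ground reaction force whose centre of
#' pressure progresses heel to toe, crossing the metatarsophalangeal
#' flexion axis at the stated stance fraction. All generating values are
#' returned.
#'
#' @param params a [synthetic_gait_params()]
#' @param model the model whose geometry the trial is consistent with
#' @return list with `trial` (walking `gait_trial`), `truth` (generating
#'   joint angles at marker frames, events, COP crossing fraction)
#' @export
make_walking_trial <- function(params = synthetic_gait_params(), model) {
  bw <- model$patient$body_weight_N
  t0 <- params$pad_s
  t1 <- t0 + params$stance_s
  duration <- params$stance_s + 2 * params$pad_s
  time <- seq(0, duration, by = 1 / params$rate)
  s_of <- function(t) (t - t0) / params$stance_s
  d2r <- pi / 180

  # the pelvis advances over the planted foot while the hip extends, so the
  # ground reaction line stays close to the knee and hip as in real stance
  traj <- list(
    ankle_flexion = traj_fun(c(0, .3, .55, .8, 1), d2r * c(-3, 5, 10, -8, -18)),
    knee_flexion = traj_fun(c(0, .15, .5, .8, 1), d2r * c(-6, -15, -6, -12, -38)),
    hip_flexion = traj_fun(c(0, .3, .6, 1), d2r * c(24, 12, -5, -18)),
    mtp_flexion = traj_fun(c(0, .6, .8, 1), d2r * c(0, 0, 12, 25)),
    ankle_inversion = traj_fun(c(0, .4, .8, 1), d2r * c(1, -2, 2, 1)),
    pelvis_tilt = traj_fun(c(0, .5, 1), d2r * c(2, -1, 2)),
    hip_adduction = traj_fun(c(0, .4, 1), d2r * c(-2, 3, -2)),
    pelvis_tx = traj_fun(c(0, .5, 1), c(-0.24, 0.03, 0.28))
  )
  stand_ty <- standing_height(model)

  n <- length(time)
  tab <- model$dof_table
  Q <- matrix(0, n, nrow(tab), dimnames = list(NULL, tab$name))
  for (i in seq_len(n)) {
    s <- s_of(time[i])
    q <- kinematic_state(model)
    for (nm in names(traj)) if (nm %in% tab$name) q[nm] <- traj[[nm]](s)
    q["pelvis_ty"] <- stand_ty + 0.012 * sin(2 * pi * pmin(pmax(s, 0), 1))
    Q[i, ] <- q
  }

  seg_of <- vapply(model$markers, `[[`, character(1), "segment")
  loc <- t(vapply(model$markers, `[[`, numeric(3), "p"))
  data <- array(0, c(n, length(seg_of), 3))
  anchors <- matrix(0, n, 8)  # heel/ankle/mtp/toe x and z
  for (i in seq_len(n)) {
    poses <- forward_kinematics(model, Q[i, ])
    for (m in seq_along(seg_of))
      data[i, m, ] <- tf_apply(poses[[seg_of[m]]], loc[m, ])
    heel <- tf_apply(poses$hindfoot, model$markers$RHEE$p)
    ank <- tf_origin(poses$hindfoot)
    mtp <- tf_origin(poses$toes)
    toe <- tf_apply(poses$toes, c(0.05, -0.015, 0))
    # ground-plane abscissa at which a COP (y = 0) sits exactly on the MTP
    # flexion axis as seen along the forefoot anterior direction
    ant <- poses$forefoot[1:3, 1]
    mtp_cross_x <- mtp[1] + mtp[2] * ant[2] / ant[1]
    anchors[i, ] <- c(heel[1], ank[1], mtp_cross_x, toe[1],
                      heel[3], ank[3], mtp[3], toe[3])
  }
  local_seed(params$seed, {
    if (params$marker_noise_m > 0)
      data <- data + array(stats::rnorm(length(data), 0, params$marker_noise_m),
                           dim(data))
    markers <- marker_trajectories(data, names(model$markers), params$rate, time)

    gt <- seq(0, duration, by = 1 / params$grf_rate)
    sg <- s_of(gt)
    vshape <- traj_fun(c(0, .1, .25, .5, .75, .9, 1),
                       c(0, 0.55, params$hump1_bw, params$valley_bw,
                         params$hump2_bw, 0.65, 0))
    in_stance <- sg >= 0 & sg <= 1
    fy <- ifelse(in_stance, pmax(vshape(sg), 0) * bw, 0)
    fx <- ifelse(in_stance,
                 traj_fun(c(0, .25, .5, .75, 1), c(0, -0.15, 0, 0.17, 0))(sg) * bw, 0)
    fz <- ifelse(in_stance, 0.02 * bw * sin(2 * pi * sg), 0)
    my <- ifelse(in_stance,
                 traj_fun(c(0, .4, .8, 1), c(0, -0.3, -1, 0))(sg) * params$free_moment_Nm, 0)

    knots <- c(0, 0.35, params$cop_cross_frac, 1)
    ax_t <- vapply(1:8, function(k)
      stats::approx(time, anchors[, k], xout = pmin(pmax(gt, t0), t1), rule = 2)$y,
      numeric(length(gt)))
    cop <- matrix(NA_real_, length(gt), 3)
    for (g in which(in_stance & fy > 20)) {
      xs <- ax_t[g, 1:4]
      zs <- ax_t[g, 5:8]
      cop[g, 1] <- stats::approx(knots, xs, xout = sg[g], rule = 2)$y
      cop[g, 2] <- 0
      cop[g, 3] <- stats::approx(knots, zs, xout = sg[g], rule = 2)$y +
        0.002 * sin(2 * pi * sg[g])
    }
    grf <- forceplate_series(gt, cbind(fx, fy, fz), cop,
                             cbind(0, my, 0), rate = params$grf_rate)
    trial <- gait_trial(markers, grf, kind = "walking")
    list(trial = trial,
         truth = list(q = Q, time = time, events = trial$events,
                      cop_cross_frac = params$cop_cross_frac,
                      stance_window = c(t0, t1), params = params))
  })
}
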