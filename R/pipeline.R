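# Joint reaction analysis and the end-to-end gait pipeline:
# IK -> GRF assignment -> inverse dynamics -> moment arms -> static
# optimization -> joint reaction, windowed to stance, with all
# intermediates kept for the sensitivity fast path.

# world geometry of each ankle-crossing muscle's joint-spanning strand:
# the pair of consecutive path points with the proximal one outside and the
# distal one inside the foot subtree
ankle_crossing_geometry <- function(model, poses, muscles = NULL) {
  foot_segs <- joint_subtrees(model)$ankle
  muscles <- muscles %||% rownames(model$crossing)[model$crossing[, "ankle"]]
  out <- list()
  for (mn in muscles) {
    pts <- model$muscles[[mn]]$points
    distal <- vapply(pts, function(p) p$segment %in% foot_segs, logical(1))
    k <- which(!distal[-length(distal)] & distal[-1])
    if (!length(k)) next
    k <- k[1]
    p_prox <- tf_apply(poses[[pts[[k]]$segment]], pts[[k]]$p)
    p_dist <- tf_apply(poses[[pts[[k + 1]]$segment]], pts[[k + 1]]$p)
    if (sqrt(sum((p_prox - p_dist)^2)) < 1e-9)
      stop("degenerate muscle path at the ankle (coincident points): ", mn)
    out[[mn]] <- list(dir = unit(p_prox - p_dist), at = p_dist)
  }
  out
}

#' Joint reaction analysis at the ankle
#'
#' The ankle joint reaction force on the foot is the intersegmental force
#' from inverse dynamics minus the vector sum of the forces the
#' ankle-crossing muscles apply to the foot (each acting along its local
#' path direction where it spans the joint). The reaction is expressed in
#' the chosen ankle frame and its magnitude normalized by body weight.
#'
#' @param model a `msk_model`
#' @param states IK result on the stance window
#' @param muscle_state a `muscle_state` from [static_optimization()]
#' @param id inverse-dynamics result ([inverse_dynamics()])
#' @param frame_axes optional 3x3 world axes to express components in;
#'   default: the ankle joint frame on the shank side, posed per frame
#' @return object of class `joint_load_series`: data.frame with time,
#'   stance percentage, ankle-frame components (N) and magnitude (%BW)
#' @export
joint_reaction <- function(model, states, muscle_state, id, frame_axes = NULL) {
  n <- length(states$time)
  bw <- model$patient$body_weight_N
  jrf <- matrix(0, n, 3)
  comp <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    poses <- forward_kinematics(model, states$q[i, ])
    geom <- ankle_crossing_geometry(model, poses)
    Fm <- c(0, 0, 0)
    for (mn in names(geom))
      Fm <- Fm + muscle_state$forces[i, mn] * geom[[mn]]$dir
    Fj <- id$ankle_force[i, ] - Fm
    jrf[i, ] <- Fj
    axes <- frame_axes %||% ankle_parent_axes(model, poses)
    comp[i, ] <- as.numeric(t(axes) %*% Fj)
  }
  stance_pct <- 100 * (states$time - states$time[1]) /
    max(states$time[n] - states$time[1], .Machine$double.eps)
  out <- data.frame(time = states$time, stance_pct = stance_pct,
                    jx = comp[, 1], jy = comp[, 2], jz = comp[, 3],
                    mag_bw = 100 * sqrt(rowSums(jrf^2)) / bw)
  attr(out, "world") <- jrf
  attr(out, "body_weight_N") <- bw
  class(out) <- c("joint_load_series", "data.frame")
  out
}

ankle_parent_axes <- function(model, poses) {
  poses$shank[1:3, 1:3] %*% model$joints$ankle$orientation
}

#' Pipeline configuration
#'
#' @param mode GRF segment assumption, "1SEG" or "2SEG"
#' @param axes ankle frame definition, "MR" (cylinder-based, as assembled)
#'   or "CGA" (marker-based)
#' @param reserves reserve actuators: "off", "on" or "auto"
#' @param stance_threshold vertical-force threshold (N) for stance detection
#' @param locked_dofs coordinates held constant during simulation
#' @param id_mode inverse dynamics mode
#' @param ik_weights optional named marker weights
#' @return config list
#' @export
pipeline_config <- function(mode = c("1SEG", "2SEG"), axes = c("MR", "CGA"),
                            reserves = c("auto", "off", "on"),
                            stance_threshold = 20,
                            locked_dofs = simulation_locked_dofs(),
                            id_mode = c("quasi_static", "full"),
                            ik_weights = NULL) {
  list(mode = match.arg(mode), axes = match.arg(axes),
       reserves = match.arg(reserves), stance_threshold = stance_threshold,
       locked_dofs = locked_dofs, id_mode = match.arg(id_mode),
       ik_weights = ik_weights)
}

# free coordinates for the static-optimization constraint set: everything
# unlocked except the ground-referenced pelvis residuals
so_free_dofs <- function(model) {
  tab <- model$dof_table
  setdiff(tab$name[!tab$locked], tab$name[tab$joint == "ground_pelvis"])
}

#' Run the full gait simulation pipeline
#'
#' Inverse kinematics, GRF segment assignment, inverse dynamics, moment
#' arms, static optimization and joint reaction analysis, windowed to the
#' stance phase. All intermediates are kept on the result, which makes
#' muscle-point perturbation reruns cheap (kinematics and inverse dynamics
#' are unaffected by muscle geometry and are reused).
#'
#' @param model an assembled `msk_model`
#' @param trial a walking `gait_trial`
#' @param config a [pipeline_config()]
#' @return object of class `gait_result`
#' @export
run_pipeline <- function(model, trial, config = pipeline_config()) {
  stopifnot(inherits(trial, "gait_trial"))
  model <- with_stage("axes", set_ankle_axes(model, config$axes))
  model <- with_stage("lock", set_locked(model, config$locked_dofs, TRUE, 0))

  events <- trial$events %||% with_stage("stance_detection",
    detect_stance(trial$grf, config$stance_threshold))
  mt <- trial$markers$time
  stance_frames <- which(mt >= events$foot_strike - 1e-9 &
                         mt <= events$foot_off + 1e-9)
  if (!length(stance_frames)) stop("stage 'stance_detection': empty stance window")

  states <- with_stage("inverse_kinematics",
    inverse_kinematics(model, trial$markers, weights = config$ik_weights,
                       frames = stance_frames))
  loads <- with_stage("grf_assignment",
    assign_grf(trial, model, states, config$mode))
  id <- with_stage("inverse_dynamics",
    inverse_dynamics(model, states, loads, mode = config$id_mode))

  free <- so_free_dofs(model)
  cross_any <- rownames(model$crossing)[
    rowSums(model$crossing[, unique(model$dof_table[free, "joint"]), drop = FALSE]) > 0]
  n <- length(states$time)
  R <- array(0, c(length(cross_any), length(free), n),
             dimnames = list(cross_any, free, NULL))
  with_stage("moment_arms", for (i in seq_len(n))
    R[, , i] <- moment_arms(model, states$q[i, ], muscles = cross_any, dofs = free))

  ms <- with_stage("static_optimization",
    static_optimization(R, id$tau, muscle_fmax(model)[cross_any], free,
                        reserves = config$reserves))
  full_act <- matrix(0, n, length(model$muscles),
                     dimnames = list(NULL, names(model$muscles)))
  full_act[, cross_any] <- ms$activations
  full_forces <- sweep(full_act, 2, muscle_fmax(model), "*")
  ms$activations <- full_act
  ms$forces <- full_forces

  jrf <- with_stage("joint_reaction", joint_reaction(model, states, ms, id))

  structure(list(model = model, config = config, events = events,
                 states = states, loads = loads, id = id,
                 moment_arm_array = R, so_muscles = cross_any,
                 free_dofs = free, muscle_state = ms, jrf = jrf,
                 trial_rate = trial$markers$rate),
            class = "gait_result")
}

#' Maximum isometric forces of all muscle paths
#' @param model a `msk_model`
#' @return named numeric vector (N)
#' @export
muscle_fmax <- function(model) {
  vapply(model$muscles, `[[`, numeric(1), "fmax")
}

#' @export
print.gait_result <- function(x, ...) {
  cat("<gait_result> ", x$config$mode, " / ", x$config$axes, "_axes, ",
      length(x$states$time), " stance frames\n", sep = "")
  cat(sprintf("  peak ankle JRF %.1f %%BW at %.0f%% stance; IK residual %.2f mm rms\n",
              max(x$jrf$mag_bw), x$jrf$stance_pct[which.max(x$jrf$mag_bw)],
              mean(x$states$residual_rms_mm)))
  if (x$muscle_state$reserves_used)
    cat("  note: reserve actuators were required\n")
  invisible(x)
}

#' @export
summary.gait_result <- function(object, ...) {
  print(object)
  f <- object$muscle_state$forces
  bw <- object$model$patient$body_weight_N
  peak <- sort(apply(f, 2, max), decreasing = TRUE)
  top <- utils::head(peak[peak > 1], 6)
  cat("\nPeak muscle forces (%BW):\n")
  for (nm in names(top)) cat(sprintf("  %-16s %6.1f\n", nm, 100 * top[nm] / bw))
  invisible(object)
}

#' Plot the ankle joint reaction force over stance
#' @param x a `gait_result` or `joint_load_series`
#' @param ... passed to [graphics::plot()]
#' @export
plot.gait_result <- function(x, ...) plot(x$jrf, ...)

#' @export
plot.joint_load_series <- function(x, ...) {
  graphics::plot(x$stance_pct, x$mag_bw, type = "l", lwd = 2,
                 xlab = "Stance (%)", ylab = "Ankle JRF (%BW)", ...)
  graphics::grid()
  invisible(x)
}

#' @export
print.joint_load_series <- function(x, ...) {
  cat(sprintf("<joint_load_series> %d frames, peak %.1f %%BW, mean %.1f %%BW\n",
              nrow(x), max(x$mag_bw), mean(x$mag_bw)))
  invisible(x)
}

#' Resample a stance series to 0-100% (101 points)
#' @param series a `joint_load_series` (or any data.frame with `stance_pct`)
#' @param column column to resample
#' @return numeric vector of length 101
#' @export
resample_stance <- function(series, column = "mag_bw") {
  stats::approx(series$stance_pct, series[[column]], xout = 0:100, rule = 2)$y
}

# Fast rerun after a muscle-geometry-only change: kinematics, loads and
# inverse dynamics are unchanged; only the perturbed muscles' moment-arm
# rows, the static optimization and the joint reaction are recomputed.
rerun_muscle_stages <- function(result, new_model) {
  base <- result$model
  changed <- names(new_model$muscles)[vapply(names(new_model$muscles), function(mn) {
    !isTRUE(all.equal(new_model$muscles[[mn]]$points, base$muscles[[mn]]$points,
                      tolerance = 0))
  }, logical(1))]
  if (!length(changed) &&
      identical(muscle_fmax(new_model), muscle_fmax(base))) {
    out <- result
    out$model <- new_model
    return(out)
  }
  states <- result$states
  R <- result$moment_arm_array
  n <- length(states$time)
  changed_so <- intersect(changed, result$so_muscles)
  if (length(changed_so)) {
    for (i in seq_len(n)) {
      R[changed_so, , i] <- moment_arms(new_model, states$q[i, ],
                                        muscles = changed_so,
                                        dofs = result$free_dofs)
    }
  }
  ms <- static_optimization(R, result$id$tau, muscle_fmax(new_model)[result$so_muscles],
                            result$free_dofs, reserves = result$config$reserves)
  full_act <- matrix(0, n, length(new_model$muscles),
                     dimnames = list(NULL, names(new_model$muscles)))
  full_act[, result$so_muscles] <- ms$activations
  ms$activations <- full_act
  ms$forces <- sweep(full_act, 2, muscle_fmax(new_model), "*")
  jrf <- joint_reaction(new_model, states, ms, result$id)
  out <- result
  out$model <- new_model
  out$moment_arm_array <- R
  out$muscle_state <- ms
  out$jrf <- jrf
  out
}
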