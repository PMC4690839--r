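# Ground-reaction-force segment assignment (one- and two-segment foot
# assumptions), quasi-static inverse dynamics over the joint tree, and
# tendon-excursion moment arms.

#' Assign the ground reaction force to a foot segment per frame
#'
#' Under the one-segment assumption (`"1SEG"`) the GRF is applied to the
#' hindfoot throughout stance. Under the two-segment assumption (`"2SEG"`)
#' it is applied to the hindfoot until the centre of pressure crosses the
#' metatarsophalangeal flexion/extension axis (signed distance along the
#' foot's anterior direction becomes positive), and entirely to the toe
#' segment from that frame on; the switch is latched so COP noise near the
#' axis cannot cause chattering.
#'
#' @param trial a walking `gait_trial`
#' @param model a `msk_model`
#' @param states IK result (from [inverse_kinematics()]) on the stance window
#' @param mode "1SEG" or "2SEG"
#' @return object of class `external_loads`: data.frame with one row per
#'   stance frame (time, segment, force, COP, free moment)
#' @export
assign_grf <- function(trial, model, states, mode = c("1SEG", "2SEG")) {
  mode <- match.arg(mode)
  grf <- resample_grf(trial$grf, states$time)
  n <- length(states$time)
  segment <- rep("hindfoot", n)
  if (mode == "2SEG") {
    switched <- FALSE
    for (i in seq_len(n)) {
      if (!switched) {
        cop <- grf$cop[i, ]
        if (!all(is.finite(cop))) {
          if (grf$force[i, 2] > grf$contact_threshold)
            stop("COP undefined during stance at frame ", i)
          next
        }
        poses <- forward_kinematics(model, states$q[i, ])
        mtp_origin <- tf_origin(poses$toes)
        anterior <- poses$forefoot[1:3, 1]
        if (sum((cop - mtp_origin) * anterior) > 0) switched <- TRUE
      }
      if (switched) segment[i] <- "toes"
    }
  }
  out <- data.frame(frame = states$frames, time = states$time, segment = segment,
                    fx = grf$force[, 1], fy = grf$force[, 2], fz = grf$force[, 3],
                    px = grf$cop[, 1], py = grf$cop[, 2], pz = grf$cop[, 3],
                    mx = grf$free_moment[, 1], my = grf$free_moment[, 2],
                    mz = grf$free_moment[, 3], stringsAsFactors = FALSE)
  class(out) <- c("external_loads", "data.frame")
  out
}

# subtree segments distal of each joint
joint_subtrees <- function(model) {
  lapply(stats::setNames(nm = names(model$joints)), function(jn)
    names(model$segments)[vapply(model$joint_chain, function(ch) jn %in% ch,
                                 logical(1))])
}

# per-dof world axis and point for a given pose set
dof_geometry <- function(model, q) {
  out <- vector("list", nrow(model$dof_table))
  poses <- list(ground = diag(4))
  qi <- 0L
  for (jn in model$joint_order) {
    j <- model$joints[[jn]]
    T <- poses[[j$parent]] %*% make_transform(j$orientation %||% diag(3),
                                              j$location %||% c(0, 0, 0))
    nd <- length(j$dofs)
    qj <- q[qi + seq_len(nd)]
    for (k in seq_len(nd)) {
      d <- j$dofs[[k]]
      out[[qi + k]] <- list(type = d$type,
                            axis = as.numeric(T[1:3, 1:3] %*% d$axis),
                            point = T[1:3, 4], joint = jn)
      M <- if (d$type == "rot") make_transform(axis_angle(d$axis, qj[k]))
           else make_transform(p = d$axis * qj[k])
      T <- T %*% M
    }
    if (!is.null(j$coupling)) T <- T %*% j$coupling(qj)
    poses[[j$child]] <- T
    qi <- qi + nd
  }
  list(dofs = out, poses = poses[names(model$segments)])
}

#' Inverse dynamics over the joint tree
#'
#' Computes the net generalized forces the joint actuators must produce to
#' balance the applied loads, by projecting every applied wrench (ground
#' reaction, segment weights and, in `"full"` mode, inertial wrenches from
#' numerically differentiated kinematics) onto each degree of freedom's
#' instantaneous axis. `"quasi_static"` (the default) drops all inertial
#' terms and keeps segment weights, following the free-body reasoning that
#' the ankle load during stance is dominated by the ground reaction and the
#' muscle forces balancing its moment. Also returns the ankle
#' intersegmental force (the load the shank applies to the foot free body,
#' muscles excluded).
#'
#' @param model a `msk_model`
#' @param states IK result (stance window)
#' @param loads an `external_loads` on the same time base
#' @param mode "quasi_static" or "full"
#' @param g gravitational acceleration (m/s^2)
#' @return list with `tau` (frames x nDoF), `ankle_force` (frames x 3,
#'   world), `mode`
#' @export
inverse_dynamics <- function(model, states, loads, mode = c("quasi_static", "full"),
                             g = 9.81) {
  mode <- match.arg(mode)
  if (nrow(loads) != length(states$time) ||
      max(abs(loads$time - states$time)) > 1e-9)
    stop("kinematics and external loads are not on a common time base")
  n <- length(states$time)
  tab <- model$dof_table
  subtree <- joint_subtrees(model)
  foot_segs <- subtree$ankle
  masses <- vapply(model$segments, `[[`, numeric(1), "mass")

  # segment kinematics for the inertial terms (full mode)
  acc <- NULL
  if (mode == "full") acc <- segment_accelerations(model, states)

  tau <- matrix(0, n, nrow(tab), dimnames = list(NULL, tab$name))
  ankle_force <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    geo <- dof_geometry(model, states$q[i, ])
    poses <- geo$poses
    # collect wrenches: per segment gravity (+ inertial), plus the GRF
    wr <- list()
    for (sn in names(model$segments)) {
      com_w <- tf_apply(poses[[sn]], model$segments[[sn]]$com)
      Fg <- c(0, -masses[[sn]] * g, 0)
      Mw <- c(0, 0, 0)
      if (!is.null(acc)) {
        Fg <- Fg - masses[[sn]] * acc$lin[i, sn, ]
        Iw <- poses[[sn]][1:3, 1:3] %*% model$segments[[sn]]$inertia %*%
          t(poses[[sn]][1:3, 1:3])
        om <- acc$omega[i, sn, ]
        Mw <- -(Iw %*% acc$alpha[i, sn, ] + cross3(om, as.numeric(Iw %*% om)))
      }
      wr[[length(wr) + 1]] <- list(seg = sn, F = Fg, p = com_w, M = as.numeric(Mw))
    }
    if (is.finite(loads$fy[i]) && abs(loads$fy[i]) + abs(loads$fx[i]) > 0) {
      p_app <- c(loads$px[i], loads$py[i], loads$pz[i])
      if (!all(is.finite(p_app))) p_app <- c(0, 0, 0)
      wr[[length(wr) + 1]] <- list(seg = loads$segment[i],
                                   F = c(loads$fx[i], loads$fy[i], loads$fz[i]),
                                   p = p_app,
                                   M = c(loads$mx[i], loads$my[i], loads$mz[i]))
    }
    for (jdx in seq_len(nrow(tab))) {
      d <- geo$dofs[[jdx]]
      below <- subtree[[d$joint]]
      s <- 0
      for (w in wr) {
        if (!(w$seg %in% below)) next
        s <- s + if (d$type == "rot")
          sum(d$axis * (cross3(w$p - d$point, w$F) + w$M))
        else sum(d$axis * w$F)
      }
      tau[i, jdx] <- -s
    }
    Fsum <- c(0, 0, 0)
    for (w in wr) if (w$seg %in% foot_segs) Fsum <- Fsum + w$F
    ankle_force[i, ] <- -Fsum
  }
  list(tau = tau, ankle_force = ankle_force, mode = mode)
}

# central-difference linear/angular accelerations per segment (full mode)
segment_accelerations <- function(model, states) {
  n <- length(states$time)
  segs <- names(model$segments)
  dt <- stats::median(diff(states$time))
  com <- array(0, c(n, length(segs), 3), dimnames = list(NULL, segs, NULL))
  Rs <- vector("list", n)
  for (i in seq_len(n)) {
    poses <- forward_kinematics(model, states$q[i, ])
    Rs[[i]] <- lapply(poses, function(T) T[1:3, 1:3])
    for (s in seq_along(segs))
      com[i, s, ] <- tf_apply(poses[[segs[s]]], model$segments[[segs[s]]]$com)
  }
  lin <- array(0, c(n, length(segs), 3), dimnames = list(NULL, segs, NULL))
  omega <- array(0, c(n, length(segs), 3), dimnames = list(NULL, segs, NULL))
  alpha <- array(0, c(n, length(segs), 3), dimnames = list(NULL, segs, NULL))
  for (s in segs) {
    for (i in 2:(n - 1)) {
      lin[i, s, ] <- (com[i + 1, s, ] - 2 * com[i, s, ] + com[i - 1, s, ]) / dt^2
      W <- (Rs[[i + 1]][[s]] - Rs[[i - 1]][[s]]) %*% t(Rs[[i]][[s]]) / (2 * dt)
      omega[i, s, ] <- c(W[3, 2], W[1, 3], W[2, 1])
    }
    for (i in 3:(n - 2))
      alpha[i, s, ] <- (omega[i + 1, s, ] - omega[i - 1, s, ]) / (2 * dt)
  }
  list(lin = lin, omega = omega, alpha = alpha)
}

#' Tendon-excursion moment arms
#'
#' Moment arm of muscle i about coordinate j as the negative partial
#' derivative of the muscle path length with respect to the coordinate,
#' by central finite difference. With this sign convention a plantarflexor
#' (which shortens with plantarflexion, i.e. decreasing ankle flexion
#' angle) has a negative moment arm about the dorsiflexion-positive ankle
#' flexion coordinate. Entries for muscles that do not span a coordinate's
#' joint are exactly zero.
#'
#' @param model a `msk_model`
#' @param q state vector
#' @param muscles muscle path names (default all)
#' @param dofs coordinate names (default all unlocked)
#' @param delta finite-difference step (rad or m)
#' @return muscles x dofs matrix of moment arms (m)
#' @export
moment_arms <- function(model, q, muscles = NULL, dofs = NULL, delta = 1e-5) {
  muscles <- muscles %||% names(model$muscles)
  tab <- model$dof_table
  dofs <- dofs %||% tab$name[!tab$locked]
  R <- matrix(0, length(muscles), length(dofs), dimnames = list(muscles, dofs))
  for (dn in dofs) {
    jn <- tab[tab$name == dn, "joint"]
    cross_m <- muscles[model$crossing[muscles, jn]]
    if (!length(cross_m)) next
    jdx <- match(dn, tab$name)
    qp <- q; qp[jdx] <- qp[jdx] + delta
    qm <- q; qm[jdx] <- qm[jdx] - delta
    pp <- forward_kinematics(model, qp)
    pm <- forward_kinematics(model, qm)
    for (mn in cross_m) {
      lp <- world_muscle_path(model, NULL, mn, poses = pp)$length
      lm <- world_muscle_path(model, NULL, mn, poses = pm)$length
      R[mn, dn] <- -(lp - lm) / (2 * delta)
    }
  }
  R
}
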