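# Marker-driven inverse kinematics: per frame, weighted nonlinear least
# squares of the model marker positions onto the measured trajectories over
# the unlocked coordinates (Levenberg-Marquardt), warm-started from the
# previous frame.

#' Inverse kinematics
#'
#' For each requested frame, minimizes the weighted sum of squared
#' distances between the model's markers and the measured marker positions
#' over the unlocked generalized coordinates. Locked coordinates are held
#' at their lock value. The initial guess is the solution of the previous
#' frame (first frame: the reference pose, or `q0`).
#'
#' @param model a `msk_model`
#' @param markers a `marker_trajectories`
#' @param weights optional named per-marker weights (default uniform)
#' @param frames frame indices to solve (default all)
#' @param q0 optional initial full state for the first frame
#' @return list with `q` (frames x nDoF matrix, all coordinates), `residual_rms_mm`
#'   per frame, `flagged` (frames that failed to converge and carried the
#'   previous solution), `time`
#' @export
inverse_kinematics <- function(model, markers, weights = NULL, frames = NULL,
                               q0 = NULL) {
  frames <- frames %||% seq_len(markers$frames)
  driven <- intersect(names(model$markers), markers$labels)
  if (length(driven) < 3) stop("too few model markers present in the trial")
  tab <- model$dof_table
  free <- which(!tab$locked)
  col <- match(driven, markers$labels)
  w <- rep(1, length(driven))
  if (!is.null(weights)) {
    idx <- match(driven, names(weights))
    w[!is.na(idx)] <- weights[idx[!is.na(idx)]]
  }
  sw <- sqrt(rep(w, each = 3))
  seg_of <- vapply(model$markers[driven], `[[`, character(1), "segment")
  loc <- t(vapply(model$markers[driven], `[[`, numeric(3), "p"))

  q_full <- kinematic_state(model)
  if (!is.null(q0)) q_full[] <- q0
  nq <- nrow(tab)
  Q <- matrix(NA_real_, length(frames), nq, dimnames = list(NULL, tab$name))
  rms <- numeric(length(frames))
  flagged <- integer(0)

  model_pts <- function(q) {
    poses <- forward_kinematics(model, q)
    t(vapply(seq_along(driven), function(i)
      tf_apply(poses[[seg_of[i]]], loc[i, ]), numeric(3)))
  }

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    vis <- markers$visible[f, col]
    if (3 * sum(vis) < length(free))
      stop("frame ", f, ": too few visible markers (", sum(vis),
           ") to drive ", length(free), " coordinates")
    meas <- matrix(markers$data[f, col, ], ncol = 3)
    resid <- function(qu) {
      q_full[free] <- qu
      d <- model_pts(q_full) - meas
      (sw * as.vector(t(d)))[rep(vis, each = 3)]
    }
    fit <- minpack.lm::nls.lm(q_full[free], fn = resid,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 120, ftol = 1e-15, ptol = 1e-13))
    if (fit$info %in% c(0, 5, 9) && fit$rsstrace[length(fit$rsstrace)] > 1e-8) {
      flagged <- c(flagged, f)
      warning("inverse kinematics did not converge at frame ", f,
              "; carrying the previous solution")
    } else {
      q_full[free] <- fit$par
      # canonicalize rotational coordinates: the optimizer may land on an
      # equivalent angle a multiple of 2*pi away
      rot <- free[tab$type[free] == "rot"]
      q_full[rot] <- ((q_full[rot] + pi) %% (2 * pi)) - pi
    }
    Q[fi, ] <- q_full
    d <- model_pts(q_full)[vis, , drop = FALSE] - meas[vis, , drop = FALSE]
    rms[fi] <- sqrt(mean(rowSums(d^2))) * 1000
  }
  list(q = Q, residual_rms_mm = rms, flagged = flagged,
       time = markers$time[frames], frames = frames)
}
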