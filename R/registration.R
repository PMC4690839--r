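# Closed-form least-squares rigid registration between corresponding named
# point sets (Horn's quaternion method), and the per-segment mapping of
# generic model points onto patient anatomy that is built on top of it.

#' Rigid registration of corresponding point sets (Horn's method)
#'
#' Finds the rigid transform (rotation + translation, no scale, no
#' reflection) minimizing the sum of squared distances between corresponding
#' points, using the closed-form quaternion solution. Correspondence is by
#' landmark name; at least three non-collinear common landmarks are required.
#'
#' @param source,target `landmark_set`s or named n x 3 matrices; the
#'   transform maps source points onto target points
#' @return object of class `rigid_transform`: list with `T` (4x4 homogeneous
#'   matrix), `rms_mm` (root-mean-square residual in millimetres), `names`
#'   (landmarks used)
#' @export
horn_register <- function(source, target) {
  S <- if (inherits(source, "landmark_set")) source$points else rbind(source)
  T_ <- if (inherits(target, "landmark_set")) target$points else rbind(target)
  common <- intersect(rownames(S), rownames(T_))
  if (length(common) < 3)
    stop("registration needs at least 3 common landmarks, got ", length(common))
  S <- S[common, , drop = FALSE]
  Tt <- T_[common, , drop = FALSE]

  s_bar <- colMeans(S)
  t_bar <- colMeans(Tt)
  Sc <- sweep(S, 2, s_bar)
  Tc <- sweep(Tt, 2, t_bar)
  H <- crossprod(Sc, Tc)   # sum over points of s_c t_c^T

  sv <- svd(H)$d
  if (sv[3] < 1e-10 * sv[1])
    stop("degenerate landmark configuration (collinear or rank-deficient ",
         "cross-covariance): registration is ill-posed")

  Sxx <- H[1, 1]; Sxy <- H[1, 2]; Sxz <- H[1, 3]
  Syx <- H[2, 1]; Syy <- H[2, 2]; Syz <- H[2, 3]
  Szx <- H[3, 1]; Szy <- H[3, 2]; Szz <- H[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  eig <- eigen(N, symmetric = TRUE)
  q <- eig$vectors[, 1]
  R <- quat_to_mat(q)   # maps source to target; unit quaternion => det +1

  p <- t_bar - as.numeric(R %*% s_bar)
  T4 <- make_transform(R, p)
  res <- tf_apply(T4, S) - Tt
  rms_mm <- sqrt(mean(rowSums(res^2))) * 1000

  structure(list(T = T4, rms_mm = rms_mm, names = common),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(tf_rot(x$T)) * 180 / pi
  tr <- tf_origin(x$T)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.4f, %.4f, %.4f) m\n",
              ang, tr[1], tr[2], tr[3]))
  cat(sprintf("  fitted on %d landmarks, rms %.4f mm\n", length(x$names), x$rms_mm))
  invisible(x)
}

#' Map generic model points onto patient anatomy, segment by segment
#'
#' Computes one Horn transform per segment from the named landmark
#' correspondences between the generic model and the patient, and applies
#' that segment's transform to the generic points belonging to it. This is
#' how generic muscle attachment and via points are carried onto the
#' patient-specific bone geometry.
#'
#' @param generic_landmarks,patient_landmarks `landmark_set`s with segment
#'   tags; correspondence is by landmark name within each segment
#' @param generic_points n x 3 matrix of points to map
#' @param point_segment character vector assigning each point to a segment
#' @return list with `points` (mapped n x 3 matrix), `transforms` (named list
#'   of `rigid_transform` per segment), `rms_mm` (named residual vector)
#' @export
map_generic_points <- function(generic_landmarks, patient_landmarks,
                               generic_points, point_segment) {
  generic_points <- rbind(generic_points)
  point_segment <- rep_len(point_segment, nrow(generic_points))
  segs <- unique(point_segment)
  transforms <- list()
  mapped <- generic_points
  for (s in segs) {
    gi <- which(generic_landmarks$segment == s)
    if (!length(gi)) stop("no generic landmarks for segment '", s, "'")
    g <- landmark_set(generic_landmarks$points[gi, , drop = FALSE],
                      rownames(generic_landmarks$points)[gi], s)
    tr <- horn_register(g, patient_landmarks)
    transforms[[s]] <- tr
    idx <- point_segment == s
    mapped[idx, ] <- tf_apply(tr$T, generic_points[idx, , drop = FALSE])
  }
  list(points = mapped, transforms = transforms,
       rms_mm = vapply(transforms, `[[`, numeric(1), "rms_mm"))
}
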