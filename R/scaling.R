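# Generic-to-patient scaling of the proximal segments (pelvis, femur,
# shank) from the averaged static trial, and the full marker/MRI
# registration chain that assembles the hybrid patient-specific model.

#' Average a static (standing) trial in time
#'
#' Per-marker mean over the frames in which the marker is visible; markers
#' visible in fewer than half of the frames are rejected.
#'
#' @param trial a `gait_trial` of kind "static" (or a `marker_trajectories`)
#' @param required markers that must be present (default: all labels)
#' @return object of class `static_summary`: named positions (m), duration,
#'   frame count
#' @export
average_static_trial <- function(trial, required = NULL) {
  mk <- if (inherits(trial, "gait_trial")) trial$markers else trial
  required <- required %||% mk$labels
  missing <- setdiff(required, mk$labels)
  if (length(missing)) stop("required markers absent from the static trial: ",
                            paste(missing, collapse = ", "))
  frac <- colMeans(mk$visible)
  bad <- mk$labels[frac < 0.5 & mk$labels %in% required]
  if (length(bad)) stop("markers visible in fewer than half the frames: ",
                        paste(bad, collapse = ", "))
  pts <- t(vapply(seq_along(mk$labels), function(j) {
    vis <- mk$visible[, j]
    colMeans(mk$data[vis, j, , drop = FALSE], na.rm = TRUE)
  }, numeric(3)))
  lms <- landmark_set(pts, mk$labels, source = "static")
  structure(list(points = lms, duration = diff(range(mk$time)),
                 frames = mk$frames),
            class = "static_summary")
}

#' @export
print.static_summary <- function(x, ...) {
  cat(sprintf("<static_summary> %d markers averaged over %d frames (%.2f s)\n",
              length(x$points), x$frames, x$duration))
  invisible(x)
}

#' Anthropometric scale factors from static markers
#'
#' Pelvis: depth (mid-ASIS to mid-PSIS), height (mean of the four
#' ASIS/PSIS points to the mid greater trochanters), width (mid right
#' ASIS/PSIS to mid left ASIS/PSIS). Femur: greater trochanter to
#' mid femoral epicondyles. Shank: mid epicondyles to mid malleoli.
#' Each factor is the patient distance over the generic distance.
#'
#' @param generic named positions of the generic model's markers in the
#'   reference pose (a `landmark_set`, e.g. from [model_marker_world()])
#' @param patient_static a `static_summary`
#' @return object of class `scale_factors`
#' @export
compute_scale_factors <- function(generic, patient_static) {
  pat <- patient_static$points
  need <- c("RASI", "LASI", "RPSI", "LPSI", "RGTR", "LGTR",
            "RKNE", "RKNM", "RANK", "RMMA")
  for (set in list(generic, pat)) {
    missing <- setdiff(need, names(set))
    if (length(missing)) stop("markers required for scaling are missing: ",
                              paste(missing, collapse = ", "))
  }
  dims <- function(s) {
    g <- function(n) lm_point(s, n)
    mid_asis <- (g("RASI") + g("LASI")) / 2
    mid_psis <- (g("RPSI") + g("LPSI")) / 2
    mean_ap <- (g("RASI") + g("LASI") + g("RPSI") + g("LPSI")) / 4
    mid_gt <- (g("RGTR") + g("LGTR")) / 2
    mid_epi <- (g("RKNE") + g("RKNM")) / 2
    mid_mal <- (g("RANK") + g("RMMA")) / 2
    d <- function(a, b) sqrt(sum((a - b)^2))
    c(depth = d(mid_asis, mid_psis),
      height = d(mean_ap, mid_gt),
      width = d((g("RASI") + g("RPSI")) / 2, (g("LASI") + g("LPSI")) / 2),
      femur = d(g("RGTR"), mid_epi),
      shank = d(mid_epi, mid_mal))
  }
  dg <- dims(generic)
  if (any(dg <= 1e-12)) stop("zero generic distance in scaling dimensions")
  r <- dims(pat) / dg
  structure(list(pelvis = r[c("depth", "height", "width")],
                 femur = unname(r["femur"]), shank = unname(r["shank"])),
            class = "scale_factors")
}

#' @export
print.scale_factors <- function(x, ...) {
  cat(sprintf("<scale_factors> pelvis (depth %.3f, height %.3f, width %.3f), femur %.3f, shank %.3f\n",
              x$pelvis[1], x$pelvis[2], x$pelvis[3], x$femur, x$shank))
  invisible(x)
}

#' Apply scale factors to a model
#'
#' Scales the segment-local geometry (muscle and ligament points, markers,
#' landmarks, centre of mass, child-joint locations) of the pelvis
#' anisotropically by (depth, height, width) along its (anterior, vertical,
#' lateral) axes, and the femur and shank isotropically by their length
#' ratios. Segment masses are by default redistributed so the template's
#' mass proportions are preserved at the patient's body mass
#' (`mass_mode = "preserve"`); `mass_mode = "cubic"` instead multiplies the
#' scaled segments' masses by their volume ratio.
#'
#' @param model a `msk_model`
#' @param s a `scale_factors`
#' @param mass_mode "preserve" or "cubic"
#' @param patient optional patient metadata ([patient_meta()]) installed on
#'   the scaled model
#' @return scaled `msk_model`
#' @export
apply_scaling <- function(model, s, mass_mode = c("preserve", "cubic"),
                          patient = NULL) {
  mass_mode <- match.arg(mass_mode)
  if (any(unlist(s[c("pelvis", "femur", "shank")]) <= 0))
    stop("scale factors must be positive")
  fac <- list(pelvis = as.numeric(s$pelvis),
              femur = rep(s$femur, 3), shank = rep(s$shank, 3))
  scale_pt <- function(seg, p) if (seg %in% names(fac)) p * fac[[seg]] else p

  for (sn in names(fac)) {
    if (is.null(model$segments[[sn]])) next
    model$segments[[sn]]$com <- model$segments[[sn]]$com * fac[[sn]]
  }
  for (jn in names(model$joints)) {
    par <- model$joints[[jn]]$parent
    model$joints[[jn]]$location <- scale_pt(par, model$joints[[jn]]$location)
  }
  for (mn in names(model$muscles))
    model$muscles[[mn]]$points <- lapply(model$muscles[[mn]]$points, function(pt) {
      pt$p <- scale_pt(pt$segment, pt$p); pt
    })
  for (ln in seq_along(model$ligaments))
    model$ligaments[[ln]]$points <- lapply(model$ligaments[[ln]]$points, function(pt) {
      pt$p <- scale_pt(pt$segment, pt$p); pt
    })
  for (mk in names(model$markers))
    model$markers[[mk]]$p <- scale_pt(model$markers[[mk]]$segment, model$markers[[mk]]$p)
  for (lm in names(model$landmarks))
    model$landmarks[[lm]]$p <- scale_pt(model$landmarks[[lm]]$segment, model$landmarks[[lm]]$p)

  if (!is.null(patient)) model$patient <- patient
  if (mass_mode == "cubic") {
    for (sn in names(fac))
      if (!is.null(model$segments[[sn]]))
        model$segments[[sn]]$mass <- model$segments[[sn]]$mass * prod(fac[[sn]])
  } else {
    # preserve the template's segment-mass proportions at the patient mass
    ratio <- model$patient$mass_kg / 75
    for (sn in names(model$segments))
      model$segments[[sn]]$mass <- model$segments[[sn]]$mass * ratio
  }
  rebuild_model_tables(model)
}

#' Register the averaged static foot markers onto the MRI marker replicas
#'
#' Rigid (Horn) registration from the time-averaged static gait markers of
#' the foot — including the malleoli — to the corresponding radio-opaque
#' marker replicas identified in the MRI scan. Assumes the foot was rigidly
#' transformed between the scan and the standing trial; the residual is the
#' cost of that assumption and is reported.
#'
#' @param static a `static_summary`
#' @param mri_markers `landmark_set` of the MRI marker replicas
#' @return a `rigid_transform` (static -> MRI)
#' @export
register_foot_to_mri <- function(static, mri_markers) {
  horn_register(static$points, mri_markers)
}

#' The six foot gait markers replicated in the MRI scan
#'
#' Lateral malleolus, medial malleolus, head of the fifth metatarsal,
#' between the second and third metatarsal heads, head of the first
#' metatarsal and base of the hallux.
#'
#' @return character vector of marker names
#' @export
mri_replica_markers <- function() c("RANK", "RMMA", "RP5M", "RTOE", "RP1M", "RHLX")

#' Optimal femur rotation about the knee flexion axis
#'
#' Rotates the palpated greater trochanter about the knee flexion/extension
#' axis until its distance to the greater trochanter gait marker is
#' minimal. Solved by bounded scalar minimization (Brent) on a bracket
#' found by a coarse grid, to 1e-8 rad.
#'
#' @param gt_palpated palpated greater trochanter (3-vector, model space)
#' @param gt_marker greater trochanter gait marker (3-vector, model space)
#' @param axis_point point on the knee flexion axis
#' @param axis_dir knee flexion axis direction
#' @return list with `angle` (rad) and `distance` (residual, m)
#' @export
optimize_femur_rotation <- function(gt_palpated, gt_marker, axis_point, axis_dir) {
  u <- unit(axis_dir)
  rel <- gt_palpated - axis_point
  radial <- rel - sum(rel * u) * u
  if (sqrt(sum(radial^2)) < 1e-9)
    stop("degenerate geometry: palpated greater trochanter lies on the knee axis")
  dist2 <- function(th) {
    p <- axis_point + as.numeric(axis_angle(u, th) %*% rel)
    sum((p - gt_marker)^2)
  }
  grid <- seq(-pi, pi, by = pi / 180)
  th0 <- grid[which.min(vapply(grid, dist2, numeric(1)))]
  opt <- stats::optimize(dist2, interval = c(th0 - pi / 90, th0 + pi / 90),
                         tol = 1e-10)
  list(angle = opt$minimum, distance = sqrt(opt$objective))
}

rotate_segment_geometry <- function(model, segment, axis_point, axis_dir, angle) {
  R <- axis_angle(axis_dir, angle)
  rot <- function(p) axis_point + as.numeric(R %*% (p - axis_point))
  for (mk in names(model$markers))
    if (model$markers[[mk]]$segment == segment)
      model$markers[[mk]]$p <- rot(model$markers[[mk]]$p)
  for (lm in names(model$landmarks))
    if (model$landmarks[[lm]]$segment == segment)
      model$landmarks[[lm]]$p <- rot(model$landmarks[[lm]]$p)
  for (mn in names(model$muscles))
    model$muscles[[mn]]$points <- lapply(model$muscles[[mn]]$points, function(pt) {
      if (pt$segment == segment) pt$p <- rot(pt$p)
      pt
    })
  model
}
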