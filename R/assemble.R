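# Assembly of the hybrid patient-specific model: anthropometric scaling of
# the proximal segments, per-segment registration of the generic foot onto
# the patient's segmented geometry, cylinder-based ankle frame, marker
# registration chain and femur rotation adjustment. Each stage is callable
# standalone; failures are labelled with their stage name and every
# transform/residual is logged in the provenance.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

#' Assemble a patient-specific model
#'
#' Runs the patient-specific modelling chain on a generic template:
#' (1) time-average the static trial; (2) compute and apply the
#' pelvis/femur/shank scale factors; (3) register the averaged static foot
#' markers onto the MRI marker replicas; (4) register each foot segment's
#' generic landmarks onto the virtually palpated patient landmarks (Horn,
#' per segment) and carry the generic muscle attachment/via points with
#' them; (5) fit a cylinder to the talar dome and redefine the ankle joint
#' centre and flexion axis from it; (6) register the leg and pelvis markers;
#' (7) rotate the femur about the knee flexion axis until the palpated and
#' marker greater trochanters are closest.
#'
#' @param template a `msk_model` (the generic template)
#' @param patient list with `landmarks` (`landmark_set`, MRI space, segment
#'   tags for hindfoot/talus/forefoot/toes/shank), `dome_points` (n x 3, MRI
#'   space), `static` (a static `gait_trial`), `mri_markers`
#'   (`landmark_set`, the six replicated foot markers in MRI space), `meta`
#'   ([patient_meta()])
#' @return hybrid `msk_model` with a `provenance` attribute: one record per
#'   stage with the transform and residual (mm)
#' @export
assemble_patient_model <- function(template, patient) {
  prov <- list()
  log_stage <- function(name, transform = NULL, rms_mm = NA_real_, note = "") {
    prov[[length(prov) + 1]] <<- list(stage = name, transform = transform,
                                      rms_mm = rms_mm, note = note)
  }
  for (fld in c("landmarks", "dome_points", "static", "mri_markers"))
    if (is.null(patient[[fld]]))
      stop("stage 'inputs': patient input '", fld, "' is missing")

  static <- with_stage("static_average", average_static_trial(patient$static))
  log_stage("static_average", note = sprintf("%d frames", static$frames))

  model <- with_stage("scaling", {
    generic <- model_marker_world(template)
    s <- compute_scale_factors(generic, static)
    m <- apply_scaling(template, s, patient = patient$meta %||% template$patient)
    log_stage("scaling", note = sprintf(
      "pelvis (%.3f, %.3f, %.3f), femur %.3f, shank %.3f",
      s$pelvis[1], s$pelvis[2], s$pelvis[3], s$femur, s$shank))
    m
  })

  T_foot <- with_stage("foot_mri_registration", {
    tr <- register_foot_to_mri(static, patient$mri_markers)
    log_stage("foot_mri_registration", tr$T, tr$rms_mm)
    tr
  })

  ref <- forward_kinematics(model, kinematic_state(model))
  gen_lm <- model_landmark_world(model, poses = ref)

  seg_tf <- with_stage("foot_segment_registration", {
    out <- list()
    for (sn in c("shank", "hindfoot", "talus", "forefoot", "toes")) {
      gi <- which(gen_lm$segment == sn)
      g <- landmark_set(gen_lm$points[gi, , drop = FALSE],
                        names(gen_lm)[gi], sn)
      tr <- horn_register(g, patient$landmarks)
      log_stage(paste0("register_", sn), tr$T, tr$rms_mm)
      out[[sn]] <- tr
    }
    out
  })

  ankle_mr <- with_stage("cylinder_fit", {
    hint <- lm_point(patient$mri_markers, "RANK") -
      lm_point(patient$mri_markers, "RMMA")
    cyl <- fit_cylinder(patient$dome_points, lateral_hint = hint)
    kjc_mri <- tf_apply(seg_tf$shank$T,
                        tf_apply(ref$shank, lm_point_local(model, "KJC")))
    fr <- ankle_frame_mr(cyl, kjc_mri)
    log_stage("cylinder_fit", frame_to_transform(fr), cyl$rms_mm,
              sprintf("radius %.4f m", cyl$radius))
    list(cylinder = cyl, frame = fr)
  })

  model <- with_stage("foot_reanchoring",
                      reanchor_foot(model, ref, seg_tf, ankle_mr$frame,
                                    patient$landmarks, patient$mri_markers))

  # the femur is carried into MRI space with the shank's transform (knee at
  # the reference angle); the condyle targets of the leg registration and
  # the palpated greater trochanter live in that space
  femur_mri <- seg_tf$shank$T %*% ref$femur
  T_leg <- with_stage("leg_registration", {
    src <- static$points[c("RANK", "RMMA", "RKNE", "RKNM")]
    tgt_pts <- rbind(lm_point(patient$mri_markers, "RANK"),
                     lm_point(patient$mri_markers, "RMMA"),
                     tf_apply(femur_mri, lm_point_local(model, "FEM_COND_LAT")),
                     tf_apply(femur_mri, lm_point_local(model, "FEM_COND_MED")))
    tgt <- landmark_set(tgt_pts, c("RANK", "RMMA", "RKNE", "RKNM"), source = "mixed")
    tr <- horn_register(src, tgt)
    log_stage("leg_registration", tr$T, tr$rms_mm)
    tr
  })

  model <- with_stage("femur_rotation", {
    gt_palp <- tf_apply(femur_mri, lm_point_local(model, "GT_PALP"))
    gt_marker <- tf_apply(T_leg$T, lm_point(static$points, "RGTR"))
    knee <- model$joints$knee
    axis_world <- tf_rot(femur_mri) %*% (knee$orientation %*% knee$dofs[[1]]$axis)
    res <- optimize_femur_rotation(gt_palp, gt_marker,
                                   tf_apply(femur_mri, knee$location),
                                   as.numeric(axis_world))
    log_stage("femur_rotation", rms_mm = res$distance * 1000,
              note = sprintf("angle %.4f rad", res$angle))
    rotate_segment_geometry(model, "femur", knee$location,
                            as.numeric(knee$orientation %*% knee$dofs[[1]]$axis),
                            res$angle)
  })

  T_pelvis <- with_stage("pelvis_registration", {
    src <- static$points[c("RASI", "LASI", "RPSI", "LPSI")]
    gen <- model_marker_world(model, poses = ref)
    tr <- horn_register(src, gen[c("RASI", "LASI", "RPSI", "LPSI")])
    log_stage("pelvis_registration", tr$T, tr$rms_mm)
    tr
  })

  model <- rebuild_model_tables(model)
  model$ankle_mr <- ankle_mr
  model$gait_to_model <- T_pelvis$T
  attr(model, "provenance") <- prov
  model$name <- paste0(template$name, " (patient-specific)")
  model
}

lm_point_local <- function(model, name) {
  lm <- model$landmarks[[name]]
  if (is.null(lm)) stop("model landmark not found: ", name)
  lm$p
}

# Re-express the foot subtree in patient geometry: the ankle joint frame is
# replaced by the cylinder-based frame; each foot segment's geometry is
# mapped by its registration transform and re-expressed in its new frame.
reanchor_foot <- function(model, ref, seg_tf, ankle_frame, patient_landmarks,
                          mri_markers) {
  G <- frame_to_transform(ankle_frame)      # new hindfoot/talus world pose (MRI)
  B_shank <- seg_tf$shank$T %*% ref$shank   # patient shank pose in MRI
  M <- seg_tf$forefoot$T %*% ref$forefoot   # patient forefoot pose in MRI
  P <- seg_tf$toes$T %*% ref$toes           # patient toes pose in MRI

  new_pose <- list(shank = B_shank, hindfoot = G, talus = G, forefoot = M, toes = P)

  # ankle joint in the (scaled) shank frame
  rel <- tf_inv(B_shank) %*% G
  model$joints$ankle$location <- tf_origin(rel)
  model$joints$ankle$orientation <- tf_rot(rel)
  # hindfoot -> forefoot and forefoot -> toes joints
  relm <- tf_inv(G) %*% M
  model$joints$midfoot$location <- tf_origin(relm)
  model$joints$midfoot$orientation <- tf_rot(relm)
  relp <- tf_inv(M) %*% P
  model$joints$mtp$location <- tf_origin(relp)
  model$joints$mtp$orientation <- tf_rot(relp)

  # carry geometry: world (reference) -> patient MRI -> new local frame
  remap <- function(seg, p_local) {
    x_mri <- tf_apply(seg_tf[[seg]]$T, tf_apply(ref[[seg]], p_local))
    tf_apply(tf_inv(new_pose[[seg]]), x_mri)
  }
  foot_segs <- c("hindfoot", "talus", "forefoot", "toes")
  for (mn in names(model$muscles))
    model$muscles[[mn]]$points <- lapply(model$muscles[[mn]]$points, function(pt) {
      if (pt$segment %in% foot_segs) pt$p <- remap(pt$segment, pt$p)
      pt
    })
  for (ln in seq_along(model$ligaments))
    model$ligaments[[ln]]$points <- lapply(model$ligaments[[ln]]$points, function(pt) {
      if (pt$segment %in% foot_segs) pt$p <- remap(pt$segment, pt$p)
      pt
    })

  # patient landmarks (MRI space) become the model's landmarks on the foot
  for (lm in names(model$landmarks)) {
    seg <- model$landmarks[[lm]]$segment
    if (seg %in% foot_segs) {
      if (lm %in% names(patient_landmarks)) {
        x_mri <- lm_point(patient_landmarks, lm)
        model$landmarks[[lm]]$p <- tf_apply(tf_inv(new_pose[[seg]]), x_mri)
      } else {
        model$landmarks[[lm]]$p <- remap(seg, model$landmarks[[lm]]$p)
      }
    }
  }

  # MRI marker replicas define the foot marker positions
  owner <- c(RANK = "shank", RMMA = "shank", RP5M = "forefoot",
             RTOE = "forefoot", RP1M = "forefoot", RHLX = "toes")
  for (mk in names(owner)) {
    if (!(mk %in% names(mri_markers))) next
    x_mri <- lm_point(mri_markers, mk)
    model$markers[[mk]]$p <- tf_apply(tf_inv(new_pose[[owner[[mk]]]]), x_mri)
  }
  # remaining foot markers follow their segment registration
  for (mk in names(model$markers)) {
    seg <- model$markers[[mk]]$segment
    if (seg %in% foot_segs && !(mk %in% names(owner)))
      model$markers[[mk]]$p <- remap(seg, model$markers[[mk]]$p)
  }
  model
}

#' Replace the ankle joint frame by a marker-based (CGA) definition
#'
#' Re-parameterizes the ankle joint using the frame built from the model's
#' own malleoli markers and knee joint centre (the marker-based recipe),
#' preserving the world-space geometry of the foot: the joint centre moves
#' to the inter-malleolar midpoint and the flexion/inversion/rotation axes
#' become the marker-based axes. With `axes = "MR"` the model is returned
#' unchanged.
#'
#' @param model a `msk_model`
#' @param axes "MR" or "CGA"
#' @return a `msk_model`
#' @export
set_ankle_axes <- function(model, axes = c("MR", "CGA")) {
  axes <- match.arg(axes)
  if (axes == "MR") return(model)
  ref <- forward_kinematics(model, kinematic_state(model))
  mall_lat <- tf_apply(ref$shank, model$markers$RANK$p)
  mall_med <- tf_apply(ref$shank, model$markers$RMMA$p)
  kjc <- tf_apply(ref$shank, lm_point_local(model, "KJC"))
  fr <- ankle_frame_cga(mall_lat, mall_med, kjc)
  G_new <- frame_to_transform(fr)

  H_old <- ref$hindfoot
  rel <- tf_inv(ref$shank) %*% G_new
  model$joints$ankle$location <- tf_origin(rel)
  model$joints$ankle$orientation <- tf_rot(rel)
  relm <- tf_inv(G_new) %*% ref$forefoot
  model$joints$midfoot$location <- tf_origin(relm)
  model$joints$midfoot$orientation <- tf_rot(relm)

  move <- tf_inv(G_new) %*% H_old   # old hindfoot local -> new local
  upd <- function(p) tf_apply(move, p)
  for (mn in names(model$muscles))
    model$muscles[[mn]]$points <- lapply(model$muscles[[mn]]$points, function(pt) {
      if (pt$segment %in% c("hindfoot", "talus")) pt$p <- upd(pt$p)
      pt
    })
  for (ln in seq_along(model$ligaments))
    model$ligaments[[ln]]$points <- lapply(model$ligaments[[ln]]$points, function(pt) {
      if (pt$segment %in% c("hindfoot", "talus")) pt$p <- upd(pt$p)
      pt
    })
  for (mk in names(model$markers))
    if (model$markers[[mk]]$segment %in% c("hindfoot", "talus"))
      model$markers[[mk]]$p <- upd(model$markers[[mk]]$p)
  for (lm in names(model$landmarks))
    if (model$landmarks[[lm]]$segment %in% c("hindfoot", "talus"))
      model$landmarks[[lm]]$p <- upd(model$landmarks[[lm]]$p)
  model$ankle_axes_mode <- "CGA"
  model$ankle_cga_frame <- fr
  rebuild_model_tables(model)
}

#' Provenance log of an assembled model
#' @param model a `msk_model` from [assemble_patient_model()]
#' @return data.frame with stage, residual (mm) and notes
#' @export
provenance <- function(model) {
  prov <- attr(model, "provenance")
  if (is.null(prov)) return(NULL)
  data.frame(stage = vapply(prov, `[[`, character(1), "stage"),
             rms_mm = vapply(prov, function(p) p$rms_mm %||% NA_real_, numeric(1)),
             note = vapply(prov, function(p) p$note %||% "", character(1)),
             stringsAsFactors = FALSE)
}
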