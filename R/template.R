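# The packaged generic lower-limb template with a three-segment foot
# (hindfoot, forefoot, toes, plus a talus welded to the hindfoot carrying the
# dome articular surface). Seventeen DoF: 6 pelvis, 3 hip, 1 knee, 3 ankle,
# 3 hindfoot/forefoot, 1 forefoot/toes. Fifty-four muscle paths describe 39
# distinct muscles, 16 of which cross the ankle or the internal foot joints;
# seven ankle/foot ligaments are carried as inert records. Maximum isometric
# forces and inertial parameters are literature-plausible placeholder values
# shipped as configuration, not measured quantities.

seg_ <- function(name, mass, com, inertia_diag) {
  list(name = name, mass = mass, com = com, inertia = diag(inertia_diag))
}

jnt_ <- function(name, parent, child, location, dofs, orientation = diag(3),
                 coupling = NULL) {
  list(name = name, parent = parent, child = child, location = location,
       orientation = orientation, dofs = dofs, coupling = coupling)
}

dof_ <- function(name, type, axis) list(name = name, type = type, axis = axis,
                                        locked = FALSE, lock_value = 0)

mp_ <- function(name, muscle, fmax, crosses, ...) {
  pts <- lapply(list(...), function(p) list(segment = p[[1]], p = p[[2]]))
  list(name = name, muscle = muscle, fmax = fmax, crosses_ankle = crosses,
       points = pts)
}

lig_ <- function(name, ...) {
  pts <- lapply(list(...), function(p) list(segment = p[[1]], p = p[[2]]))
  list(name = name, points = pts, active = FALSE)
}

mk_ <- function(name, segment, p) list(name = name, segment = segment, p = p)

#' Knee coupling hook for polynomial derived motions
#'
#' Returns a joint coupling function mapping the primary knee flexion angle
#' to derived translations and rotations, each a polynomial in the flexion
#' angle (coefficients in increasing powers, angle in radians). Intended for
#' user-supplied regression coefficients of the kind used for knee
#' anterior/posterior and medial/lateral translation and internal/external
#' and varus/valgus rotation; the default template uses no coupling.
#'
#' @param tx,ty,tz polynomial coefficients for the translations (m)
#' @param rx,ry polynomial coefficients for varus/valgus and
#'   internal/external rotation (rad)
#' @return function(q) -> 4x4 transform, usable as a joint `coupling`
#' @export
make_polynomial_coupling <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0) {
  pol <- function(cf, q) sum(cf * q^(seq_along(cf) - 1))
  function(q) {
    q1 <- q[1]
    R <- rot_x(pol(rx, q1)) %*% rot_y(pol(ry, q1))
    make_transform(R, c(pol(tx, q1), pol(ty, q1), pol(tz, q1)))
  }
}

#' Default landmark dictionaries for the foot and distal shank
#'
#' Named virtual-palpation landmarks per segment used for the generic-to-
#' patient registration: hindfoot 10, talus 6, metatarsal (forefoot) 15,
#' toe 17, plus a distal-shank set. Names and positions are the package's
#' documented defaults and can be overridden by a JSON landmark file.
#'
#' @return named list (by segment) of character vectors of landmark names
#' @export
default_landmark_dictionaries <- function() {
  lm <- template_landmarks()
  segs <- vapply(lm, `[[`, character(1), "segment")
  nms <- vapply(lm, `[[`, character(1), "name")
  out <- split(nms, segs)
  out[c("hindfoot", "talus", "forefoot", "toes", "shank")]
}

template_landmarks <- function() {
  L <- function(name, segment, p) list(name = name, segment = segment, p = p)
  c(
    # hindfoot (calcaneus): 10
    list(
      L("CAL_TUBER_POST", "hindfoot", c(-0.075, -0.045, 0.000)),
      L("CAL_TUBER_MED",  "hindfoot", c(-0.065, -0.055, -0.020)),
      L("CAL_TUBER_LAT",  "hindfoot", c(-0.062, -0.052, 0.022)),
      L("SUSTENTACULUM",  "hindfoot", c(-0.010, -0.035, -0.030)),
      L("PERONEAL_TROCHLEA", "hindfoot", c(-0.005, -0.045, 0.035)),
      L("CAL_ANT_SUP",    "hindfoot", c(0.035, -0.020, 0.010)),
      L("CAL_ANT_INF",    "hindfoot", c(0.035, -0.050, 0.005)),
      L("CAL_DORSAL",     "hindfoot", c(-0.030, -0.010, 0.005)),
      L("CAL_PLANTAR_MED", "hindfoot", c(-0.030, -0.060, -0.015)),
      L("CAL_PLANTAR_LAT", "hindfoot", c(-0.025, -0.058, 0.020))),
    # talus: 6
    list(
      L("TAL_HEAD",      "talus", c(0.035, -0.010, -0.008)),
      L("TAL_NECK_SUP",  "talus", c(0.020, 0.005, 0.000)),
      L("TAL_DOME_MED",  "talus", c(0.000, 0.018, -0.012)),
      L("TAL_DOME_LAT",  "talus", c(0.000, 0.018, 0.012)),
      L("TAL_POST_PROC", "talus", c(-0.025, -0.005, 0.002)),
      L("TAL_LAT_PROC",  "talus", c(-0.002, -0.012, 0.025))),
    # metatarsal segment (forefoot): 15
    list(
      L("MT1_BASE", "forefoot", c(0.010, -0.030, -0.030)),
      L("MT2_BASE", "forefoot", c(0.015, -0.022, -0.008)),
      L("MT3_BASE", "forefoot", c(0.015, -0.024, 0.008)),
      L("MT4_BASE", "forefoot", c(0.012, -0.028, 0.022)),
      L("MT5_BASE", "forefoot", c(0.010, -0.035, 0.038)),
      L("MT1_HEAD", "forefoot", c(0.095, -0.035, -0.033)),
      L("MT2_HEAD", "forefoot", c(0.100, -0.025, -0.010)),
      L("MT3_HEAD", "forefoot", c(0.100, -0.027, 0.006)),
      L("MT4_HEAD", "forefoot", c(0.095, -0.030, 0.022)),
      L("MT5_HEAD", "forefoot", c(0.088, -0.038, 0.040)),
      L("NAVICULAR_TUB", "forefoot", c(0.000, -0.020, -0.028)),
      L("CUBOID_TUB",    "forefoot", c(0.005, -0.040, 0.030)),
      L("CUNEIFORM_MED", "forefoot", c(0.015, -0.012, -0.022)),
      L("CUNEIFORM_INT", "forefoot", c(0.018, -0.010, -0.005)),
      L("CUNEIFORM_LAT", "forefoot", c(0.018, -0.012, 0.010))),
    # toes: 17
    list(
      L("PP1_BASE", "toes", c(0.005, -0.012, -0.022)),
      L("PP1_HEAD", "toes", c(0.030, -0.012, -0.020)),
      L("DP1_TIP",  "toes", c(0.055, -0.014, -0.020)),
      L("SES_MED",  "toes", c(0.000, -0.020, -0.028)),
      L("SES_LAT",  "toes", c(0.000, -0.020, -0.016)),
      L("PP2_BASE", "toes", c(0.005, -0.008, -0.002)),
      L("PP2_HEAD", "toes", c(0.028, -0.010, 0.000)),
      L("DP2_TIP",  "toes", c(0.050, -0.012, 0.000)),
      L("PP3_BASE", "toes", c(0.004, -0.010, 0.010)),
      L("PP3_HEAD", "toes", c(0.026, -0.012, 0.012)),
      L("DP3_TIP",  "toes", c(0.045, -0.014, 0.012)),
      L("PP4_BASE", "toes", c(0.003, -0.012, 0.020)),
      L("PP4_HEAD", "toes", c(0.022, -0.014, 0.022)),
      L("DP4_TIP",  "toes", c(0.040, -0.016, 0.022)),
      L("PP5_BASE", "toes", c(0.002, -0.015, 0.030)),
      L("PP5_HEAD", "toes", c(0.020, -0.016, 0.032)),
      L("DP5_TIP",  "toes", c(0.035, -0.018, 0.032))),
    # distal shank (for the shank registration) + knee centre + palpated
    # femoral points used by the leg/pelvis registration chain
    list(
      L("TIB_DIST_ANT",   "shank", c(0.020, -0.380, -0.010)),
      L("TIB_DIST_MED",   "shank", c(0.010, -0.390, -0.035)),
      L("FIB_DIST_LAT",   "shank", c(-0.002, -0.400, 0.047)),
      L("TIB_SHAFT_DIST", "shank", c(0.015, -0.320, -0.020)),
      L("FIB_SHAFT_DIST", "shank", c(-0.005, -0.330, 0.042)),
      L("KJC",            "shank", c(0.000, 0.000, 0.000)),
      L("FEM_COND_MED",   "femur", c(0.000, -0.420, -0.050)),
      L("FEM_COND_LAT",   "femur", c(0.000, -0.420, 0.050)),
      L("GT_PALP",        "femur", c(-0.010, -0.020, 0.062)),
      L("RASI_P", "pelvis", c(0.120, 0.020, 0.120)),
      L("LASI_P", "pelvis", c(0.118, 0.024, -0.120)),
      L("RPSI_P", "pelvis", c(-0.050, 0.032, 0.050)),
      L("LPSI_P", "pelvis", c(-0.052, 0.028, -0.050)))
  )
}

#' The packaged generic template configuration
#'
#' Returns the configuration list consumed by [build_template()]. Geometry
#' is in metres in segment frames (X anterior, Y up, Z lateral, right side);
#' the hindfoot frame originates at the ankle joint centre, the forefoot at
#' the hindfoot/forefoot joint and the toes at the metatarsophalangeal
#' joint. The talar dome is described by a cylinder of radius 0.02 m whose
#' axis is the reference ankle flexion axis.
#'
#' @return template configuration list
#' @export
default_template_config <- function() {
  segments <- list(
    seg_("pelvis",  11.80, c(-0.010, 0.000, 0.000), c(0.080, 0.090, 0.070)),
    seg_("femur",    7.50, c(0.000, -0.180, 0.000), c(0.120, 0.030, 0.120)),
    seg_("shank",    3.49, c(0.000, -0.170, 0.000), c(0.050, 0.008, 0.050)),
    seg_("talus",    0.10, c(0.005, 0.000, 0.000),  c(0.0002, 0.0002, 0.0002)),
    seg_("hindfoot", 0.70, c(-0.020, -0.030, 0.000), c(0.0012, 0.0012, 0.0010)),
    seg_("forefoot", 0.40, c(0.050, -0.025, 0.000), c(0.0008, 0.0008, 0.0006)),
    seg_("toes",     0.15, c(0.015, -0.010, 0.000), c(0.0002, 0.0003, 0.0002))
  )

  joints <- list(
    jnt_("ground_pelvis", "ground", "pelvis", c(0, 0, 0), list(
      dof_("pelvis_tx", "trans", c(1, 0, 0)),
      dof_("pelvis_ty", "trans", c(0, 1, 0)),
      dof_("pelvis_tz", "trans", c(0, 0, 1)),
      dof_("pelvis_tilt", "rot", c(0, 0, 1)),
      dof_("pelvis_list", "rot", c(1, 0, 0)),
      dof_("pelvis_rotation", "rot", c(0, 1, 0)))),
    jnt_("hip", "pelvis", "femur", c(0.030, -0.080, 0.090), list(
      dof_("hip_flexion", "rot", c(0, 0, 1)),
      dof_("hip_adduction", "rot", c(1, 0, 0)),
      dof_("hip_rotation", "rot", c(0, 1, 0)))),
    jnt_("knee", "femur", "shank", c(0.000, -0.420, 0.000), list(
      dof_("knee_flexion", "rot", c(0, 0, 1)))),
    jnt_("ankle", "shank", "hindfoot", c(0.000, -0.400, 0.000), list(
      dof_("ankle_flexion", "rot", c(0, 0, 1)),
      dof_("ankle_inversion", "rot", c(1, 0, 0)),
      dof_("ankle_rotation", "rot", c(0, 1, 0)))),
    jnt_("talus_weld", "hindfoot", "talus", c(0, 0, 0), list()),
    jnt_("midfoot", "hindfoot", "forefoot", c(0.050, -0.035, 0.005), list(
      dof_("midfoot_flexion", "rot", c(0, 0, 1)),
      dof_("midfoot_inversion", "rot", c(1, 0, 0)),
      dof_("midfoot_rotation", "rot", c(0, 1, 0)))),
    jnt_("mtp", "forefoot", "toes", c(0.100, -0.025, 0.005), list(
      dof_("mtp_flexion", "rot", c(0, 0, 1))))
  )

  markers <- list(
    mk_("RASI", "pelvis", c(0.120, 0.020, 0.120)),
    mk_("LASI", "pelvis", c(0.118, 0.024, -0.120)),
    mk_("RPSI", "pelvis", c(-0.050, 0.032, 0.050)),
    mk_("LPSI", "pelvis", c(-0.052, 0.028, -0.050)),
    # left greater trochanter carried on the pelvis (single-limb model);
    # used only for pelvis-height scaling distances
    mk_("LGTR", "pelvis", c(0.020, -0.100, -0.152)),
    mk_("RGTR", "femur", c(-0.010, -0.020, 0.060)),
    mk_("RTHI", "femur", c(0.020, -0.200, 0.050)),
    mk_("RKNE", "femur", c(0.000, -0.420, 0.050)),
    mk_("RKNM", "femur", c(0.000, -0.420, -0.050)),
    mk_("RTIB", "shank", c(0.010, -0.220, 0.040)),
    mk_("RANK", "shank", c(-0.022, -0.415, 0.066)),
    mk_("RMMA", "shank", c(0.025, -0.398, -0.030)),
    mk_("RHEE", "hindfoot", c(-0.065, -0.055, 0.000)),
    mk_("RPCA", "hindfoot", c(-0.070, -0.025, 0.010)),
    mk_("RLCA", "hindfoot", c(-0.045, -0.055, 0.035)),
    mk_("RP5M", "forefoot", c(0.085, -0.040, 0.045)),
    mk_("RP1M", "forefoot", c(0.095, -0.035, -0.035)),
    mk_("RTOE", "forefoot", c(0.100, -0.020, 0.012)),
    mk_("RHLX", "toes", c(0.025, -0.015, -0.018))
  )

  muscles <- c(template_foot_muscles(), template_proximal_muscles())

  ligaments <- list(
    lig_("atfl", list("shank", c(-0.002, -0.405, 0.046)), list("talus", c(0.010, -0.005, 0.030))),
    lig_("cfl", list("shank", c(-0.005, -0.410, 0.048)), list("hindfoot", c(-0.010, -0.030, 0.030))),
    lig_("ptfl", list("shank", c(-0.015, -0.405, 0.045)), list("talus", c(-0.020, 0.000, 0.025))),
    lig_("deltoid_ant", list("shank", c(0.005, -0.400, -0.040)), list("talus", c(0.015, -0.005, -0.025))),
    lig_("deltoid_mid", list("shank", c(0.002, -0.400, -0.041)), list("hindfoot", c(0.000, -0.035, -0.025))),
    lig_("deltoid_post", list("shank", c(-0.008, -0.402, -0.040)), list("talus", c(-0.018, -0.005, -0.020))),
    lig_("plantar_fascia", list("hindfoot", c(-0.050, -0.060, 0.000)), list("toes", c(0.010, -0.012, 0.000)))
  )

  list(name = "generic lower limb + three-segment foot",
       segments = segments, joints = joints, muscles = muscles,
       ligaments = ligaments, markers = markers,
       landmarks = template_landmarks(),
       dome = list(segment = "talus", centre = c(0, 0, 0), axis = c(0, 0, 1),
                   radius = 0.020, half_length = 0.012, arc_deg = 80),
       patient = list(mass_kg = 75, height_m = 1.75))
}

template_foot_muscles <- function() {
  list(
    mp_("gastroc_med", "gastroc_med", 1558, TRUE,
        list("femur", c(-0.020, -0.400, -0.020)),
        list("shank", c(-0.035, -0.250, -0.005)),
        list("hindfoot", c(-0.048, -0.022, -0.004))),
    mp_("gastroc_lat", "gastroc_lat", 683, TRUE,
        list("femur", c(-0.020, -0.400, 0.020)),
        list("shank", c(-0.035, -0.250, 0.008)),
        list("hindfoot", c(-0.048, -0.022, 0.004))),
    mp_("soleus", "soleus", 3549, TRUE,
        list("shank", c(-0.025, -0.120, 0.005)),
        list("hindfoot", c(-0.048, -0.022, 0.000))),
    mp_("tib_ant", "tib_ant", 905, TRUE,
        list("shank", c(0.018, -0.150, 0.012)),
        list("shank", c(0.032, -0.390, -0.006)),
        list("forefoot", c(0.015, -0.020, -0.028))),
    mp_("tib_post", "tib_post", 1588, TRUE,
        list("shank", c(-0.012, -0.150, -0.006)),
        list("shank", c(-0.012, -0.400, -0.038)),
        list("forefoot", c(0.005, -0.035, -0.032))),
    mp_("per_long", "per_long", 943, TRUE,
        list("shank", c(0.002, -0.130, 0.032)),
        list("shank", c(-0.008, -0.405, 0.046)),
        list("hindfoot", c(0.035, -0.050, 0.025)),
        list("forefoot", c(0.018, -0.042, -0.022))),
    mp_("per_brev", "per_brev", 521, TRUE,
        list("shank", c(0.000, -0.240, 0.028)),
        list("shank", c(-0.006, -0.402, 0.044)),
        list("forefoot", c(0.028, -0.038, 0.040))),
    mp_("per_tert", "per_tert", 180, TRUE,
        list("shank", c(0.012, -0.280, 0.022)),
        list("shank", c(0.028, -0.390, 0.025)),
        list("forefoot", c(0.035, -0.028, 0.038))),
    mp_("flex_hal_long", "flex_hal_long", 519, TRUE,
        list("shank", c(-0.018, -0.200, 0.008)),
        list("shank", c(-0.018, -0.400, -0.022)),
        list("forefoot", c(0.030, -0.050, -0.025)),
        list("toes", c(0.028, -0.018, -0.014))),
    mp_("flex_dig_long", "flex_dig_long", 441, TRUE,
        list("shank", c(-0.014, -0.180, -0.010)),
        list("shank", c(-0.015, -0.400, -0.030)),
        list("forefoot", c(0.035, -0.048, 0.005)),
        list("toes", c(0.030, -0.016, 0.012))),
    mp_("ext_hal_long", "ext_hal_long", 165, TRUE,
        list("shank", c(0.014, -0.220, 0.008)),
        list("shank", c(0.034, -0.390, -0.012)),
        list("forefoot", c(0.060, -0.012, -0.022)),
        list("toes", c(0.030, 0.002, -0.012))),
    mp_("ext_dig_long", "ext_dig_long", 512, TRUE,
        list("shank", c(0.014, -0.170, 0.018)),
        list("shank", c(0.034, -0.390, 0.012)),
        list("forefoot", c(0.060, -0.012, 0.015)),
        list("toes", c(0.028, 0.002, 0.012))),
    mp_("flex_dig_brev", "flex_dig_brev", 310, TRUE,
        list("hindfoot", c(-0.040, -0.055, 0.002)),
        list("forefoot", c(0.050, -0.046, 0.012)),
        list("toes", c(0.024, -0.014, 0.010))),
    mp_("ext_dig_brev", "ext_dig_brev", 120, TRUE,
        list("hindfoot", c(0.015, -0.028, 0.028)),
        list("forefoot", c(0.065, -0.012, 0.020)),
        list("toes", c(0.022, 0.000, 0.016))),
    mp_("flex_hal_brev", "flex_hal_brev", 180, TRUE,
        list("forefoot", c(0.020, -0.042, -0.024)),
        list("toes", c(0.020, -0.016, -0.016))),
    mp_("abd_hal", "abd_hal", 350, TRUE,
        list("hindfoot", c(-0.035, -0.050, -0.022)),
        list("forefoot", c(0.045, -0.044, -0.028)),
        list("toes", c(0.020, -0.014, -0.020)))
  )
}

template_proximal_muscles <- function() {
  list(
    mp_("glut_max1", "glut_max", 550, FALSE,
        list("pelvis", c(-0.070, 0.010, 0.040)), list("femur", c(-0.015, -0.060, 0.030))),
    mp_("glut_max2", "glut_max", 550, FALSE,
        list("pelvis", c(-0.075, -0.010, 0.050)), list("femur", c(-0.012, -0.080, 0.025))),
    mp_("glut_max3", "glut_max", 550, FALSE,
        list("pelvis", c(-0.080, -0.030, 0.050)), list("femur", c(-0.010, -0.100, 0.020))),
    mp_("glut_med1", "glut_med", 820, FALSE,
        list("pelvis", c(0.055, -0.045, 0.095)),
        list("femur", c(0.025, -0.010, 0.048)),
        list("femur", c(-0.012, -0.028, 0.048))),
    mp_("glut_med2", "glut_med", 700, FALSE,
        list("pelvis", c(-0.030, 0.020, 0.100)), list("femur", c(-0.005, -0.015, 0.055))),
    mp_("glut_med3", "glut_med", 700, FALSE,
        list("pelvis", c(-0.010, 0.020, 0.115)), list("femur", c(0.005, -0.015, 0.055))),
    mp_("glut_min1", "glut_min", 300, FALSE,
        list("pelvis", c(0.045, -0.050, 0.085)),
        list("femur", c(0.022, -0.008, 0.045)),
        list("femur", c(-0.010, -0.020, 0.045))),
    mp_("glut_min2", "glut_min", 300, FALSE,
        list("pelvis", c(0.040, -0.048, 0.088)),
        list("femur", c(0.021, -0.009, 0.046)),
        list("femur", c(-0.009, -0.021, 0.046))),
    mp_("glut_min3", "glut_min", 300, FALSE,
        list("pelvis", c(0.035, -0.045, 0.090)),
        list("femur", c(0.020, -0.010, 0.046)),
        list("femur", c(-0.008, -0.022, 0.046))),
    mp_("iliacus1", "iliacus", 430, FALSE,
        list("pelvis", c(0.060, 0.000, 0.060)),
        list("pelvis", c(0.050, -0.085, 0.085)),
        list("femur", c(0.005, -0.040, -0.010))),
    mp_("iliacus2", "iliacus", 430, FALSE,
        list("pelvis", c(0.055, 0.010, 0.055)),
        list("pelvis", c(0.050, -0.085, 0.082)),
        list("femur", c(0.004, -0.042, -0.010))),
    mp_("psoas1", "psoas", 500, FALSE,
        list("pelvis", c(0.040, 0.050, 0.040)),
        list("pelvis", c(0.050, -0.085, 0.080)),
        list("femur", c(0.004, -0.045, -0.012))),
    mp_("psoas2", "psoas", 500, FALSE,
        list("pelvis", c(0.042, 0.040, 0.038)),
        list("pelvis", c(0.050, -0.086, 0.078)),
        list("femur", c(0.003, -0.047, -0.012))),
    mp_("rect_fem", "rect_fem", 849, FALSE,
        list("pelvis", c(0.055, -0.020, 0.095)),
        list("femur", c(0.045, -0.400, 0.000)),
        list("shank", c(0.035, -0.055, 0.000))),
    mp_("vas_lat1", "vas_lat", 1128, FALSE,
        list("femur", c(0.020, -0.120, 0.040)),
        list("femur", c(0.045, -0.400, 0.010)),
        list("shank", c(0.035, -0.055, 0.005))),
    mp_("vas_lat2", "vas_lat", 1128, FALSE,
        list("femur", c(0.015, -0.180, 0.042)),
        list("femur", c(0.045, -0.400, 0.012)),
        list("shank", c(0.035, -0.055, 0.006))),
    mp_("vas_med1", "vas_med", 722, FALSE,
        list("femur", c(0.020, -0.140, -0.030)),
        list("femur", c(0.045, -0.400, -0.008)),
        list("shank", c(0.035, -0.055, -0.005))),
    mp_("vas_med2", "vas_med", 722, FALSE,
        list("femur", c(0.015, -0.200, -0.032)),
        list("femur", c(0.045, -0.400, -0.010)),
        list("shank", c(0.035, -0.055, -0.006))),
    mp_("vas_int", "vas_int", 1024, FALSE,
        list("femur", c(0.025, -0.120, 0.000)),
        list("femur", c(0.045, -0.400, 0.000)),
        list("shank", c(0.035, -0.055, 0.000))),
    mp_("bifemlh1", "bifemlh", 705, FALSE,
        list("pelvis", c(-0.060, -0.060, 0.040)), list("shank", c(-0.025, -0.040, 0.042))),
    mp_("bifemlh2", "bifemlh", 705, FALSE,
        list("pelvis", c(-0.058, -0.062, 0.042)), list("shank", c(-0.024, -0.042, 0.040))),
    mp_("bifemsh", "bifemsh", 315, FALSE,
        list("femur", c(-0.010, -0.250, 0.020)), list("shank", c(-0.025, -0.045, 0.040))),
    mp_("semimem1", "semimem", 1030, FALSE,
        list("pelvis", c(-0.062, -0.058, 0.030)), list("shank", c(-0.025, -0.045, -0.030))),
    mp_("semimem2", "semimem", 1030, FALSE,
        list("pelvis", c(-0.064, -0.055, 0.028)), list("shank", c(-0.022, -0.050, -0.032))),
    mp_("semiten", "semiten", 410, FALSE,
        list("pelvis", c(-0.060, -0.062, 0.035)), list("shank", c(-0.015, -0.070, -0.025))),
    mp_("sartorius", "sartorius", 113, FALSE,
        list("pelvis", c(0.065, 0.000, 0.105)),
        list("femur", c(0.010, -0.350, -0.040)),
        list("shank", c(0.010, -0.060, -0.030))),
    mp_("gracilis", "gracilis", 137, FALSE,
        list("pelvis", c(0.010, -0.090, 0.010)), list("shank", c(-0.005, -0.070, -0.028))),
    mp_("tfl", "tfl", 155, FALSE,
        list("pelvis", c(0.055, -0.040, 0.115)),
        list("femur", c(0.028, -0.012, 0.056)),
        list("shank", c(0.010, -0.045, 0.045))),
    mp_("add_long1", "add_long", 400, FALSE,
        list("pelvis", c(0.045, -0.075, 0.015)), list("femur", c(0.005, -0.210, -0.008))),
    mp_("add_long2", "add_long", 400, FALSE,
        list("pelvis", c(0.040, -0.070, 0.020)), list("femur", c(0.000, -0.180, -0.010))),
    mp_("add_brev", "add_brev", 286, FALSE,
        list("pelvis", c(0.035, -0.080, 0.010)), list("femur", c(0.000, -0.120, -0.010))),
    mp_("add_mag1", "add_mag", 550, FALSE,
        list("pelvis", c(-0.020, -0.090, 0.012)), list("femur", c(0.000, -0.150, -0.012))),
    mp_("add_mag2", "add_mag", 550, FALSE,
        list("pelvis", c(-0.040, -0.085, 0.015)), list("femur", c(0.000, -0.250, -0.010))),
    mp_("add_mag3", "add_mag", 550, FALSE,
        list("pelvis", c(-0.055, -0.080, 0.020)), list("femur", c(-0.005, -0.380, -0.015))),
    mp_("piriformis", "piriformis", 444, FALSE,
        list("pelvis", c(-0.065, -0.020, 0.030)), list("femur", c(0.000, -0.010, 0.045))),
    mp_("quad_fem", "quad_fem", 254, FALSE,
        list("pelvis", c(-0.050, -0.080, 0.030)), list("femur", c(-0.015, -0.040, 0.030))),
    mp_("pectineus", "pectineus", 177, FALSE,
        list("pelvis", c(0.040, -0.060, 0.030)), list("femur", c(-0.005, -0.090, -0.005))),
    mp_("obt_int", "obt_int", 254, FALSE,
        list("pelvis", c(-0.055, -0.050, 0.020)), list("femur", c(-0.010, -0.015, 0.040)))
  )
}

#' Coordinates locked for simulation
#'
#' The hindfoot/forefoot coordinates and the internal/external rotation of
#' the ankle are held constant during simulation: the force-plate data do
#' not allow a load distribution across the three foot segments, and the
#' passive structures of the ankle are assumed to satisfy the
#' internal/external rotation moments.
#'
#' @return character vector of coordinate names
#' @export
simulation_locked_dofs <- function() {
  c("midfoot_flexion", "midfoot_inversion", "midfoot_rotation", "ankle_rotation")
}
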