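# Rigid-body model data structures: segments, a joint tree with lockable
# degrees of freedom, polyline muscle paths, inert ligament records, markers
# and virtual-palpation landmarks. Coordinates are metres in segment frames;
# angles are radians. Segment frames are right-handed with X anterior, Y up,
# Z lateral (right side) in the reference pose.

#' Build a musculoskeletal model from a template configuration
#'
#' Validates the configuration (unique names, existing segment references,
#' tree-shaped joint graph) and assembles a `msk_model`. The packaged default
#' configuration ([default_template_config()]) describes a generic lower limb
#' with a three-segment foot: 17 degrees of freedom (6 pelvis, 3 hip, 1 knee,
#' 3 ankle, 3 hindfoot/forefoot, 1 forefoot/toes), 54 muscle paths describing
#' 39 distinct muscles of which 16 cross the ankle or the internal foot
#' joints, and 7 inert ligament records.
#'
#' @param config template description list with `segments`, `joints`,
#'   `muscles`, `ligaments`, `markers`, `landmarks`, `patient` (see
#'   [default_template_config()] for the schema)
#' @return object of class `msk_model`
#' @export
build_template <- function(config = default_template_config()) {
  segs <- config$segments
  seg_names <- vapply(segs, `[[`, character(1), "name")
  if (anyDuplicated(seg_names)) stop("duplicate segment names: ",
                                     paste(seg_names[duplicated(seg_names)], collapse = ", "))
  names(segs) <- seg_names
  for (s in segs) {
    if (!is.null(s$mass) && s$mass < 0) stop("segment '", s$name, "' has negative mass")
    if (!is.null(s$inertia)) {
      I <- s$inertia
      if (max(abs(I - t(I))) > 1e-9) stop("segment '", s$name, "' inertia not symmetric")
      if (any(eigen(I, symmetric = TRUE, only.values = TRUE)$values < -1e-12))
        stop("segment '", s$name, "' inertia not positive semi-definite")
    }
  }

  joints <- config$joints
  j_names <- vapply(joints, `[[`, character(1), "name")
  if (anyDuplicated(j_names)) stop("duplicate joint names: ",
                                   paste(j_names[duplicated(j_names)], collapse = ", "))
  names(joints) <- j_names
  for (j in joints) {
    for (fld in c("parent", "child")) {
      ref <- j[[fld]]
      if (!(ref %in% c(seg_names, "ground")))
        stop("joint '", j$name, "' references unknown segment '", ref, "'")
    }
  }
  children <- vapply(joints, `[[`, character(1), "child")
  if (anyDuplicated(children))
    stop("joint graph is not a tree: segment '",
         children[duplicated(children)][1], "' has two parent joints")
  roots <- setdiff(seg_names, children)
  if (length(roots) > 0)
    stop("joint graph is not a tree: unconnected segment(s) ",
         paste(roots, collapse = ", "))

  check_points <- function(item, kind) {
    if (length(item$points) < 2)
      stop(kind, " '", item$name, "' needs at least 2 path points")
    for (pt in item$points)
      if (!(pt$segment %in% seg_names))
        stop(kind, " '", item$name, "' references unknown segment '", pt$segment, "'")
  }
  for (m in config$muscles) check_points(m, "muscle path")
  for (l in config$ligaments) {
    check_points(l, "ligament")
    if (isTRUE(l$active))
      stop("ligament '", l$name, "' is flagged active; ligaments are inert records")
  }
  for (mk in config$markers)
    if (!(mk$segment %in% seg_names))
      stop("marker '", mk$name, "' references unknown segment '", mk$segment, "'")
  if (!is.null(config$landmarks))
    for (lm in config$landmarks)
      if (!(lm$segment %in% seg_names))
        stop("landmark '", lm$name, "' references unknown segment '", lm$segment, "'")

  muscles <- config$muscles
  names(muscles) <- vapply(muscles, `[[`, character(1), "name")
  markers <- config$markers
  names(markers) <- vapply(markers, `[[`, character(1), "name")
  landmarks <- config$landmarks %||% list()
  if (length(landmarks))
    names(landmarks) <- vapply(landmarks, `[[`, character(1), "name")

  pm <- config$patient %||% list(mass_kg = 75, height_m = 1.75)
  model <- structure(list(
    segments = segs, joints = joints, muscles = muscles,
    ligaments = config$ligaments %||% list(),
    markers = markers, landmarks = landmarks,
    patient = patient_meta(pm$mass_kg, pm$height_m),
    dome = config$dome,
    name = config$name %||% "model"
  ), class = "msk_model")
  model <- rebuild_model_tables(model)
  model
}

#' Patient metadata
#' @param mass_kg body mass (kg)
#' @param height_m stature (m)
#' @return list with mass, height and body weight (N, g = 9.81 m/s^2)
#' @export
patient_meta <- function(mass_kg, height_m) {
  if (mass_kg <= 0 || height_m <= 0) stop("patient mass and height must be positive")
  list(mass_kg = mass_kg, height_m = height_m, body_weight_N = mass_kg * 9.81)
}

# (re)build the dof table, joint ordering and muscle/joint crossing matrix;
# called whenever the topology-bearing fields change
rebuild_model_tables <- function(model) {
  joints <- model$joints
  # topological order from ground
  ordered <- character(0)
  placed <- "ground"
  remaining <- names(joints)
  while (length(remaining)) {
    ready <- remaining[vapply(joints[remaining], function(j) j$parent %in% placed, logical(1))]
    if (!length(ready)) stop("joint graph is not a tree rooted at ground")
    ordered <- c(ordered, ready)
    placed <- c(placed, vapply(joints[ready], `[[`, character(1), "child"))
    remaining <- setdiff(remaining, ready)
  }
  model$joint_order <- ordered

  rows <- list()
  for (jn in ordered) {
    j <- joints[[jn]]
    for (k in seq_along(j$dofs)) {
      d <- j$dofs[[k]]
      rows[[length(rows) + 1]] <- data.frame(
        joint = jn, index = k, name = d$name, type = d$type,
        locked = isTRUE(d$locked), lock_value = d$lock_value %||% 0,
        stringsAsFactors = FALSE)
    }
  }
  model$dof_table <- do.call(rbind, rows)
  rownames(model$dof_table) <- model$dof_table$name

  # parent segment chain for each segment (towards ground)
  parent_of <- stats::setNames(vapply(joints, `[[`, character(1), "parent"),
                               vapply(joints, `[[`, character(1), "child"))
  model$parent_joint <- stats::setNames(names(joints),
                                        vapply(joints, `[[`, character(1), "child"))
  chain <- function(seg) {
    out <- character(0)
    while (seg != "ground") {
      out <- c(out, model$parent_joint[[seg]])
      seg <- parent_of[[seg]]
    }
    out
  }
  model$joint_chain <- lapply(stats::setNames(nm = names(model$segments)), chain)

  # muscle x joint crossing: a path crosses every joint on the tree path
  # between consecutive attachment segments
  cross <- matrix(FALSE, length(model$muscles), length(joints),
                  dimnames = list(names(model$muscles), names(joints)))
  for (mn in names(model$muscles)) {
    pts <- model$muscles[[mn]]$points
    for (k in seq_len(length(pts) - 1)) {
      a <- model$joint_chain[[pts[[k]]$segment]]
      b <- model$joint_chain[[pts[[k + 1]]$segment]]
      crossed <- union(setdiff(a, b), setdiff(b, a))
      cross[mn, crossed] <- TRUE
    }
  }
  model$crossing <- cross
  model
}

#' Number of degrees of freedom
#' @param model a `msk_model`
#' @param unlocked_only count only unlocked coordinates
#' @return integer
#' @export
n_dof <- function(model, unlocked_only = FALSE) {
  if (unlocked_only) sum(!model$dof_table$locked) else nrow(model$dof_table)
}

#' Lock or unlock model coordinates
#'
#' Locked coordinates hold a constant value: they are excluded from the
#' inverse-kinematics search and from the static-optimization constraint set
#' (their moments are not required to reach equilibrium).
#'
#' @param model a `msk_model`
#' @param dof_names coordinate names (see `model$dof_table$name`)
#' @param locked logical
#' @param values lock values (recycled), default 0
#' @return modified model
#' @export
set_locked <- function(model, dof_names, locked = TRUE, values = 0) {
  values <- rep_len(values, length(dof_names))
  for (i in seq_along(dof_names)) {
    row <- model$dof_table[model$dof_table$name == dof_names[i], ]
    if (!nrow(row)) stop("unknown coordinate: ", dof_names[i])
    j <- row$joint; k <- row$index
    model$joints[[j]]$dofs[[k]]$locked <- locked
    model$joints[[j]]$dofs[[k]]$lock_value <- values[i]
  }
  rebuild_model_tables(model)
}

#' Kinematic state vector
#'
#' Builds a full generalized-coordinate vector from named values, holding
#' locked coordinates at their lock value.
#'
#' @param model a `msk_model`
#' @param q named or unnamed numeric vector; unnamed vectors must have one
#'   entry per coordinate
#' @return numeric vector of length `n_dof(model)` with coordinate names
#' @export
kinematic_state <- function(model, q = NULL) {
  tab <- model$dof_table
  full <- stats::setNames(ifelse(tab$locked, tab$lock_value, 0), tab$name)
  if (!is.null(q)) {
    if (is.null(names(q))) {
      if (length(q) != nrow(tab))
        stop("state length ", length(q), " does not match model (", nrow(tab), " DoFs)")
      full[] <- q
    } else {
      unknown <- setdiff(names(q), tab$name)
      if (length(unknown)) stop("unknown coordinates: ", paste(unknown, collapse = ", "))
      full[names(q)] <- q
    }
  }
  full[tab$locked] <- tab$lock_value[tab$locked]
  full
}

#' Forward kinematics
#'
#' Composes the joint tree to give the world pose of every segment for a
#' given generalized-coordinate vector. Joint coupling functions (e.g. knee
#' derived translations/rotations) are applied after the joint's own motion.
#'
#' @param model a `msk_model`
#' @param q numeric vector of length `n_dof(model)` (radians / metres)
#' @return named list of 4x4 homogeneous world transforms, one per segment
#' @export
forward_kinematics <- function(model, q) {
  tab <- model$dof_table
  if (length(q) != nrow(tab))
    stop("state length ", length(q), " does not match model (", nrow(tab), " DoFs)")
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
      M <- if (d$type == "rot") make_transform(axis_angle(d$axis, qj[k]))
           else make_transform(p = d$axis * qj[k])
      T <- T %*% M
    }
    if (!is.null(j$coupling)) T <- T %*% j$coupling(qj)
    poses[[j$child]] <- T
    qi <- qi + nd
  }
  poses[names(model$segments)]
}

#' World positions of the model markers
#' @param model a `msk_model`
#' @param q state vector (default reference pose, all zero)
#' @param poses optional precomputed pose list from [forward_kinematics()]
#' @return `landmark_set` of marker positions in world coordinates
#' @export
model_marker_world <- function(model, q = NULL, poses = NULL) {
  if (is.null(poses)) poses <- forward_kinematics(model, q %||% kinematic_state(model))
  pts <- t(vapply(model$markers, function(mk) tf_apply(poses[[mk$segment]], mk$p),
                  numeric(3)))
  landmark_set(pts, names(model$markers),
               vapply(model$markers, `[[`, character(1), "segment"), "model")
}

#' World positions of the model's palpation landmarks
#' @inheritParams model_marker_world
#' @return `landmark_set` in world coordinates
#' @export
model_landmark_world <- function(model, q = NULL, poses = NULL) {
  if (is.null(poses)) poses <- forward_kinematics(model, q %||% kinematic_state(model))
  pts <- t(vapply(model$landmarks, function(lm) tf_apply(poses[[lm$segment]], lm$p),
                  numeric(3)))
  landmark_set(pts, names(model$landmarks),
               vapply(model$landmarks, `[[`, character(1), "segment"), "model")
}

#' Muscle path in world coordinates
#'
#' Maps each local path point through its segment's world pose and sums the
#' inter-point Euclidean distances.
#'
#' @param model a `msk_model`
#' @param q state vector, or NULL with `poses` supplied
#' @param muscle muscle path name
#' @param poses optional precomputed poses
#' @return list with `points` (n x 3 world matrix) and `length` (m)
#' @export
world_muscle_path <- function(model, q, muscle, poses = NULL) {
  m <- model$muscles[[muscle]]
  if (is.null(m)) stop("unknown muscle: ", muscle)
  if (is.null(poses)) poses <- forward_kinematics(model, q)
  pts <- t(vapply(m$points, function(pt) tf_apply(poses[[pt$segment]], pt$p),
                  numeric(3)))
  segs <- diff(pts)
  list(points = pts, length = sum(sqrt(rowSums(segs^2))))
}

#' @export
print.msk_model <- function(x, ...) {
  cat("<msk_model> '", x$name, "'\n", sep = "")
  cat(sprintf("  %d segments, %d joints, %d DoFs (%d locked)\n",
              length(x$segments), length(x$joints), n_dof(x),
              sum(x$dof_table$locked)))
  cat(sprintf("  %d muscle paths (%d distinct muscles, %d crossing the ankle/foot), %d ligaments (inert)\n",
              length(x$muscles),
              length(unique(vapply(x$muscles, function(m) m$muscle %||% m$name, character(1)))),
              sum(vapply(x$muscles, function(m) isTRUE(m$crosses_ankle), logical(1))),
              length(x$ligaments)))
  cat(sprintf("  %d markers, %d landmarks; patient %.1f kg, %.2f m (BW %.0f N)\n",
              length(x$markers), length(x$landmarks),
              x$patient$mass_kg, x$patient$height_m, x$patient$body_weight_N))
  invisible(x)
}

#' @export
summary.msk_model <- function(object, ...) {
  print(object)
  cat("\nCoordinates:\n")
  tab <- object$dof_table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-22s %-6s %s\n", tab$name[i], tab$type[i],
                if (tab$locked[i]) sprintf("locked at %.3f", tab$lock_value[i]) else "free"))
  invisible(object)
}
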