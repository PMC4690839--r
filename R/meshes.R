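# Minimal ASCII PLY surface-mesh IO (the interchange for segmented bone
# geometry) and JSON serialization of models.

#' Read / write ASCII PLY meshes
#'
#' Supports the minimal subset used for segmented bone surfaces: float
#' vertex x/y/z properties and integer-list faces. Vertices are metres.
#'
#' @param path file path
#' @return list with `vertices` (n x 3 matrix) and `faces` (m x 3 integer
#'   matrix, 1-based, possibly empty)
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "ply")) stop("not a PLY file: ", path)
  end <- match(TRUE, trimws(lines) == "end_header")
  if (is.na(end)) stop("malformed PLY (no end_header): ", path)
  hdr <- lines[1:end]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf_line <- grep("^element face", hdr, value = TRUE)
  nf <- if (length(nf_line)) as.integer(sub("element face ", "", nf_line)) else 0L
  if (!length(nv)) stop("malformed PLY (no vertex element): ", path)
  vtx <- utils::read.table(text = lines[end + seq_len(nv)])[, 1:3]
  faces <- matrix(integer(0), 0, 3)
  if (nf > 0) {
    f <- utils::read.table(text = lines[end + nv + seq_len(nf)])
    faces <- matrix(as.integer(as.matrix(f[, 2:4])) + 1L, nrow = nf)
  }
  list(vertices = as.matrix(vtx), faces = faces)
}

#' @rdname read_ply
#' @param mesh list with `vertices` and optional `faces` (1-based)
#' @export
write_ply <- function(mesh, path) {
  v <- rbind(mesh$vertices)
  f <- mesh$faces %||% matrix(integer(0), 0, 3)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  vl <- apply(v, 1, function(r) paste(format(r, digits = 9, trim = TRUE), collapse = " "))
  fl <- if (nrow(f)) apply(f, 1, function(r) paste(c(3, r - 1L), collapse = " ")) else character(0)
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

# ---- model JSON serialization ------------------------------------------------

#' Serialize a model to JSON
#'
#' Versioned schema mirroring the template configuration: segments, joints
#' (location/orientation/DoFs/lock state), muscle paths with maximum
#' isometric forces, ligament records, markers, landmarks and patient
#' metadata. Coupling functions are not serialized (a note is emitted if
#' any are present); meshes are referenced by relative path.
#'
#' @param model a `msk_model`
#' @param path output path
#' @export
write_model_json <- function(model, path) {
  j2l <- function(j) list(
    name = j$name, parent = j$parent, child = j$child,
    location = as.numeric(j$location %||% c(0, 0, 0)),
    orientation = as.matrix(j$orientation %||% diag(3)),
    dofs = lapply(j$dofs, function(d)
      list(name = d$name, type = d$type, axis = as.numeric(d$axis),
           locked = isTRUE(d$locked), lock_value = d$lock_value %||% 0)))
  if (any(vapply(model$joints, function(j) !is.null(j$coupling), logical(1))))
    message("note: joint coupling functions are not serialized")
  obj <- list(
    schema = "mskfoot-model", version = 1, name = model$name,
    patient = model$patient[c("mass_kg", "height_m")],
    segments = lapply(unname(model$segments), function(s)
      list(name = s$name, mass = s$mass, com = as.numeric(s$com),
           inertia = as.matrix(s$inertia), mesh_ref = s$mesh_ref)),
    joints = lapply(unname(model$joints), j2l),
    muscles = lapply(unname(model$muscles), function(m)
      list(name = m$name, muscle = m$muscle, fmax = m$fmax,
           crosses_ankle = isTRUE(m$crosses_ankle),
           points = lapply(m$points, function(p)
             list(segment = p$segment, p = as.numeric(p$p))))),
    ligaments = lapply(unname(model$ligaments), function(l)
      list(name = l$name, active = FALSE,
           points = lapply(l$points, function(p)
             list(segment = p$segment, p = as.numeric(p$p))))),
    markers = lapply(unname(model$markers), function(mk)
      list(name = mk$name, segment = mk$segment, p = as.numeric(mk$p))),
    landmarks = lapply(unname(model$landmarks), function(lm)
      list(name = lm$name, segment = lm$segment, p = as.numeric(lm$p))),
    dome = model$dome
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model from JSON
#' @param path file path
#' @return a `msk_model`
#' @export
read_model_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(o$schema, "mskfoot-model"))
    stop("not a mskfoot model file: ", path)
  num <- function(x) as.numeric(unlist(x))
  m3 <- function(x) matrix(num(x), 3, 3)
  cfg <- list(
    name = o$name,
    patient = list(mass_kg = o$patient$mass_kg, height_m = o$patient$height_m),
    segments = lapply(o$segments, function(s)
      list(name = s$name, mass = s$mass, com = num(s$com), inertia = m3(s$inertia),
           mesh_ref = s$mesh_ref)),
    joints = lapply(o$joints, function(j)
      list(name = j$name, parent = j$parent, child = j$child,
           location = num(j$location), orientation = m3(j$orientation),
           coupling = NULL,
           dofs = lapply(j$dofs, function(d)
             list(name = d$name, type = d$type, axis = num(d$axis),
                  locked = isTRUE(d$locked), lock_value = d$lock_value)))),
    muscles = lapply(o$muscles, function(m)
      list(name = m$name, muscle = m$muscle, fmax = m$fmax,
           crosses_ankle = isTRUE(m$crosses_ankle),
           points = lapply(m$points, function(p)
             list(segment = p$segment, p = num(p$p))))),
    ligaments = lapply(o$ligaments, function(l)
      list(name = l$name, active = FALSE,
           points = lapply(l$points, function(p)
             list(segment = p$segment, p = num(p$p))))),
    markers = lapply(o$markers, function(mk)
      list(name = mk$name, segment = mk$segment, p = num(mk$p))),
    landmarks = lapply(o$landmarks, function(lm)
      list(name = lm$name, segment = lm$segment, p = num(lm$p)))
  )
  if (!is.null(o$dome))
    cfg$dome <- list(segment = o$dome$segment, centre = num(o$dome$centre),
                     axis = num(o$dome$axis), radius = o$dome$radius,
                     half_length = o$dome$half_length, arc_deg = o$dome$arc_deg)
  model <- build_template(cfg)
  model$dome <- cfg$dome
  model
}
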