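# Named 3D landmark sets: the currency of virtual palpation and registration.

#' Create a landmark set
#'
#' A landmark set is a named collection of 3D points (metres), each optionally
#' tagged with the segment it belongs to and the source it was palpated from
#' (MRI mesh, gait static trial, generic model).
#'
#' @param points n x 3 numeric matrix with one row per landmark
#' @param names character vector of unique landmark names
#' @param segment character vector (length 1 or n) of owning segment names
#' @param source character scalar, e.g. "mri", "static", "generic"
#' @return object of class `landmark_set`
#' @export
landmark_set <- function(points, names, segment = NA_character_, source = "generic") {
  points <- rbind(points)
  if (is.null(dim(points)) || ncol(points) != 3)
    stop("landmark points must form an n x 3 matrix")
  if (length(names) != nrow(points)) stop("one name per landmark row required")
  if (anyDuplicated(names)) stop("landmark names must be unique: ",
                                 paste(unique(names[duplicated(names)]), collapse = ", "))
  if (!all(is.finite(points))) stop("landmark coordinates must be finite")
  rownames(points) <- names
  segment <- rep_len(segment, nrow(points))
  structure(list(points = points, segment = segment, source = source),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", nrow(x$points), " landmarks (source: ", x$source, ")\n", sep = "")
  segs <- unique(x$segment[!is.na(x$segment)])
  if (length(segs)) cat("  segments:", paste(segs, collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.landmark_set` <- function(x, i, ...) {
  if (is.character(i)) {
    missing <- setdiff(i, rownames(x$points))
    if (length(missing)) stop("unknown landmarks: ", paste(missing, collapse = ", "))
  }
  idx <- if (is.character(i)) match(i, rownames(x$points)) else i
  landmark_set(x$points[idx, , drop = FALSE], rownames(x$points)[idx],
               x$segment[idx], x$source)
}

#' @export
names.landmark_set <- function(x) rownames(x$points)

#' @export
length.landmark_set <- function(x) nrow(x$points)

lm_point <- function(x, name) {
  i <- match(name, rownames(x$points))
  if (is.na(i)) stop("landmark not found: ", name)
  as.numeric(x$points[i, ])
}

#' Apply a rigid transform to a landmark set
#' @param T 4x4 homogeneous transform
#' @param lms a `landmark_set`
#' @return transformed `landmark_set`
#' @export
transform_landmarks <- function(T, lms) {
  landmark_set(tf_apply(T, lms$points), rownames(lms$points), lms$segment, lms$source)
}

#' Read / write landmark sets as JSON
#'
#' The JSON schema is `{"units": "m"|"mm", "source": ..., "landmarks":
#' {"NAME": {"p": [x,y,z], "segment": "..."}}}`. Millimetre files are
#' converted to metres on read.
#'
#' @param path file path
#' @return a `landmark_set`
#' @export
read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$landmarks)) stop("malformed landmark file (no 'landmarks' field): ", path)
  units <- obj$units %||% "m"
  scale <- switch(units, m = 1, mm = 1e-3,
                  stop("unknown landmark units token: ", units))
  nms <- names(obj$landmarks)
  pts <- t(vapply(obj$landmarks, function(l) as.numeric(l$p), numeric(3))) * scale
  seg <- vapply(obj$landmarks, function(l) l$segment %||% NA_character_, character(1))
  landmark_set(pts, nms, seg, obj$source %||% "file")
}

#' @rdname read_landmarks_json
#' @param lms a `landmark_set`
#' @export
write_landmarks_json <- function(lms, path) {
  entries <- lapply(seq_len(nrow(lms$points)), function(i) {
    list(p = as.numeric(lms$points[i, ]), segment = lms$segment[i])
  })
  names(entries) <- rownames(lms$points)
  jsonlite::write_json(list(units = "m", source = lms$source, landmarks = entries),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
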