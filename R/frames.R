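# Anatomical coordinate frames at the ankle: the image-based (cylinder)
# definition and the gait-marker (malleoli) definition, plus the scalar
# comparison between two frames.

#' Create an anatomical frame
#'
#' @param origin length-3 origin (m)
#' @param axes 3x3 orthonormal matrix, columns = anatomical directions
#'   (X anterior, Y vertical, Z transverse/lateral)
#' @return object of class `anatomical_frame`
#' @export
anatomical_frame <- function(origin, axes) {
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9)
    stop("frame axes must be orthonormal")
  if (det(axes) < 0) stop("frame must be right-handed")
  structure(list(origin = as.numeric(origin), axes = axes),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("<anatomical_frame> origin (%.4f, %.4f, %.4f) m\n",
              x$origin[1], x$origin[2], x$origin[3]))
  labs <- c("anterior ", "vertical ", "transverse")
  for (i in 1:3)
    cat(sprintf("  %s (%.3f, %.3f, %.3f)\n", labs[i],
                x$axes[1, i], x$axes[2, i], x$axes[3, i]))
  invisible(x)
}

# shank-style frame recipe shared by both ankle definitions:
# vertical axis from the inter-"malleolar" midpoint to the knee joint centre,
# anterior axis perpendicular to the plane of the vertical axis and the
# medial-to-lateral vector, transverse axis mutually perpendicular.
shank_frame_recipe <- function(lat, med, knee) {
  origin <- (lat + med) / 2
  if (sqrt(sum((lat - med)^2)) < 1e-9)
    stop("malleolar points coincide: frame undefined")
  y <- unit(knee - origin)
  w <- unit(lat - med)           # medial -> lateral
  xv <- cross3(y, w)
  if (sqrt(sum(xv^2)) < 1e-9)
    stop("knee centre collinear with the malleolar axis: frame undefined")
  x <- unit(xv)
  z <- cross3(x, y)
  anatomical_frame(origin, cbind(x, y, z))
}

#' Ankle frame from the fitted talar-dome cylinder (image-based definition)
#'
#' The ankle joint centre is the midpoint of the fitted axial extent; the
#' flexion/extension axis is the cylinder axis. The remaining axes follow the
#' malleolar shank recipe with the cylinder's lateral and medial axis
#' endpoints substituted for the malleoli.
#'
#' @param cyl a `cylinder3d` whose direction points lateral
#' @param knee_centre length-3 knee joint centre (m)
#' @return `anatomical_frame`
#' @export
ankle_frame_mr <- function(cyl, knee_centre) {
  if (missing(knee_centre) || is.null(knee_centre))
    stop("knee joint centre is required to construct the ankle frame")
  if (diff(cyl$extent) < 1e-9)
    stop("degenerate cylinder extent: cannot place medial/lateral axis endpoints")
  lat <- cyl$point + cyl$extent[2] * cyl$direction
  med <- cyl$point + cyl$extent[1] * cyl$direction
  shank_frame_recipe(lat, med, knee_centre)
}

#' Ankle frame from gait-analysis malleoli markers (marker-based definition)
#'
#' Vertical axis from the inter-malleolar midpoint to the knee joint centre,
#' anterior axis perpendicular to the plane of the vertical axis and the
#' medial-to-lateral malleolar vector, transverse axis mutually
#' perpendicular; origin at the inter-malleolar midpoint.
#'
#' @param lat_malleolus,med_malleolus,knee_centre length-3 points (m)
#' @return `anatomical_frame`
#' @export
ankle_frame_cga <- function(lat_malleolus, med_malleolus, knee_centre) {
  shank_frame_recipe(lat_malleolus, med_malleolus, knee_centre)
}

#' Scalar difference between two anatomical frames
#'
#' @param a,b `anatomical_frame`s
#' @return list with `angle_deg` (angle of the relative rotation) and
#'   `offset_mm` (distance between the origins)
#' @export
frame_difference <- function(a, b) {
  list(angle_deg = rotation_angle(crossprod(a$axes, b$axes)) * 180 / pi,
       offset_mm = sqrt(sum((a$origin - b$origin)^2)) * 1000)
}

#' Export a frame as a 4x4 homogeneous matrix
#' @param frame an `anatomical_frame`
#' @return 4x4 matrix mapping frame coordinates to world
#' @export
frame_to_transform <- function(frame) make_transform(frame$axes, frame$origin)
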