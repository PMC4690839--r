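# Least-squares cylinder fitting to an articular surface patch. The fitted
# cylinder of the talar dome supplies the image-based ankle joint centre
# (midpoint of the fitted axial extent) and flexion/extension axis.

#' Fit a cylinder to a point cloud
#'
#' Nonlinear least squares over axis point, axis direction and radius,
#' minimizing the sum of squared orthogonal-distance-to-axis minus radius
#' residuals. Initialization tries each principal component of the cloud as a
#' candidate axis with an algebraic (Kasa) circle fit in the normal plane and
#' keeps the best; the solution is refined by Levenberg-Marquardt. Works on
#' partial patches (e.g. a 60-90 degree arc of the talar dome).
#'
#' @param points n x 3 matrix (metres), n >= 6, spanning a curved patch
#' @param lateral_hint optional 3-vector; the axis direction is flipped so
#'   that its projection on this vector is positive (used to make the dome
#'   axis point lateral, resolving the sign ambiguity of an unoriented axis)
#' @param max_iter maximum Levenberg-Marquardt iterations
#' @return object of class `cylinder3d`: `point` (on axis, closest to the
#'   cloud centroid), `direction` (unit axis), `radius` (m), `extent`
#'   (range of axial projections of the fitted points, relative to `point`),
#'   `rms_mm` (residual)
#' @export
fit_cylinder <- function(points, lateral_hint = NULL, max_iter = 200) {
  P <- rbind(points)
  if (ncol(P) != 3) stop("cylinder fit needs an n x 3 point matrix")
  if (nrow(P) < 6) stop("cylinder fit needs at least 6 points")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc)
  if (sv$d[3] < 1e-6 * sv$d[1])
    stop("ill-conditioned cylinder fit: point cloud is (near) planar")

  # initial candidates: each principal direction as axis
  best <- NULL
  for (k in 1:3) {
    d0 <- sv$v[, k]
    init <- init_circle_in_plane(Pc, d0)
    if (is.null(best) || init$rms < best$rms) best <- c(init, list(d0 = d0))
  }
  d0 <- best$d0
  # orthonormal basis of the plane normal to d0
  u1 <- unit(pick_perp(d0))
  u2 <- cross3(d0, u1)

  # parameters: axis tilt (a, b), axis point in-plane offset (alpha, beta), radius
  par0 <- c(0, 0, best$c1, best$c2, best$r)
  resid_fn <- function(par) {
    d <- unit(d0 + par[1] * u1 + par[2] * u2)
    p <- par[3] * u1 + par[4] * u2   # axis point relative to centroid
    rel <- sweep(Pc, 2, p)
    ax <- as.numeric(rel %*% d)
    radial <- rel - outer(ax, d)
    sqrt(rowSums(radial^2)) - par[5]
  }
  fit <- minpack.lm::nls.lm(par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = 1e-15, ptol = 1e-15))
  if (fit$info == 0 || fit$info == 9)
    stop("cylinder fit did not converge after ", max_iter, " iterations")
  par <- fit$par
  if (par[5] <= 0) stop("cylinder fit collapsed to non-positive radius")

  d <- unit(d0 + par[1] * u1 + par[2] * u2)
  p <- ctr + par[3] * u1 + par[4] * u2
  # re-anchor axis point at the projection of the centroid
  p <- p + sum((ctr - p) * d) * d
  if (!is.null(lateral_hint) && sum(d * lateral_hint) < 0) d <- -d
  ax <- as.numeric(sweep(P, 2, p) %*% d)
  res <- resid_fn(par)
  structure(list(point = p, direction = d, radius = par[5],
                 extent = range(ax), rms_mm = sqrt(mean(res^2)) * 1000,
                 n = nrow(P)),
            class = "cylinder3d")
}

# algebraic circle fit (Kasa) of the cloud projected on the plane normal to d
init_circle_in_plane <- function(Pc, d) {
  u1 <- unit(pick_perp(d))
  u2 <- cross3(d, u1)
  x <- as.numeric(Pc %*% u1)
  y <- as.numeric(Pc %*% u2)
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) c(0, 0, mean(b)))
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(max(sol[3] + cx^2 + cy^2, 1e-12))
  rms <- sqrt(mean((sqrt((x - cx)^2 + (y - cy)^2) - r)^2))
  list(c1 = cx, c2 = cy, r = r, rms = rms)
}

pick_perp <- function(d) {
  e <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e - sum(e * d) * d
}

#' @export
print.cylinder3d <- function(x, ...) {
  cat(sprintf("<cylinder3d> radius %.4f m, axis (%.3f, %.3f, %.3f)\n",
              x$radius, x$direction[1], x$direction[2], x$direction[3]))
  cat(sprintf("  axis point (%.4f, %.4f, %.4f) m, extent [%.4f, %.4f] m, rms %.4f mm (n=%d)\n",
              x$point[1], x$point[2], x$point[3], x$extent[1], x$extent[2], x$rms_mm, x$n))
  invisible(x)
}

#' Midpoint of the fitted axial extent (the ankle joint centre)
#' @param cyl a `cylinder3d`
#' @return length-3 point (m)
#' @export
cylinder_centre <- function(cyl) {
  cyl$point + mean(cyl$extent) * cyl$direction
}
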