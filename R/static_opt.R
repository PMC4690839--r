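# Static optimization: frame-by-frame resolution of the muscle redundancy
# problem — minimize the sum of squared activations subject to joint moment
# equilibrium on the free coordinates and activation bounds — solved exactly
# by a primal active-set method for the diagonal-Hessian quadratic program.
# Optional reserve actuators (idealized, heavily penalized torque
# generators) guarantee feasibility; without them, infeasibility is reported
# with the violated coordinate, which is how a marker-based ankle frame
# manifests in practice.

# min 1/2 x' H x  s.t.  A x = d,  l <= x <= u, with H diagonal positive.
# Feasible-path primal active set; the caller guarantees a feasible start
# (here: reserve variables are unbounded, so x = (0, d) is always feasible).
solve_qp_activeset <- function(A, d, h, lower, upper, x0, max_iter = 500) {
  n <- length(h)
  x <- x0
  active <- ifelse(abs(x - lower) < 1e-14, -1L, ifelse(abs(x - upper) < 1e-14, 1L, 0L))
  active[!is.finite(lower) & !is.finite(upper)] <- 0L
  lambda <- rep(0, nrow(A))
  for (iter in seq_len(max_iter)) {
    f <- active == 0L
    Af <- A[, f, drop = FALSE]
    hf <- h[f]
    r <- d - A[, !f, drop = FALSE] %*% x[!f]
    S <- Af %*% (t(Af) / hf)
    lambda <- tryCatch(solve(S, r), error = function(e)
      solve(S + diag(1e-12 * max(diag(S), 1), nrow(S)), r))
    xf_star <- as.numeric(t(Af) %*% lambda) / hf
    p <- numeric(n)
    p[f] <- xf_star - x[f]
    if (max(abs(p)) < 1e-11) {
      grad <- h * x
      mult <- grad - as.numeric(t(A) %*% lambda)
      viol_lo <- active == -1L & mult < -1e-9
      viol_hi <- active == 1L & mult > 1e-9
      if (!any(viol_lo) && !any(viol_hi)) {
        return(list(x = x, lambda = as.numeric(lambda), iterations = iter))
      }
      score <- rep(0, n)
      score[viol_lo] <- -mult[viol_lo]
      score[viol_hi] <- mult[viol_hi]
      active[which.max(score)] <- 0L
      next
    }
    alpha <- 1
    block <- 0L
    bdir <- 0L
    for (i in which(f)) {
      if (p[i] < -1e-15 && is.finite(lower[i])) {
        a <- (lower[i] - x[i]) / p[i]
        if (a < alpha) { alpha <- a; block <- i; bdir <- -1L }
      } else if (p[i] > 1e-15 && is.finite(upper[i])) {
        a <- (upper[i] - x[i]) / p[i]
        if (a < alpha) { alpha <- a; block <- i; bdir <- 1L }
      }
    }
    x <- x + alpha * p
    if (block > 0L && alpha < 1) {
      x[block] <- if (bdir < 0L) lower[block] else upper[block]
      active[block] <- bdir
    }
  }
  stop("active-set QP did not converge in ", max_iter, " iterations")
}

# one frame of static optimization. Reserve variables are always carried
# internally so the active-set solver starts feasible; in "no reserves"
# mode they get a large penalty and the solution is then polished to an
# exact equality-constrained optimum on the final active set, so the
# moment constraints are satisfied to machine precision (or the frame is
# reported infeasible with the violated coordinate).
so_solve_frame <- function(Rmat, tau_free, fmax, reserves, w_res = 1000, tau0 = 1) {
  n <- length(fmax)
  m <- length(tau_free)
  A <- t(Rmat * fmax)              # m x n: A[j, i] = fmax_i * R[i, j]
  w_internal <- if (reserves) w_res else 1e6
  A_aug <- cbind(A, diag(m))
  h <- c(rep(2, n), rep(2 * w_internal / tau0^2, m))
  lower <- c(rep(0, n), rep(-Inf, m))
  upper <- c(rep(1, n), rep(Inf, m))
  x0 <- c(rep(0, n), tau_free)
  sol <- solve_qp_activeset(A_aug, tau_free, h, lower, upper, x0)
  a <- sol$x[seq_len(n)]
  res <- sol$x[n + seq_len(m)]
  if (!reserves) {
    pol <- so_polish(A, tau_free, a)
    if (is.null(pol)) {
      worst <- which.max(abs(res))
      stop("static optimization infeasible without reserve actuators: ",
           sprintf("unbalanced moment %.3f N m at coordinate '%s'",
                   res[worst], names(tau_free)[worst] %||% worst),
           call. = FALSE)
    }
    a <- pol
    res[] <- 0
  }
  list(a = a, reserves = res, objective = sum(a^2))
}

# exact least-norm solve on the free muscles of the (near-)final active
# set; returns NULL when the bounds-constrained equalities cannot be met
so_polish <- function(A, d, a, tol = 1e-7) {
  n <- ncol(A)
  for (pass in 1:10) {
    lo <- a < tol
    hi <- a > 1 - tol
    f <- !(lo | hi)
    r <- d - A[, hi, drop = FALSE] %*% rep(1, sum(hi))
    if (!sum(f)) {
      if (max(abs(r)) < 1e-6) { a[lo] <- 0; a[hi] <- 1; return(a) }
      return(NULL)
    }
    Af <- A[, f, drop = FALSE]
    S <- tcrossprod(Af) / 2
    sv <- svd(S)
    keep <- sv$d > max(sv$d) * 1e-12
    if (!any(keep)) return(NULL)
    lam <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% r) / sv$d[keep])
    af <- as.numeric(t(Af) %*% lam) / 2
    resid <- max(abs(Af %*% af - r))
    if (resid > 1e-6) return(NULL)
    if (all(af > -1e-9 & af < 1 + 1e-9)) {
      a[f] <- pmin(pmax(af, 0), 1)
      a[lo] <- 0; a[hi] <- 1
      return(a)
    }
    # clamp the worst violator and retry
    worst <- which.max(pmax(-af, af - 1))
    idx <- which(f)[worst]
    a[idx] <- if (af[worst] < 0) 0 else 1
  }
  NULL
}

#' Static optimization of the muscle redundancy problem
#'
#' Per frame, solves: minimize the sum of squared activations (plus, with
#' reserves enabled, a heavily weighted quadratic penalty on per-coordinate
#' reserve torques) subject to the joint moment equilibrium constraints on
#' the free coordinates and activation bounds 0 <= a <= 1. Muscles are
#' ideal force generators: force = activation x Fmax. The free coordinate
#' set excludes the locked coordinates (hindfoot/forefoot and ankle
#' internal/external rotation by default), whose moments are not required
#' to reach equilibrium.
#'
#' @param R muscles x dofs x frames array (or matrix for one frame) of
#'   moment arms, with named dimensions
#' @param tau frames x dofs matrix of required joint moments (named columns)
#' @param fmax named vector of maximum isometric forces (N)
#' @param free_dofs coordinate names to constrain
#' @param reserves "off", "on" or "auto" (retry with reserves on
#'   infeasibility)
#' @param w_res reserve penalty weight
#' @param tau0 reserve normalizing torque (N m)
#' @return object of class `muscle_state`: `activations` and `forces`
#'   (frames x muscles), `reserves` (frames x free dofs),
#'   `reserves_used` flag, `objective` per frame
#' @export
static_optimization <- function(R, tau, fmax, free_dofs, reserves = c("off", "on", "auto"),
                                w_res = 1000, tau0 = 1) {
  reserves <- match.arg(reserves)
  if (length(dim(R)) == 2) R <- array(R, c(dim(R), 1), dimnames = c(dimnames(R), list(NULL)))
  if (is.null(dim(tau))) tau <- matrix(tau, 1, length(tau), dimnames = list(NULL, names(tau)))
  muscles <- dimnames(R)[[1]]
  missing_dofs <- setdiff(free_dofs, dimnames(R)[[2]])
  if (length(missing_dofs))
    stop("free coordinates absent from the moment-arm array: ",
         paste(missing_dofs, collapse = ", "))
  n_frames <- dim(R)[3]
  fmax <- fmax[muscles]

  run <- function(use_reserves) {
    a <- matrix(0, n_frames, length(muscles), dimnames = list(NULL, muscles))
    res <- matrix(0, n_frames, length(free_dofs), dimnames = list(NULL, free_dofs))
    obj <- numeric(n_frames)
    for (i in seq_len(n_frames)) {
      Rm <- matrix(R[, free_dofs, i], nrow = length(muscles),
                   dimnames = list(muscles, free_dofs))
      sol <- so_solve_frame(Rm, stats::setNames(tau[i, free_dofs], free_dofs),
                            fmax, use_reserves, w_res, tau0)
      a[i, ] <- sol$a
      res[i, ] <- sol$reserves
      obj[i] <- sol$objective
    }
    list(a = a, res = res, obj = obj)
  }

  used <- reserves == "on"
  out <- if (reserves == "auto") {
    tryCatch(run(FALSE), error = function(e) {
      message("static optimization infeasible without reserves; retrying with reserve actuators (",
              conditionMessage(e), ")")
      used <<- TRUE
      run(TRUE)
    })
  } else run(used)

  structure(list(activations = out$a,
                 forces = sweep(out$a, 2, fmax, "*"),
                 reserves = out$res, reserves_used = used,
                 objective = out$obj, free_dofs = free_dofs),
            class = "muscle_state")
}

#' @export
print.muscle_state <- function(x, ...) {
  cat(sprintf("<muscle_state> %d frames x %d muscles, reserves %s\n",
              nrow(x$activations), ncol(x$activations),
              if (x$reserves_used) "used" else "off"))
  peak <- sort(apply(x$activations, 2, max), decreasing = TRUE)
  top <- utils::head(peak[peak > 0.01], 5)
  if (length(top))
    cat("  peak activations:",
        paste(sprintf("%s %.2f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}
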