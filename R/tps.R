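#' Thin-plate-spline warp between landmark configurations
#'
#' 3D thin-plate spline with the biharmonic kernel U(r) = r: an affine part
#' plus radial coefficients per source landmark, solving the standard
#' bordered system with side conditions that keep the radial coefficients
#' orthogonal to the affine space. \code{lambda} adds diagonal
#' regularization, trading exact interpolation for smoothness; at
#' \code{lambda = 0} the warp interpolates every landmark exactly.
#'
#' @param src_lms,dst_lms landmark sets with identical names in identical
#'   order (or plain n x 3 matrices).
#' @param lambda regularization weight >= 0 (default 0).
#' @return a \code{tps_warp} object; evaluate with \code{predict}.
#' @export
tps_warp <- function(src_lms, dst_lms, lambda = 0) {
  X <- if (is.matrix(src_lms)) src_lms else lm_coords(src_lms)
  Y <- if (is.matrix(dst_lms)) dst_lms else lm_coords(dst_lms)
  if (!is.matrix(src_lms) && !is.matrix(dst_lms)) {
    if (!identical(as.character(src_lms$name), as.character(dst_lms$name))) {
      stopf("source and destination landmark names/order differ")
    }
  }
  if (nrow(X) != nrow(Y)) stopf("landmark counts differ")
  n <- nrow(X)
  if (n < 4L) stopf("need >= 4 landmarks for a 3D thin-plate spline")
  if (lambda < 0) stopf("lambda must be >= 0")

  # coplanarity check: affine part needs full rank
  cc <- sweep(X, 2, colMeans(X))
  sv <- svd(cc, nu = 0, nv = 0)$d
  if (sv[3] < 1e-10 * max(sv[1], 1e-300)) {
    stopf(paste0("landmark configuration is rank-deficient (coplanar or",
                 " collinear); 3D thin-plate spline undefined"))
  }

  K <- as.matrix(stats::dist(X, diag = TRUE, upper = TRUE))
  P <- cbind(1, X)
  A <- rbind(cbind(K + lambda * diag(n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(Y, matrix(0, 4, 3))
  coef <- solve(A, rhs)
  # one step of iterative refinement for the bordered system
  coef <- coef + solve(A, rhs - A %*% coef)
  structure(list(src = X, w = coef[seq_len(n), , drop = FALSE],
                 affine = coef[n + 1:4, , drop = FALSE],
                 lambda = lambda),
            class = "tps_warp")
}

#' Evaluate a thin-plate-spline warp at points
#'
#' @param object a \code{tps_warp}.
#' @param points k x 3 matrix of points (mm).
#' @param ... unused.
#' @return k x 3 matrix of warped points.
#' @export
predict.tps_warp <- function(object, points, ...) {
  p <- as.matrix(points)
  U <- .cross_dist(p, object$src)
  cbind(1, p) %*% object$affine + U %*% object$w
}

# |p_i - q_j| distance matrix (difference form: stable near zero)
.cross_dist <- function(p, q) {
  d2 <- outer(p[, 1], q[, 1], "-")^2 + outer(p[, 2], q[, 2], "-")^2 +
    outer(p[, 3], q[, 3], "-")^2
  sqrt(d2)
}

#' @export
print.tps_warp <- function(x, ...) {
  cat(sprintf("<tps_warp> %d landmarks, lambda = %g\n",
              nrow(x$src), x$lambda))
  invisible(x)
}
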