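# Geometry of latent trajectories: total-least-squares plane fits, unsigned
# dihedral angles between latent subspaces, the linear angle-frequency
# relationship, and direct least-squares elliptic attractor fits.

traj_points <- function(traj) {
  if (inherits(traj, "latent_trajectory")) traj$Z
  else if (is.matrix(traj)) traj
  else stopf("expected a latent_trajectory or a numeric matrix of points")
}

# Deterministic sign convention: first nonzero component positive.
fix_sign <- function(v) {
  nz <- which(abs(v) > 1e-12)
  if (length(nz) && v[nz[1L]] < 0) -v else v
}

#' Fit a plane to a 3-D trajectory
#'
#' Total least squares: the plane through the centroid spanned by the top two
#' principal directions of the centered points (the "acupuncture modes" p1 and
#' p2); the third direction is the plane normal. Signs are fixed so the first
#' nonzero component of each basis vector is positive.
#'
#' @param traj A `latent_trajectory` (first 3 columns used) or an `n x 3`
#'   matrix with at least 3 non-collinear points.
#' @return An object of class `plane_model`: `centroid`, `p1`, `p2`, `normal`
#'   (unit 3-vectors), `residual_frac` (fraction of variance off-plane).
#' @export
fit_plane <- function(traj) {
  P <- traj_points(traj)
  if (ncol(P) < 3L) stopf("plane fitting needs 3-dimensional points")
  P <- P[, 1:3, drop = FALSE]
  if (nrow(P) < 3L) stopf("plane fitting needs at least 3 points")
  centroid <- colMeans(P)
  Pc <- sweep(P, 2L, centroid)
  sv <- svd(Pc)
  if (sv$d[2L] <= max(sv$d[1L] * 1e-10, 1e-12)) {
    stopf("degenerate geometry: points are collinear (or coincident)")
  }
  tot <- sum(sv$d^2)
  structure(
    list(centroid = centroid,
         p1 = fix_sign(sv$v[, 1L]), p2 = fix_sign(sv$v[, 2L]),
         normal = fix_sign(sv$v[, 3L]),
         residual_frac = sv$d[3L]^2 / tot),
    class = "plane_model")
}

#' @export
print.plane_model <- function(x, ...) {
  cat(sprintf("<plane_model> normal = (%.3f, %.3f, %.3f), off-plane variance %.2g\n",
              x$normal[1L], x$normal[2L], x$normal[3L], x$residual_frac))
  invisible(x)
}

#' Unsigned dihedral angle between two planes
#'
#' `acos(|n_a . n_b|)` in degrees, range `[0, 90]`; symmetric in its
#' arguments.
#'
#' @param a,b `plane_model` objects.
#' @return Angle in degrees.
#' @export
plane_angle <- function(a, b) {
  stopifnot(inherits(a, "plane_model"), inherits(b, "plane_model"))
  c0 <- abs(sum(a$normal * b$normal))
  acos(min(1, max(-1, c0))) * 180 / pi
}

#' Linear regression of plane angle on manipulation frequency
#'
#' Ordinary least squares of the inter-plane angle on the manipulation
#' frequency across trials.
#'
#' @param angles Angles in degrees, one per trial.
#' @param freqs Manipulation frequencies in times/min, one per trial
#'   (at least 3 distinct values).
#' @return List with `slope` (deg per times/min), `intercept` (deg),
#'   `r_squared`.
#' @export
angle_frequency_regression <- function(angles, freqs) {
  if (length(angles) != length(freqs)) stopf("angles and freqs must have equal length")
  if (length(unique(freqs)) < 3L) stopf("need at least 3 distinct frequencies")
  fit <- stats::lm(angles ~ freqs)
  sst <- sum((angles - mean(angles))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 0
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2)
}

#' Project a trajectory into a plane's 2-D coordinates
#'
#' Coordinates `((x - centroid) . p1, (x - centroid) . p2)`; for in-plane
#' points the projection is exact and idempotent.
#'
#' @param traj A `latent_trajectory` or `n x 3` matrix.
#' @param plane A `plane_model`.
#' @return `n x 2` matrix of in-plane coordinates.
#' @export
project_to_plane <- function(traj, plane) {
  stopifnot(inherits(plane, "plane_model"))
  P <- traj_points(traj)[, 1:3, drop = FALSE]
  sweep(P, 2L, plane$centroid) %*% cbind(plane$p1, plane$p2)
}

#' Fit an ellipse to 2-D points by the direct least-squares conic method
#'
#' Numerically stable direct algebraic fit with the ellipse constraint
#' (4ac - b^2 = 1): deterministic, closed form, no initialization. Semi-axes
#' and orientation are extracted from the conic's eigen-structure.
#'
#' @param points `n x 2` matrix with at least 6 non-collinear points.
#' @return An object of class `ellipse_attractor`: `center` (2-vector),
#'   `long_axis` (a), `short_axis` (b), `orientation` (radians in `[0, pi)`),
#'   `fit_residual` (RMS algebraic distance on the unit-norm conic).
#' @export
fit_ellipse <- function(points) {
  P <- as.matrix(points)
  if (ncol(P) != 2L) stopf("fit_ellipse expects n x 2 points")
  if (nrow(P) < 6L) stopf("ellipse fitting needs at least 6 points")
  x <- P[, 1L]; y <- P[, 2L]
  # guard: collinear points have no conic with the ellipse constraint
  sv <- svd(cbind(x - mean(x), y - mean(y)))$d
  if (sv[2L] <= max(sv[1L] * 1e-10, 1e-12)) {
    stopf("degenerate fit: points are collinear")
  }
  # Halir & Flusser partitioned solution of the Fitzgibbon system
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, rep(1, length(x)))
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  ei <- eigen(M)
  evec <- Re(ei$vectors)
  cond <- 4 * evec[1L, ] * evec[3L, ] - evec[2L, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) stopf("degenerate fit: no ellipse satisfies the conic constraint")
  a1 <- evec[, ok[1L]]
  coef <- unname(c(a1, Tm %*% a1))              # A, B, C, D, E, F
  A <- coef[1L]; B <- coef[2L]; C <- coef[3L]; D <- coef[4L]; E <- coef[5L]; F0 <- coef[6L]
  den <- 4 * A * C - B^2
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  # conic value at the center
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F0
  Q <- matrix(c(A, B / 2, B / 2, C), 2L, 2L)
  eq <- eigen(Q, symmetric = TRUE)
  ax <- sqrt(-Fc / eq$values)
  if (any(!is.finite(ax)) || any(ax <= 0)) stopf("degenerate fit: not an ellipse")
  ord <- order(ax, decreasing = TRUE)
  major_vec <- eq$vectors[, ord[1L]]
  orientation <- atan2(major_vec[2L], major_vec[1L]) %% pi
  nc <- sqrt(sum(coef^2))
  resid <- (A * x^2 + B * x * y + C * y^2 + D * x + E * y + F0) / nc
  structure(
    list(center = c(cx, cy), long_axis = ax[ord[1L]], short_axis = ax[ord[2L]],
         orientation = orientation, fit_residual = sqrt(mean(resid^2)),
         conic = coef),
    class = "ellipse_attractor")
}

#' @export
print.ellipse_attractor <- function(x, ...) {
  cat(sprintf("<ellipse_attractor> a = %.4g, b = %.4g, orientation %.1f deg, RMS resid %.2g\n",
              x$long_axis, x$short_axis, x$orientation * 180 / pi, x$fit_residual))
  invisible(x)
}

#' Per-condition summary of attractor axes
#'
#' Mean and variance of the long and short semi-axes across trials, grouped by
#' condition.
#'
#' @param fits Either a list of `ellipse_attractor` objects with a parallel
#'   `conditions` vector, or a `data.frame` with columns `condition`,
#'   `long_axis` (or `a`), `short_axis` (or `b`).
#' @param conditions Condition label per fit (when `fits` is a list).
#' @return `data.frame` with columns `condition`, `n`, `mean_a`, `var_a`,
#'   `mean_b`, `var_b`; one row per condition (>= 2 trials each required).
#' @export
attractor_stats <- function(fits, conditions = NULL) {
  if (is.data.frame(fits)) {
    df <- fits
    if (!"long_axis" %in% names(df) && "a" %in% names(df)) df$long_axis <- df$a
    if (!"short_axis" %in% names(df) && "b" %in% names(df)) df$short_axis <- df$b
  } else {
    if (is.null(conditions) || length(conditions) != length(fits)) {
      stopf("`conditions` must label each fit")
    }
    df <- data.frame(
      condition = conditions,
      long_axis = vapply(fits, function(f) f$long_axis, numeric(1)),
      short_axis = vapply(fits, function(f) f$short_axis, numeric(1)))
  }
  if (!nrow(df)) stopf("no fits to summarize")
  sp <- split(df, df$condition)
  out <- do.call(rbind, lapply(sp, function(g) {
    if (nrow(g) < 2L) {
      stopf("condition '%s' has %d trial(s); need at least 2", g$condition[1L], nrow(g))
    }
    data.frame(condition = g$condition[1L], n = nrow(g),
               mean_a = mean(g$long_axis), var_a = stats::var(g$long_axis),
               mean_b = mean(g$short_axis), var_b = stats::var(g$short_axis))
  }))
  rownames(out) <- NULL
  out
}
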