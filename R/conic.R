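#' Conic and ellipse-geometry representations
#'
#' The active-ellipse tracker works with the conic
#' `a x^2 + b x y + c y^2 + d x + e y = 1`, which is an ellipse when
#' `b^2 - 4 a c < 0`.  `conic_vector()` builds the coefficient object;
#' `ellipse_geometry()` is the equivalent geometric view (center, semi-axes,
#' major-axis angle).
#'
#' @param a,b,c,d,e conic coefficients.
#' @return Object of class `conic_vector` (a named numeric vector).
#' @export
conic_vector <- function(a, b, c, d, e) {
  v <- c(a = a, b = b, c = c, d = d, e = e)
  if (!all(is.finite(v))) stop("non-finite conic coefficients")
  structure(v, class = "conic_vector")
}

#' @param x0,y0 ellipse center in pixels.
#' @param semi_major,semi_minor semi-axes in pixels
#'   (`semi_major >= semi_minor > 0`).
#' @param angle major-axis angle in radians from +x, in `(-pi/2, pi/2]`.
#' @rdname conic_vector
#' @export
ellipse_geometry <- function(x0, y0, semi_major, semi_minor, angle = 0) {
  stopifnot(semi_major >= semi_minor, semi_minor > 0)
  angle <- .wrap_half_pi(angle)
  structure(list(x0 = x0, y0 = y0, semi_major = semi_major,
                 semi_minor = semi_minor, angle = angle),
            class = "ellipse_geometry")
}

#' @export
print.ellipse_geometry <- function(x, ...) {
  cat(sprintf(
    "<ellipse center (%.2f, %.2f), semi-axes %.2f x %.2f px, angle %.1f deg>\n",
    x$x0, x$y0, x$semi_major, x$semi_minor, 180 * x$angle / pi))
  invisible(x)
}

.wrap_half_pi <- function(angle) {
  angle <- ((angle + pi / 2) %% pi) - pi / 2
  if (angle <= -pi / 2 + 1e-15) angle <- angle + pi
  if (angle > pi / 2) angle <- angle - pi
  angle
}

#' Least-squares conic fit
#'
#' Fits `a x^2 + b x y + c y^2 + d x + e y = 1` to a set of points by
#' minimizing the sum of squared algebraic residuals, i.e. the least-squares
#' solution of the overdetermined linear system `X A = 1`, computed by QR
#' with column equilibration (each design column scaled to unit norm).
#' Column scaling is an exact reparameterization of the same least-squares
#' problem, so the minimizer is exact while the QR never squares the
#' condition number the way normal equations would.  Note that translating
#' the points first would silently change the problem: the "= 1"
#' normalization of the conic is not translation invariant.
#'
#' @param points n x 2 matrix of (x, y) coordinates, n >= 5.
#' @param check if `TRUE` (default) the fit errors with "non-elliptical fit"
#'   unless `b^2 - 4 a c < 0`; set to `FALSE` to obtain the unconstrained
#'   least-squares conic.
#' @return A [conic_vector()].
#' @export
fit_conic_lsq <- function(points, check = TRUE) {
  stopifnot(is.matrix(points), ncol(points) == 2)
  if (nrow(points) < 5) stop("degenerate point set: need at least 5 points")
  x <- points[, 1]; y <- points[, 2]
  X <- cbind(x^2, x * y, y^2, x, y)
  cs <- sqrt(colSums(X^2))
  if (any(cs == 0)) stop("degenerate point set: rank-deficient design")
  qrX <- qr(sweep(X, 2, cs, "/"))
  if (qrX$rank < 5) stop("degenerate point set: rank-deficient design")
  A <- unname(qr.coef(qrX, rep(1, nrow(points))) / cs)
  out <- conic_vector(A[1], A[2], A[3], A[4], A[5])
  if (check && !(out["b"]^2 - 4 * out["a"] * out["c"] < 0))
    stop("non-elliptical fit")
  out
}

#' Convert a conic to ellipse geometry
#'
#' @param conic a [conic_vector()] with `b^2 - 4 a c < 0`.
#' @return An [ellipse_geometry()].  For a circle the angle is reported as 0.
#' @export
conic_to_geometry <- function(conic) {
  stopifnot(inherits(conic, "conic_vector"))
  a <- conic[["a"]]; b <- conic[["b"]]; cc <- conic[["c"]]
  d <- conic[["d"]]; e <- conic[["e"]]
  if (!(b^2 - 4 * a * cc < 0)) stop("non-elliptical conic")
  M <- matrix(c(2 * a, b, b, 2 * cc), 2, 2)
  ctr <- solve(M, c(-d, -e))
  x0 <- ctr[1]; y0 <- ctr[2]
  c0 <- a * x0^2 + b * x0 * y0 + cc * y0^2 + d * x0 + e * y0
  k <- 1 - c0
  Q <- matrix(c(a, b / 2, b / 2, cc), 2, 2) / k
  ev <- eigen(Q, symmetric = TRUE)
  if (any(ev$values <= 0)) stop("non-elliptical conic")
  semi <- 1 / sqrt(ev$values)            # descending semi-axes
  major_vec <- ev$vectors[, which.max(semi)]
  angle <- if (abs(semi[1] - semi[2]) < 1e-9 * max(semi)) 0 else
    atan2(major_vec[2], major_vec[1])
  ellipse_geometry(x0, y0, max(semi), min(semi), .wrap_half_pi(angle))
}

#' Convert ellipse geometry to a conic
#'
#' Inverse of [conic_to_geometry()]: round-tripping preserves all geometric
#' fields to 1e-9.
#'
#' @param geom an [ellipse_geometry()].
#' @return A [conic_vector()].
#' @export
geometry_to_conic <- function(geom) {
  stopifnot(inherits(geom, "ellipse_geometry"))
  Q <- .geom_quadform(geom)
  ctr <- c(geom$x0, geom$y0)
  k <- 1 - drop(ctr %*% Q %*% ctr)
  if (abs(k) < 1e-12)
    stop("ellipse passes through the origin; conic '= 1' form undefined")
  lin <- -2 * drop(Q %*% ctr)
  conic_vector(Q[1, 1] / k, 2 * Q[1, 2] / k, Q[2, 2] / k,
               lin[1] / k, lin[2] / k)
}

# Conic coefficients re-expressed in a shape-local frame u = (p - p0) / s
# (renormalized to "= 1" form).  In the raw "= 1" parameterization the
# coefficients of a vessel-sized conic far from the image origin are tiny
# and nearly insensitive to the shape, so a fixed tolerance on them is
# meaningless; in the local frame (p0 = current center, s = geometric-mean
# semi-axis) they are O(1) and a coefficient change of t corresponds to a
# boundary motion of about s * t / 2 pixels.
.conic_local <- function(conic, x0, y0, s) {
  a <- conic[["a"]]; b <- conic[["b"]]; cc <- conic[["c"]]
  d <- conic[["d"]]; e <- conic[["e"]]
  c0 <- a * x0^2 + b * x0 * y0 + cc * y0^2 + d * x0 + e * y0
  k <- 1 - c0
  c(a * s^2, b * s^2, cc * s^2,
    (2 * a * x0 + b * y0 + d) * s,
    (b * x0 + 2 * cc * y0 + e) * s) / k
}

# centered quadratic form: (p - c)' Q (p - c) = 1
.geom_quadform <- function(geom) {
  u1 <- c(cos(geom$angle), sin(geom$angle))
  u2 <- c(-sin(geom$angle), cos(geom$angle))
  outer(u1, u1) / geom$semi_major^2 + outer(u2, u2) / geom$semi_minor^2
}

#' AP-diameter of an ellipse (maximal vertical chord)
#'
#' The AP-diameter of an elliptical cross-section is the longest vertical
#' (y-direction) chord.  For the centered quadratic form
#' `(p - c)' Q (p - c) = 1` the chord at horizontal offset `s` from the
#' center has length `(2 / Q22) * sqrt(Q22 - det(Q) s^2)`, which is maximal
#' at `s = 0` with value `2 / sqrt(Q22)`.  Note this is a chord through the
#' shape, not the vertical extent of the bounding box; for rotated ellipses
#' the two differ.
#'
#' @param geom an [ellipse_geometry()].
#' @param spacing pixel spacing in cm per pixel (1 gives pixels).
#' @return Length in cm (or pixels if `spacing = 1`).
#' @export
ellipse_ap_diameter <- function(geom, spacing) {
  stopifnot(inherits(geom, "ellipse_geometry"))
  q22 <- sin(geom$angle)^2 / geom$semi_major^2 +
         cos(geom$angle)^2 / geom$semi_minor^2
  2 / sqrt(q22) * spacing
}
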