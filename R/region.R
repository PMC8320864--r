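#' Contour samples
#'
#' Sampled boundary points of a shape together with their outward unit
#' normals and (once computed) the per-point evolution forces in pixels of
#' displacement along the normal.
#'
#' @param points K x 2 matrix of continuous (x, y) coordinates.
#' @param normals K x 2 matrix of outward unit normal vectors.
#' @param forces numeric vector of length K (defaults to zeros).
#' @return Object of class `contour_samples`.
#' @export
contour_samples <- function(points, normals, forces = rep(0, nrow(points))) {
  stopifnot(is.matrix(points), ncol(points) == 2,
            is.matrix(normals), ncol(normals) == 2,
            nrow(points) == nrow(normals),
            length(forces) == nrow(points))
  nrm <- sqrt(rowSums(normals^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("normals must have unit norm")
  structure(list(points = points, normals = normals, forces = forces),
            class = "contour_samples")
}

#' Region statistics: inside and outside-band mean intensity
#'
#' Computes `u`, the mean intensity over the pixels whose centers lie in the
#' inside mask, and `v`, the mean intensity over the band of pixels within
#' `band_width` pixels outside the mask (morphological dilation with a disc
#' structuring element, minus the mask, clipped to the frame).
#'
#' @param fr an [frame()] object.
#' @param inside_mask logical matrix of the frame's dimensions.
#' @param band_width band width in pixels (>= 1).
#' @return List with fields `u` and `v`, class `region_stats`.
#' @export
region_means <- function(fr, inside_mask, band_width = 10) {
  stopifnot(inherits(fr, "ivc_frame"), is.logical(inside_mask),
            all(dim(inside_mask) == dim(fr$pixels)), band_width >= 1)
  n_in <- sum(inside_mask)
  if (n_in == 0) stop("empty inside mask")
  if (n_in == length(inside_mask)) stop("mask covers the whole frame")
  dil <- EBImage::dilate(inside_mask * 1, .disc_kernel(band_width)) > 0.5
  band <- dil & !inside_mask
  if (!any(band)) stop("empty outside band")
  structure(list(u = mean(fr$pixels[inside_mask]),
                 v = mean(fr$pixels[band])),
            class = "region_stats")
}

# disc structuring element: all integer offsets within Euclidean distance r
.disc_kernel <- function(r) {
  off <- seq(-ceiling(r), ceiling(r))
  outer(off, off, function(dy, dx) as.numeric(dx^2 + dy^2 <= r^2))
}

#' Evolution forces along the contour normals
#'
#' For each contour sample k with intensity `I_k` (bilinear interpolation)
#' the region-based force is `f_k = alpha * (u - v) * (2 * I_k - u - v)`,
#' clipped to `+/- force_clip`.  Positive forces displace the point outward
#' along its normal.  The force vanishes exactly where `I_k = (u + v) / 2`,
#' i.e. halfway between the inside and outside mean intensities, and is
#' antisymmetric under swapping `u` and `v`, so dark-on-bright and
#' bright-on-dark vessels are handled identically.
#'
#' @param fr an [frame()] object.
#' @param samples a [contour_samples()] object (forces are overwritten).
#' @param stats a `region_stats` object from [region_means()].
#' @param params an [evolution_params()] object.
#' @return `samples` with the `forces` field filled in and an `"oob"`
#'   attribute counting clamped sample points.
#' @export
boundary_forces <- function(fr, samples, stats, params = evolution_params()) {
  stopifnot(inherits(samples, "contour_samples"),
            inherits(stats, "region_stats"))
  I <- sample_intensity(fr, samples$points[, 1], samples$points[, 2])
  f <- params$alpha * (stats$u - stats$v) * (2 * I - stats$u - stats$v)
  f <- pmin(pmax(f, -params$force_clip), params$force_clip)
  samples$forces <- as.numeric(f)
  attr(samples, "oob") <- sum(attr(I, "oob"))
  samples
}

# ---- internal shape-region statistics used by the fit loops ----------------
#
# The fits evaluate u over the pixels whose centers lie inside the continuous
# shape and v over the pixels within a Euclidean distance `band` of the shape
# (exact offset for circle/rectangle; for the ellipse the offset curve is
# approximated by adding `band` to both semi-axes).  If the band contrast
# |u - v| falls below contrast_eps -- typically on a cold start deep inside a
# large lumen, where a thin band is uninformative -- the band is doubled until
# contrast appears or the band covers the frame.
#
# The escalation floor is expressed as a fraction (params$contrast_eps) of
# the frame's robust dynamic range (5th-95th intensity percentile), so it is
# invariant to the per-frame renormalization that heavy speckle induces.
#
# classify(xmat, ymat, band) must return list(inside = , band = ) of logical
# matrices.  bbox(band) returns c(x0, x1, y0, y1) enclosing shape + band.
.contrast_floor <- function(fr, params) {
  q <- stats::quantile(fr$pixels, c(0.05, 0.95), names = FALSE)
  params$contrast_eps * (q[2] - q[1])
}

.shape_stats <- function(fr, classify, bbox, params, eps_abs = NULL,
                         b_start = NULL) {
  if (is.null(eps_abs)) eps_abs <- .contrast_floor(fr, params)
  b <- max(params$band_width, b_start %||% 0)
  bmax <- sqrt(fr$width^2 + fr$height^2)
  repeat {
    bb <- bbox(b)
    xs <- max(1L, floor(bb[1])):min(fr$width, ceiling(bb[2]))
    ys <- max(1L, floor(bb[3])):min(fr$height, ceiling(bb[4]))
    if (length(xs) * length(ys) > 6000) {
      # wide escalated bands cover thousands of pixels; their means are
      # insensitive to 2x subsampling, which bounds the per-iteration cost
      xs <- xs[seq(1L, length(xs), 2L)]
      ys <- ys[seq(1L, length(ys), 2L)]
    }
    xm <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    ym <- matrix(ys, nrow = length(ys), ncol = length(xs))
    cls <- classify(xm, ym, b)
    px <- fr$pixels[ys, xs, drop = FALSE]
    n_in <- sum(cls$inside); n_band <- sum(cls$band)
    if (n_in == 0 || n_band == 0) {
      if (b >= bmax) stop("degenerate region: empty inside or band")
      b <- min(2 * b, bmax)
      next
    }
    u <- sum(px[cls$inside]) / n_in
    v <- sum(px[cls$band]) / n_band
    if (abs(u - v) >= eps_abs || b >= bmax)
      return(structure(list(u = u, v = v, band_used = b),
                       class = "region_stats"))
    b <- min(2 * b, bmax)
  }
}

.circle_stats <- function(fr, xc, yc, r, params, eps_abs = NULL,
                          b_start = NULL) {
  .shape_stats(
    fr,
    classify = function(xm, ym, b) {
      d2 <- (xm - xc)^2 + (ym - yc)^2
      inside <- d2 <= r^2
      list(inside = inside, band = !inside & d2 <= (r + b)^2)
    },
    bbox = function(b) c(xc - r - b, xc + r + b, yc - r - b, yc + r + b),
    params, eps_abs, b_start)
}

.rect_stats <- function(fr, xc, yc, w, h, params, eps_abs = NULL,
                        b_start = NULL) {
  .shape_stats(
    fr,
    classify = function(xm, ym, b) {
      ax <- abs(xm - xc); ay <- abs(ym - yc)
      inside <- ax <= w / 2 & ay <= h / 2
      dx <- ax - w / 2; dx <- dx * (dx > 0)
      dy <- ay - h / 2; dy <- dy * (dy > 0)
      list(inside = inside, band = !inside & dx * dx + dy * dy <= b^2)
    },
    bbox = function(b) c(xc - w / 2 - b, xc + w / 2 + b,
                         yc - h / 2 - b, yc + h / 2 + b),
    params, eps_abs, b_start)
}

.ellipse_stats <- function(fr, geom, params, eps_abs = NULL,
                           b_start = NULL) {
  ct <- cos(geom$angle); st <- sin(geom$angle)
  a <- geom$semi_major; bmin <- geom$semi_minor
  x0 <- geom$x0; y0 <- geom$y0
  ext <- max(a, bmin)
  .shape_stats(
    fr,
    classify = function(xm, ym, b) {
      dx <- xm - x0; dy <- ym - y0
      qx <- ct * dx + st * dy; qy <- -st * dx + ct * dy
      inside <- (qx / a)^2 + (qy / bmin)^2 <= 1
      band <- !inside & (qx / (a + b))^2 + (qy / (bmin + b))^2 <= 1
      list(inside = inside, band = band)
    },
    bbox = function(b) c(x0 - ext - b, x0 + ext + b,
                         y0 - ext - b, y0 + ext + b),
    params, eps_abs, b_start)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
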