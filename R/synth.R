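#' Phantom configuration
#'
#' Describes a synthetic ultrasound clip of a convex vessel cross-section:
#' a dark lumen on a brighter background with a bright rim (the typical
#' transverse appearance of the IVC), whose vertical (AP) diameter is
#' modulated in time to emulate respirophasic collapse, corrupted by
#' Rayleigh-distributed multiplicative speckle and optional acoustic
#' shadowing / boundary dropout.  The defaults emulate a 30 fps portable
#' scanner clip: 450 frames, 0.04 cm/px, a vessel about 2 cm across whose
#' AP-diameter swings by 40% over a 5 s respiratory cycle.
#'
#' @param image_size frame side length in pixels (square frames).
#' @param spacing pixel spacing in cm per pixel.
#' @param family shape family: `"circle"`, `"ellipse"` or `"blob"` (an
#'   ellipse perturbed by a low-order radial Fourier series, guaranteed
#'   star-convex).
#' @param center vessel center `c(x, y)` in pixels (default: frame center).
#' @param semi_axes base semi-axes `c(ax, ay)` in pixels before rotation and
#'   collapse; for `"circle"` the first element is the radius.
#' @param rotation rotation of the base ellipse in radians.
#' @param lumen,background mean intensities of lumen and surroundings
#'   (must differ; either polarity works).
#' @param rim_amp,rim_offset,rim_width bright-rim Gaussian: amplitude,
#'   offset outside the boundary (px) and width (px).  `rim_amp = 0`
#'   disables the rim.
#' @param edge_width boundary smoothing width in pixels.
#' @param sigma speckle severity in `[0, 1]`: the multiplicative factor is
#'   `1 + sigma * (r - 1)` with `r` unit-mean Rayleigh, so `sigma = 1` is
#'   fully developed speckle and `sigma = 0` is noise-free.
#' @param amplitude collapse amplitude fraction in `[0, 0.9]`: the vertical
#'   semi-axis is scaled by `1 - amplitude * (1 + sin(2 pi t / period +
#'   phase)) / 2` with `t` the 0-based frame index.
#' @param period collapse period in frames; `phase` in radians.
#' @param n_frames number of frames; `fps` frame rate (metadata only).
#' @param dropout optional boundary-dropout spec:
#'   `list(angle_deg, span_deg, depth_px)`; the rim/edge contrast within the
#'   arc (centered at `angle_deg`, y-down convention, -90 = top) is replaced
#'   by lumen-level intensity.
#' @param shadow optional shadow spec: `list(x0, x1, y0, y1, attenuation)`;
#'   intensities in the rectangle are multiplied by `attenuation`.
#' @param blob_coefs optional 2 x 3 matrix (amplitudes; phases) of the blob
#'   harmonics; by default drawn deterministically from `rng_seed` with
#'   total perturbation <= 15% of the mean radius.
#' @param rng_seed integer seed from which all randomness in the clip flows.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 128, spacing = 0.04,
                           family = c("ellipse", "circle", "blob"),
                           center = NULL, semi_axes = c(28, 25),
                           rotation = 0, lumen = 0.15, background = 0.55,
                           rim_amp = 0.3, rim_offset = 2, rim_width = 1.5,
                           edge_width = 2, sigma = 0.3, amplitude = 0.4,
                           period = 150, phase = 0, n_frames = 450,
                           fps = 30, dropout = NULL, shadow = NULL,
                           blob_coefs = NULL, rng_seed = 1) {
  family <- match.arg(family)
  if (is.null(center)) center <- c(image_size / 2, image_size / 2)
  stopifnot(image_size >= 32, spacing > 0, length(center) == 2,
            length(semi_axes) == 2, all(semi_axes > 0),
            lumen >= 0, lumen <= 1, background >= 0, background <= 1,
            sigma >= 0, sigma <= 1, amplitude >= 0, amplitude <= 0.9,
            period > 0, n_frames >= 1, fps > 0)
  if (lumen == background) stop("lumen and background means must differ")
  if (family == "circle") semi_axes <- rep(semi_axes[1], 2)
  cfg <- structure(
    list(image_size = as.integer(image_size), spacing = spacing,
         family = family, center = center, semi_axes = semi_axes,
         rotation = rotation, lumen = lumen, background = background,
         rim_amp = rim_amp, rim_offset = rim_offset, rim_width = rim_width,
         edge_width = edge_width, sigma = sigma, amplitude = amplitude,
         period = period, phase = phase, n_frames = as.integer(n_frames),
         fps = fps, dropout = dropout, shadow = shadow,
         blob_coefs = blob_coefs, rng_seed = as.integer(rng_seed)),
    class = "phantom_config")
  shp <- .phantom_shape(cfg)
  margin <- max(shp$max_r) + cfg$rim_offset + 3 * cfg$rim_width + 2
  lim <- min(cfg$center[1] - 1, image_size - cfg$center[1],
             cfg$center[2] - 1, image_size - cfg$center[2])
  if (margin > lim) stop("shape (plus rim) exceeds frame bounds")
  cfg
}

# base (uncollapsed) shape as a star-convex radial function about the center
.phantom_shape <- function(cfg) {
  ax <- cfg$semi_axes[1]; ay <- cfg$semi_axes[2]; th <- cfg$rotation
  if (cfg$family %in% c("circle", "ellipse")) {
    rfun <- function(phi) {
      ax * ay / sqrt((ay * cos(phi - th))^2 + (ax * sin(phi - th))^2)
    }
    list(rfun = rfun, max_r = max(ax, ay), coefs = NULL)
  } else {
    coefs <- cfg$blob_coefs
    if (is.null(coefs)) {
      coefs <- withr::with_seed(cfg$rng_seed, {
        amp <- stats::runif(3)
        amp <- amp / sum(amp) * stats::runif(1, 0.08, 0.15)
        rbind(amp, stats::runif(3, 0, 2 * pi))
      })
    }
    base <- function(phi) {
      ax * ay / sqrt((ay * cos(phi - th))^2 + (ax * sin(phi - th))^2)
    }
    rfun <- function(phi) {
      pert <- coefs[1, 1] * cos(phi + coefs[2, 1]) +
              coefs[1, 2] * cos(2 * phi + coefs[2, 2]) +
              coefs[1, 3] * cos(3 * phi + coefs[2, 3])
      base(phi) * (1 + pert)
    }
    list(rfun = rfun, max_r = max(ax, ay) * (1 + sum(coefs[1, ])),
         coefs = coefs)
  }
}

# vertical scale factor for a 0-based frame index
.collapse_scale <- function(cfg, t0) {
  1 - cfg$amplitude * (1 + sin(2 * pi * t0 / cfg$period + cfg$phase)) / 2
}

#' Render one noise-free phantom frame with its ground truth
#'
#' The vessel is rendered from an approximate signed distance to the
#' (collapse-scaled) contour: a logistic edge of width `edge_width` between
#' lumen and background plus a Gaussian bright rim just outside the
#' boundary.  The truth record carries the dense contour polyline, the true
#' center and the true AP-diameter (maximal vertical chord: closed form for
#' circle/ellipse, polyline chord maximization for blobs).
#'
#' @param config a [phantom_config()].
#' @param frame_index 1-based frame index.
#' @return List with elements `frame` (an [frame()]), `truth`
#'   (one-row data frame: frame, ap_px, ap_cm, xc, yc) and `contour`
#'   (dense polyline matrix).
#' @export
make_clean_frame <- function(config, frame_index = 1) {
  stopifnot(inherits(config, "phantom_config"), frame_index >= 1)
  shp <- .phantom_shape(config)
  m <- .collapse_scale(config, frame_index - 1)
  n <- config$image_size
  cx <- config$center[1]; cy <- config$center[2]
  xm <- matrix(seq_len(n), nrow = n, ncol = n, byrow = TRUE)
  ym <- matrix(seq_len(n), nrow = n, ncol = n)
  d <- .signed_dist(xm, ym, cx, cy, m, shp$rfun)
  I <- config$lumen + (config$background - config$lumen) *
    stats::plogis(4 * d / config$edge_width)
  if (config$rim_amp > 0)
    I <- I + config$rim_amp *
      exp(-(d - config$rim_offset)^2 / (2 * config$rim_width^2))
  I <- pmin(pmax(I, 0), 1)
  phi <- 2 * pi * (0:719) / 720
  rb <- shp$rfun(phi)
  contour <- cbind(x = cx + rb * cos(phi), y = cy + m * rb * sin(phi))
  ap_px <- if (config$family == "blob") {
    max_vertical_chord(contour)
  } else {
    q22 <- .base_quadform(config)[2, 2]
    2 * m / sqrt(q22)
  }
  truth <- data.frame(frame = frame_index, ap_px = ap_px,
                      ap_cm = ap_px * config$spacing, xc = cx, yc = cy)
  list(frame = frame(I, spacing = config$spacing), truth = truth,
       contour = contour)
}

# approximate signed distance (px, positive outside) to the scaled contour
.signed_dist <- function(xm, ym, cx, cy, m, rfun) {
  dx <- xm - cx; dy <- (ym - cy) / m
  phi <- atan2(dy, dx)
  rho <- sqrt(dx^2 + dy^2)
  stretch <- sqrt(cos(phi)^2 + (m * sin(phi))^2)
  (rho - rfun(phi)) * stretch
}

# centered quadratic form of the base (uncollapsed) ellipse
.base_quadform <- function(cfg) {
  u1 <- c(cos(cfg$rotation), sin(cfg$rotation))
  u2 <- c(-sin(cfg$rotation), cos(cfg$rotation))
  outer(u1, u1) / cfg$semi_axes[1]^2 + outer(u2, u2) / cfg$semi_axes[2]^2
}

#' Maximal vertical chord of a closed polyline
#'
#' Scans vertical lines across the polygon, measuring the span between the
#' lowest and highest crossing, and maximizes over x with two rounds of grid
#' refinement (resolution far below 0.1 px for smooth convex contours).
#'
#' @param poly n x 2 matrix of (x, y) vertices of a closed contour.
#' @return The maximal vertical chord length in the polyline's units.
#' @export
max_vertical_chord <- function(poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  chord <- function(xs) vapply(xs, .vchord_at, numeric(1), poly = poly)
  rng <- range(poly[, 1])
  xs <- seq(rng[1] + 1e-6, rng[2] - 1e-6, length.out = 201)
  cs <- chord(xs)
  best <- xs[which.max(cs)]
  span <- diff(rng) / 200
  for (iter in 1:2) {
    xs <- seq(best - span, best + span, length.out = 201)
    cs <- chord(xs)
    best <- xs[which.max(cs)]
    span <- span / 100
  }
  max(cs)
}

.vchord_at <- function(x, poly) {
  x1 <- poly[, 1]
  x2 <- poly[c(2:nrow(poly), 1), 1]
  y1 <- poly[, 2]
  y2 <- poly[c(2:nrow(poly), 1), 2]
  hit <- (x1 - x) * (x2 - x) <= 0 & x1 != x2
  if (!any(hit)) return(0)
  tt <- (x - x1[hit]) / (x2[hit] - x1[hit])
  ys <- y1[hit] + tt * (y2[hit] - y1[hit])
  max(ys) - min(ys)
}

#' Unit-mean Rayleigh speckle field
#'
#' Draws an i.i.d. Rayleigh field normalized to unit mean (a Rayleigh
#' variable divided by its mean `sigma * sqrt(pi / 2)`; the result's
#' distribution is scale-free with CDF `1 - exp(-pi t^2 / 4)`).
#'
#' @param dim `c(rows, cols)` of the field.
#' @param rng_seed optional seed; if `NULL` the current RNG stream is used.
#' @return Matrix of unit-mean Rayleigh draws.
#' @export
speckle_field <- function(dim, rng_seed = NULL) {
  draw <- function() {
    matrix(sqrt(-2 * log(stats::runif(prod(dim)))) / sqrt(pi / 2),
           dim[1], dim[2])
  }
  if (is.null(rng_seed)) draw() else withr::with_seed(rng_seed, draw())
}

#' Apply multiplicative Rayleigh speckle to a frame
#'
#' Each pixel is multiplied by `1 + sigma * (r - 1)` where `r` is a
#' unit-mean Rayleigh draw ([speckle_field()]), so `sigma = 1` is pure
#' unit-mean Rayleigh multiplicative speckle and the output approaches the
#' input as `sigma` approaches 0.  The result is renormalized to \[0, 1\]
#' by a saturated contrast stretch (0.5/99.5 intensity percentiles, values
#' beyond them clipped), the standard display normalization for
#' envelope-detected ultrasound; a plain min-max rescale would let the few
#' brightest speckle draws compress the tissue contrast that the trackers'
#' force law is driven by.
#'
#' @param fr an [frame()] object.
#' @param sigma speckle severity in `[0, 1]`.
#' @param rng_seed optional seed; `NULL` uses the current RNG stream.
#' @return A speckled [frame()].
#' @export
apply_speckle <- function(fr, sigma, rng_seed = NULL) {
  stopifnot(inherits(fr, "ivc_frame"), sigma >= 0, sigma <= 1)
  r <- speckle_field(c(fr$height, fr$width), rng_seed)
  fac <- pmax(1 + sigma * (r - 1), 0)
  frame(.stretch01(fr$pixels * fac), spacing = fr$spacing)
}

# saturated contrast stretch: clip at the given percentiles, rescale to [0,1]
.stretch01 <- function(x, lo_p = 0.005, hi_p = 0.995) {
  q <- stats::quantile(x, c(lo_p, hi_p), names = FALSE)
  if (q[2] <= q[1]) stop("degenerate frame: constant image")
  pmin(pmax((x - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Apply acoustic-shadow and boundary-dropout artifacts
#'
#' A shadow multiplies a rectangular region by its attenuation factor.  A
#' dropout erases the edge/rim contrast along a boundary arc by blending the
#' intensity toward the lumen level within `depth_px` of the contour, with a
#' raised-cosine angular profile.  With both specs `NULL` the frame is
#' returned unchanged.
#'
#' @param fr an [frame()] object.
#' @param dropout `list(angle_deg, span_deg, depth_px)` or `NULL`.
#' @param shadow `list(x0, x1, y0, y1, attenuation)` or `NULL`.
#' @param config the [phantom_config()] describing the vessel (required for
#'   dropout, which needs the contour geometry).
#' @param frame_index 1-based frame index (for the collapse phase).
#' @return The modified [frame()].
#' @export
apply_artifacts <- function(fr, dropout = NULL, shadow = NULL,
                            config = NULL, frame_index = 1) {
  stopifnot(inherits(fr, "ivc_frame"))
  I <- fr$pixels
  if (!is.null(dropout)) {
    if (is.null(config)) stop("dropout requires the phantom config")
    shp <- .phantom_shape(config)
    m <- .collapse_scale(config, frame_index - 1)
    n <- fr$height
    xm <- matrix(seq_len(fr$width), nrow = n, ncol = fr$width, byrow = TRUE)
    ym <- matrix(seq_len(n), nrow = n, ncol = fr$width)
    d <- .signed_dist(xm, ym, config$center[1], config$center[2], m,
                      shp$rfun)
    phi <- atan2(ym - config$center[2], xm - config$center[1])
    dphi <- abs((phi - dropout$angle_deg * pi / 180 + pi) %% (2 * pi) - pi)
    half <- dropout$span_deg * pi / 360
    taper <- 15 * pi / 180
    # full-strength plateau across the arc, cosine taper just outside it
    wphi <- ifelse(dphi <= half, 1,
                   ifelse(dphi <= half + taper,
                          0.5 * (1 + cos(pi * (dphi - half) / taper)), 0))
    wd <- exp(-0.5 * (d / dropout$depth_px)^4)
    I <- I + (config$lumen - I) * wphi * wd
  }
  if (!is.null(shadow)) {
    rows <- max(1, shadow$y0):min(fr$height, shadow$y1)
    cols <- max(1, shadow$x0):min(fr$width, shadow$x1)
    I[rows, cols] <- I[rows, cols] * shadow$attenuation
  }
  frame(pmin(pmax(I, 0), 1), spacing = fr$spacing)
}

#' Generate a phantom clip in memory
#'
#' Renders every frame of the configured clip (clean frame, artifacts,
#' speckle) together with the aligned ground-truth table.  All randomness
#' flows from `config$rng_seed`, so the output is fully reproducible.
#'
#' @param config a [phantom_config()].
#' @return List with `frames` (list of [frame()]), `truth` (data frame with
#'   columns frame, ap_px, ap_cm, xc, yc) and `contours` (list of dense
#'   truth polylines).
#' @export
generate_frames <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$rng_seed, {
    out <- vector("list", config$n_frames)
    for (t in seq_len(config$n_frames)) {
      cf <- make_clean_frame(config, t)
      fr <- apply_artifacts(cf$frame, config$dropout, config$shadow,
                            config, t)
      if (config$sigma > 0) fr <- apply_speckle(fr, config$sigma)
      out[[t]] <- list(frame = fr, truth = cf$truth, contour = cf$contour)
    }
    list(frames = lapply(out, `[[`, "frame"),
         truth = do.call(rbind, lapply(out, `[[`, "truth")),
         contours = lapply(out, `[[`, "contour"))
  })
}

#' Write a phantom clip to disk
#'
#' Writes numbered 16-bit TIFF frames (`frame_0001.tif`, ...) plus a
#' `truth.csv` aligned to the tracker's output schema, fully reproducible
#' from the config.
#'
#' @param config a [phantom_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `dir`, `files` and `truth`.
#' @export
generate_clip <- function(config, out_dir) {
  clip <- generate_frames(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(out_dir,
                     sprintf("frame_%04d.tif", seq_along(clip$frames)))
  for (i in seq_along(files))
    tiff::writeTIFF(clip$frames[[i]]$pixels, files[i], bits.per.sample = 16)
  utils::write.csv(format(clip$truth, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   file.path(out_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(dir = out_dir, files = files, truth = clip$truth))
}
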