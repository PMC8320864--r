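#' Sample an ellipse contour
#'
#' Places `K` points at uniform parametric angles on the ellipse; the outward
#' unit normal at each point is the (normalized) gradient of the conic,
#' oriented away from the center.  For a circle this reduces exactly to
#' [sample_circle()].
#'
#' @param geom an [ellipse_geometry()].
#' @param K number of contour points.
#' @return A [contour_samples()] object.
#' @export
sample_ellipse <- function(geom, K) {
  stopifnot(inherits(geom, "ellipse_geometry"), K >= 3)
  t <- 2 * pi * (0:(K - 1)) / K
  u1 <- c(cos(geom$angle), sin(geom$angle))
  u2 <- c(-sin(geom$angle), cos(geom$angle))
  p <- cbind(geom$x0 + geom$semi_major * cos(t) * u1[1] +
               geom$semi_minor * sin(t) * u2[1],
             geom$y0 + geom$semi_major * cos(t) * u1[2] +
               geom$semi_minor * sin(t) * u2[2])
  Q <- .geom_quadform(geom)
  rel <- cbind(p[, 1] - geom$x0, p[, 2] - geom$y0)
  g <- 2 * rel %*% Q                      # gradient of the centered form
  g <- g / sqrt(rowSums(g^2))
  flip <- rowSums(g * rel) < 0
  g[flip, ] <- -g[flip, ]
  contour_samples(p, g)
}

#' Evolve contour points along their normals
#'
#' Moves each sampled point by its force along its outward normal:
#' `p_k <- p_k + f_k n_k`.
#'
#' @param samples a [contour_samples()] with forces computed.
#' @return n x 2 matrix of evolved points.
#' @export
evolve_points <- function(samples) {
  stopifnot(inherits(samples, "contour_samples"))
  samples$points + samples$forces * samples$normals
}

#' Fit an active ellipse to a frame
#'
#' Iterates sample / region statistics / forces / point evolution / conic
#' least-squares refit / geometry extraction.  Convergence is declared when
#' the largest change in the conic coefficient vector, expressed in a
#' shape-local normalized frame where the coefficients are O(1), falls
#' below `tol` (default 1e-4); the sub-threshold refit is then discarded so
#' the returned geometry is a fixed point of the iteration.  A refit that is not an
#' ellipse (or is otherwise degenerate) falls back to the previous geometry;
#' more than 10 consecutive fallbacks declare the target lost.
#'
#' @param fr an [frame()] object.
#' @param init initial [ellipse_geometry()] (must lie inside the frame).
#' @param params an [evolution_params()] object.
#' @return List with elements `state` (the fitted [ellipse_geometry()]) and
#'   `diagnostics` (iterations, converged, lost, fallbacks, final_delta,
#'   band_used).
#' @export
fit_ellipse <- function(fr, init, params = evolution_params()) {
  stopifnot(inherits(fr, "ivc_frame"), inherits(init, "ellipse_geometry"))
  geom <- .clamp_ellipse(init, fr)
  conic_cur <- geometry_to_conic(geom)
  eps_abs <- .contrast_floor(fr, params)
  b_start <- params$band_width
  fail_streak <- 0L
  diag <- list(iterations = 0L, converged = FALSE, lost = FALSE,
               fallbacks = 0L, final_delta = NA_real_,
               band_used = params$band_width)
  for (i in seq_len(params$max_iter)) {
    diag$iterations <- i
    samples <- sample_ellipse(geom, params$K)
    stats <- .ellipse_stats(fr, geom, params, eps_abs, b_start)
    b_start <- if (i %% 8L == 0L) stats$band_used / 2 else stats$band_used
    samples <- boundary_forces(fr, samples, stats, params)
    pts <- evolve_points(samples)
    step <- tryCatch({
      conic_new <- fit_conic_lsq(pts)
      geom_new <- conic_to_geometry(conic_new)
      list(conic = conic_new, geom = geom_new)
    }, error = function(e) NULL)
    diag$band_used <- stats$band_used
    if (is.null(step)) {
      diag$fallbacks <- diag$fallbacks + 1L
      fail_streak <- fail_streak + 1L
      if (fail_streak > 10L) {
        diag$lost <- TRUE
        break
      }
      next
    }
    fail_streak <- 0L
    geom_new <- .clamp_ellipse(step$geom, fr)
    conic_new <- if (identical(geom_new, step$geom)) step$conic else
      geometry_to_conic(geom_new)
    s <- sqrt(geom$semi_major * geom$semi_minor)
    delta <- max(abs(.conic_local(conic_new, geom$x0, geom$y0, s) -
                     .conic_local(conic_cur, geom$x0, geom$y0, s)))
    diag$final_delta <- delta
    if (delta < params$tol) {
      diag$converged <- TRUE
      break
    }
    geom <- geom_new
    conic_cur <- conic_new
  }
  list(state = geom, diagnostics = diag)
}

# keep the ellipse center inside the frame and the axes sane
.clamp_ellipse <- function(geom, fr) {
  half <- (min(fr$width, fr$height) - 1) / 2
  a <- min(geom$semi_major, half)
  b <- max(min(geom$semi_minor, a), 0.5)
  x0 <- min(max(geom$x0, 2), fr$width - 1)
  y0 <- min(max(geom$y0, 2), fr$height - 1)
  if (a == geom$semi_major && b == geom$semi_minor &&
      x0 == geom$x0 && y0 == geom$y0) return(geom)
  ellipse_geometry(x0, y0, a, b, geom$angle)
}
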