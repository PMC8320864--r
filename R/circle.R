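#' Circle state
#'
#' The active-circle tracker's state: center `(xc, yc)` and radius `r`, all
#' in pixels.
#'
#' @param xc,yc circle center in pixels.
#' @param r radius in pixels (> 0).
#' @return Object of class `circle_state`.
#' @export
circle_state <- function(xc, yc, r) {
  stopifnot(is.numeric(xc), is.numeric(yc), is.numeric(r), r > 0)
  structure(list(xc = xc, yc = yc, r = r), class = "circle_state")
}

#' @export
print.circle_state <- function(x, ...) {
  cat(sprintf("<circle_state center (%.2f, %.2f), r %.2f px>\n",
              x$xc, x$yc, x$r))
  invisible(x)
}

#' Sample a circle contour
#'
#' Places `K` points at uniform polar angles `theta_k = 2 k pi / K`,
#' k = 0..K-1; the outward unit normal at each point is
#' `(cos theta_k, sin theta_k)`, i.e. the radial direction.
#'
#' @param state a [circle_state()].
#' @param K number of contour points.
#' @return A [contour_samples()] object.
#' @export
sample_circle <- function(state, K) {
  stopifnot(inherits(state, "circle_state"), K >= 3)
  theta <- 2 * pi * (0:(K - 1)) / K
  n <- cbind(cos(theta), sin(theta))
  p <- cbind(state$xc + state$r * n[, 1], state$yc + state$r * n[, 2])
  contour_samples(p, n)
}

#' One circle evolution step
#'
#' The center is translated by the average force vector,
#' `center += mean(f_k n_k)`, and the radius by the average force magnitude,
#' `r += mean(f_k)`, clamped below at `r_min`.  Because the normals of a
#' uniformly sampled circle sum to zero, a constant force changes only the
#' radius, never the center.
#'
#' @param state a [circle_state()].
#' @param samples a [contour_samples()] with forces computed.
#' @param r_min radius collapse guard in pixels.
#' @return Updated [circle_state()].
#' @export
evolve_circle_step <- function(state, samples, r_min = 2) {
  stopifnot(inherits(state, "circle_state"),
            inherits(samples, "contour_samples"))
  f <- samples$forces
  circle_state(state$xc + mean(f * samples$normals[, 1]),
               state$yc + mean(f * samples$normals[, 2]),
               max(state$r + mean(f), r_min))
}

# keep the circle fully inside the frame
.clamp_circle <- function(state, fr, r_min) {
  r <- min(state$r, (min(fr$width, fr$height) - 1) / 2)
  xc <- min(max(state$xc, 1 + r_min), fr$width - r_min)
  yc <- min(max(state$yc, 1 + r_min), fr$height - r_min)
  r <- max(min(r, xc - 1, fr$width - xc, yc - 1, fr$height - yc), r_min)
  circle_state(xc, yc, r)
}

#' Fit an active circle to a frame
#'
#' Iterates sample / region statistics / forces / parameter update until the
#' largest change in `(xc, yc, r)` falls below `tol * max(1, r)` or
#' `max_iter` is reached.  On convergence the sub-threshold update is
#' discarded, so the returned state is an exact fixed point of the
#' iteration.  If the radius sits at the collapse guard `r_min` for 10
#' consecutive iterations the target is declared lost.
#'
#' @param fr an [frame()] object.
#' @param init initial [circle_state()] (must lie inside the frame).
#' @param params an [evolution_params()] object.
#' @return List with elements `state` (the fitted [circle_state()]) and
#'   `diagnostics` (iterations, converged, lost, final_delta, band_used).
#' @export
fit_circle <- function(fr, init, params = evolution_params()) {
  stopifnot(inherits(fr, "ivc_frame"), inherits(init, "circle_state"))
  state <- .clamp_circle(init, fr, params$r_min)
  eps_abs <- .contrast_floor(fr, params)
  b_start <- params$band_width
  collapse <- 0L
  diag <- list(iterations = 0L, converged = FALSE, lost = FALSE,
               final_delta = NA_real_, band_used = params$band_width)
  for (i in seq_len(params$max_iter)) {
    samples <- sample_circle(state, params$K)
    stats <- .circle_stats(fr, state$xc, state$yc, state$r, params, eps_abs,
                           b_start)
    b_start <- if (i %% 8L == 0L) stats$band_used / 2 else stats$band_used
    samples <- boundary_forces(fr, samples, stats, params)
    new <- evolve_circle_step(state, samples, params$r_min)
    new <- .clamp_circle(new, fr, params$r_min)
    delta <- max(abs(new$xc - state$xc), abs(new$yc - state$yc),
                 abs(new$r - state$r))
    diag$iterations <- i
    diag$final_delta <- delta
    diag$band_used <- stats$band_used
    if (delta < params$tol * max(1, state$r)) {
      # stabilizing while pinned at the collapse guard is a loss, not a fit
      if (state$r <= params$r_min + 1e-9) diag$lost <- TRUE
      else diag$converged <- TRUE
      break
    }
    state <- new
    collapse <- if (state$r <= params$r_min) collapse + 1L else 0L
    if (collapse >= 10L) {
      diag$lost <- TRUE
      break
    }
  }
  list(state = state, diagnostics = diag)
}

#' AP-diameter of a fitted circle
#'
#' The circle models the AP-diameter as its diameter: `2 * r * spacing`.
#'
#' @param state a [circle_state()].
#' @param spacing pixel spacing in cm per pixel (1 gives pixels).
#' @return Length in cm (or pixels if `spacing = 1`).
#' @export
circle_ap_diameter <- function(state, spacing) {
  stopifnot(inherits(state, "circle_state"))
  2 * state$r * spacing
}
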