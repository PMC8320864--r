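#' Rectangle state
#'
#' The active-rectangle tracker's state: an axis-aligned rectangle with
#' center `(xc, yc)`, width `w` (horizontal) and height `h` (vertical), all
#' in pixels.  The height models the AP-diameter; the width is controlled by
#' the annealing schedule, not by image forces.
#'
#' @param xc,yc rectangle center in pixels.
#' @param w width in pixels (> 0).
#' @param h height in pixels (> 0).
#' @return Object of class `rectangle_state`.
#' @export
rectangle_state <- function(xc, yc, w, h) {
  stopifnot(w > 0, h > 0)
  structure(list(xc = xc, yc = yc, w = w, h = h), class = "rectangle_state")
}

#' @export
print.rectangle_state <- function(x, ...) {
  cat(sprintf("<rectangle_state center (%.2f, %.2f), w %.2f, h %.2f px>\n",
              x$xc, x$yc, x$w, x$h))
  invisible(x)
}

#' Sample a rectangle contour by side
#'
#' Places points at approximately `spacing_px` spacing along each of the four
#' sides, corners excluded, with at least 3 points per side.  Normals are the
#' axis-aligned outward directions (y-down convention): left `(-1, 0)`,
#' right `(+1, 0)`, upper `(0, -1)`, lower `(0, +1)`.
#'
#' @param state a [rectangle_state()].
#' @param spacing_px target sample spacing along each side in pixels.
#' @return A [contour_samples()] object with an extra `side` field, a factor
#'   with levels `l`, `r`, `u`, `b` identifying each point's side.
#' @export
sample_rectangle <- function(state, spacing_px = 1) {
  stopifnot(inherits(state, "rectangle_state"), spacing_px > 0)
  n_h <- max(3L, ceiling(state$w / spacing_px) - 1L)  # along upper/lower
  n_v <- max(3L, ceiling(state$h / spacing_px) - 1L)  # along left/right
  xs <- state$xc + seq(-state$w / 2, state$w / 2,
                       length.out = n_h + 2)[2:(n_h + 1)]
  ys <- state$yc + seq(-state$h / 2, state$h / 2,
                       length.out = n_v + 2)[2:(n_v + 1)]
  top <- state$yc - state$h / 2; bot <- state$yc + state$h / 2
  lef <- state$xc - state$w / 2; rig <- state$xc + state$w / 2
  p <- rbind(cbind(rep(lef, n_v), ys),   # left
             cbind(rep(rig, n_v), ys),   # right
             cbind(xs, rep(top, n_h)),   # upper
             cbind(xs, rep(bot, n_h)))   # lower
  n <- rbind(matrix(c(-1, 0), n_v, 2, byrow = TRUE),
             matrix(c(1, 0), n_v, 2, byrow = TRUE),
             matrix(c(0, -1), n_h, 2, byrow = TRUE),
             matrix(c(0, 1), n_h, 2, byrow = TRUE))
  out <- contour_samples(p, n)
  out$side <- factor(rep(c("l", "r", "u", "b"), c(n_v, n_v, n_h, n_h)),
                     levels = c("l", "r", "u", "b"))
  out$side_counts <- c(l = n_v, r = n_v, u = n_h, b = n_h)
  out
}

#' One rectangle evolution step
#'
#' Each side translates outward by its side-mean force `F_l, F_r, F_u, F_b`
#' (positive = outward).  Equivalently the height evolves as
#' `h <- h + F_u + F_b` (clamped below at `h_min`) and the center as
#' `xc <- xc + (F_r - F_l) / 2`, `yc <- yc + (F_b - F_u) / 2`.  The width is
#' never force-evolved; it is set by [width_schedule()].
#'
#' @param state a [rectangle_state()].
#' @param sides a [sample_rectangle()] result with forces computed.
#' @param h_min height collapse guard in pixels.
#' @return Updated [rectangle_state()].
#' @export
evolve_rectangle_step <- function(state, sides, h_min = 2) {
  stopifnot(inherits(state, "rectangle_state"), !is.null(sides$side))
  f <- sides$forces
  nc <- sides$side_counts
  if (is.null(nc)) {
    Fm <- tapply(f, sides$side, mean)
  } else {
    ends <- cumsum(nc)
    starts <- ends - nc + 1
    Fm <- c(l = mean(f[starts[1]:ends[1]]), r = mean(f[starts[2]:ends[2]]),
            u = mean(f[starts[3]:ends[3]]), b = mean(f[starts[4]:ends[4]]))
  }
  rectangle_state(state$xc + (Fm[["r"]] - Fm[["l"]]) / 2,
                  state$yc + (Fm[["b"]] - Fm[["u"]]) / 2,
                  state$w,
                  max(state$h + Fm[["u"]] + Fm[["b"]], h_min))
}

#' Rectangle width annealing schedule
#'
#' The rectangle starts wide (default 15 px) so that partially missing
#' boundaries cannot capture it, and is narrowed linearly to its final width
#' (default 3 px) over the first `n_anneal` iterations, staying constant
#' afterwards.  Values are real, not rounded.
#'
#' @param iteration 0-based iteration index.
#' @param n_anneal number of annealing iterations.
#' @param w_start,w_end initial and final width in pixels.
#' @return Width in pixels.
#' @export
width_schedule <- function(iteration, n_anneal = 100, w_start = 15,
                           w_end = 3) {
  stopifnot(all(iteration >= 0), n_anneal >= 1)
  pmax(w_start + (w_end - w_start) * pmin(iteration / n_anneal, 1), w_end)
}

.clamp_rect <- function(state, fr, h_min) {
  h <- min(state$h, fr$height - 2)
  w <- min(state$w, fr$width - 2)
  xc <- min(max(state$xc, 1 + w / 2), fr$width - w / 2)
  yc <- min(max(state$yc, 1 + h / 2), fr$height - h / 2)
  rectangle_state(xc, yc, w, max(h, h_min))
}

#' Fit an active rectangle to a frame
#'
#' Runs exactly `rect_iter` iterations (default 200) of width schedule /
#' sampling / region statistics / forces / parameter update -- the rectangle
#' has no stop condition; its fixed budget is small because only three
#' parameters evolve.  Diagnostics record `stable_iter`, the first iteration
#' after which every change in `(xc, yc, h)` stays below
#' `tol * max(1, h)`.  If the height sits at the collapse guard `h_min` for
#' 10 consecutive iterations the target is declared lost.
#'
#' @param fr an [frame()] object.
#' @param init initial [rectangle_state()] (must lie inside the frame).  The
#'   initial width is overridden by the schedule.
#' @param params an [evolution_params()] object.
#' @return List with elements `state` (the fitted [rectangle_state()]) and
#'   `diagnostics` (iterations, stable_iter, converged, lost, deltas,
#'   band_used).
#' @export
fit_rectangle <- function(fr, init, params = evolution_params()) {
  stopifnot(inherits(fr, "ivc_frame"), inherits(init, "rectangle_state"))
  state <- .clamp_rect(init, fr, params$h_min)
  eps_abs <- .contrast_floor(fr, params)
  b_start <- params$band_width
  collapse <- 0L
  deltas <- rep(NA_real_, params$rect_iter)
  thresh <- rep(NA_real_, params$rect_iter)
  diag <- list(iterations = 0L, stable_iter = NA_integer_,
               converged = FALSE, lost = FALSE, deltas = deltas,
               band_used = params$band_width)
  for (i in seq_len(params$rect_iter)) {
    state$w <- width_schedule(i - 1, params$n_anneal, params$w_start,
                              params$w_end)
    sides <- sample_rectangle(state)
    stats <- .rect_stats(fr, state$xc, state$yc, state$w, state$h, params,
                         eps_abs, b_start)
    b_start <- if (i %% 8L == 0L) stats$band_used / 2 else stats$band_used
    sides <- boundary_forces(fr, sides, stats, params)
    new <- evolve_rectangle_step(state, sides, params$h_min)
    new <- .clamp_rect(new, fr, params$h_min)
    deltas[i] <- max(abs(new$xc - state$xc), abs(new$yc - state$yc),
                     abs(new$h - state$h))
    thresh[i] <- params$tol * max(1, state$h)
    diag$iterations <- i
    diag$band_used <- stats$band_used
    state <- new
    collapse <- if (state$h <= params$h_min) collapse + 1L else 0L
    if (collapse >= 10L) {
      diag$lost <- TRUE
      break
    }
  }
  if (!diag$lost && state$h <= params$h_min + 1e-9) diag$lost <- TRUE
  done <- seq_len(diag$iterations)
  viol <- which(deltas[done] >= thresh[done])
  diag$stable_iter <- if (length(viol) == 0) 1L else
    if (max(viol) < diag$iterations) max(viol) + 1L else NA_integer_
  diag$converged <- !is.na(diag$stable_iter) && !diag$lost
  diag$deltas <- deltas[done]
  list(state = state, diagnostics = diag)
}

#' AP-diameter of a fitted rectangle
#'
#' The rectangle models the AP-diameter as its height: `h * spacing`.
#'
#' @param state a [rectangle_state()].
#' @param spacing pixel spacing in cm per pixel (1 gives pixels).
#' @return Length in cm (or pixels if `spacing = 1`).
#' @export
rectangle_ap_diameter <- function(state, spacing) {
  stopifnot(inherits(state, "rectangle_state"))
  state$h * spacing
}
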