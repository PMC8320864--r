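#' Initialize a tracker state from a seed point
#'
#' Implements the semi-automatic protocol: the operator supplies one point
#' inside the vessel on the first frame; everything after that is automatic.
#' The circle starts with radius 5 px at the seed, the ellipse as the
#' equivalent circle of radius 5, and the rectangle 15 px wide and 20 px
#' tall -- all small enough to start inside the lumen and grow outward.
#'
#' @param fr an [frame()] object.
#' @param seed numeric length-2 vector `c(x, y)` inside the frame.
#' @param model one of `"circle"`, `"ellipse"`, `"rectangle"`.
#' @return A [circle_state()], [ellipse_geometry()] or [rectangle_state()].
#' @export
init_state <- function(fr, seed, model = c("rectangle", "circle", "ellipse")) {
  model <- match.arg(model)
  stopifnot(inherits(fr, "ivc_frame"), length(seed) == 2)
  if (seed[1] < 1 || seed[1] > fr$width || seed[2] < 1 || seed[2] > fr$height)
    stop("seed point outside frame bounds")
  switch(model,
         circle = circle_state(seed[1], seed[2], 5),
         ellipse = ellipse_geometry(seed[1], seed[2], 5, 5, 0),
         rectangle = rectangle_state(seed[1], seed[2], 15, 20))
}

.fit_model <- function(model, fr, state, params) {
  switch(model,
         circle = fit_circle(fr, state, params),
         ellipse = fit_ellipse(fr, state, params),
         rectangle = fit_rectangle(fr, state, params))
}

.state_center <- function(model, state) {
  switch(model,
         circle = c(state$xc, state$yc),
         ellipse = c(state$x0, state$y0),
         rectangle = c(state$xc, state$yc))
}

.state_ap_px <- function(model, state) {
  switch(model,
         circle = circle_ap_diameter(state, 1),
         ellipse = ellipse_ap_diameter(state, 1),
         rectangle = rectangle_ap_diameter(state, 1))
}

.state_extras <- function(model, state) {
  switch(model,
         circle = c(r = state$r),
         ellipse = c(semi_major = state$semi_major,
                     semi_minor = state$semi_minor, angle = state$angle),
         rectangle = c(w = state$w, h = state$h))
}

#' Track a vessel through an image sequence
#'
#' Fits the chosen shape model to every frame: the first frame is fitted
#' from the seed-point initialization, each later frame is warm-started from
#' the previous frame's converged state (the rectangle restarts its width
#' annealing on every frame, carrying over center and height).  The whole
#' pipeline is deterministic: identical frames, seed and parameters produce
#' identical results.
#'
#' When a fit reports the target lost, the frame's record is flagged and the
#' tracker re-initializes from the last good center on the next frame.
#'
#' @param frames list of [frame()] objects with constant dimensions.
#' @param seed numeric `c(x, y)` seed point on the first frame.
#' @param model one of `"rectangle"` (default), `"circle"`, `"ellipse"`.
#' @param params an [evolution_params()] object.
#' @return A `track_result`: a data frame with one row per frame and columns
#'   `frame`, `ap_cm`, `ap_px`, `xc`, `yc`, the model parameters (`r` for
#'   the circle; `semi_major`, `semi_minor`, `angle` for the ellipse; `w`,
#'   `h` for the rectangle), `iters`, `converged`, `lost`; the model name is
#'   stored in `attr(, "model")` and the spacing in `attr(, "spacing")`.
#' @export
track_sequence <- function(frames, seed,
                           model = c("rectangle", "circle", "ellipse"),
                           params = evolution_params()) {
  model <- match.arg(model)
  stopifnot(length(frames) >= 1)
  dims <- vapply(frames, function(f) c(f$height, f$width), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frame dimensions differ across the sequence")
  spacing <- frames[[1]]$spacing
  state <- init_state(frames[[1]], seed, model)
  last_good_center <- seed
  need_reinit <- FALSE
  rows <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    fr <- frames[[t]]
    if (need_reinit) state <- init_state(fr, last_good_center, model)
    if (model == "rectangle" && t > 1 && !need_reinit) {
      # warm start: carry center and height, restart the width annealing
      state <- rectangle_state(state$xc, state$yc, params$w_start, state$h)
    }
    fit <- .fit_model(model, fr, state, params)
    st <- fit$state
    dg <- fit$diagnostics
    ctr <- .state_center(model, st)
    ap_px <- .state_ap_px(model, st)
    rows[[t]] <- data.frame(
      frame = t, ap_cm = ap_px * spacing, ap_px = ap_px,
      xc = ctr[1], yc = ctr[2],
      as.list(.state_extras(model, st)),
      iters = dg$iterations, converged = dg$converged, lost = dg$lost)
    if (dg$lost) {
      need_reinit <- TRUE
    } else {
      need_reinit <- FALSE
      last_good_center <- ctr
      state <- st
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "model") <- model
  attr(out, "spacing") <- spacing
  class(out) <- c("track_result", "data.frame")
  out
}

#' Write / read a tracking result as CSV
#'
#' One row per frame with the documented column order (see
#' [track_sequence()]).  Floating-point columns round-trip to better than
#' 1e-9; logical flags are written as 0/1.
#'
#' @param result a `track_result` data frame.
#' @param path output CSV path.
#' @return `export_result` returns `path` invisibly; `read_result` returns a
#'   data frame.
#' @export
export_result <- function(result, path) {
  stopifnot(is.data.frame(result), nrow(result) >= 1)
  out <- result
  out$converged <- as.integer(out$converged)
  out$lost <- as.integer(out$lost)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_result
#' @export
read_result <- function(path) {
  df <- utils::read.csv(path)
  df$converged <- df$converged != 0
  df$lost <- df$lost != 0
  df
}
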