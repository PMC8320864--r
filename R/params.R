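#' Evolution parameters
#'
#' Bundles the tuning parameters shared by the three active-shape trackers.
#'
#' @param alpha force gain applied to the region contrast term (unitless,
#'   > 0).  On \[0, 1\]-normalized intensities the force law is bounded, so
#'   `alpha = 1` gives sub-pixel steps near the boundary.
#' @param K number of contour sample points for circle and ellipse (>= 16).
#'   The default 90 gives 4 degree angular resolution.
#' @param max_iter iteration cap for the circle and ellipse fits.
#' @param rect_iter fixed iteration budget of the rectangle fit; the
#'   rectangle runs exactly this many iterations with no stop condition.
#' @param tol convergence tolerance on parameter change.  The circle stops
#'   when the largest change in (xc, yc, R) drops below `tol * max(1, R)`;
#'   the ellipse when the largest change in the raw conic coefficient vector
#'   drops below `tol`; the rectangle records (but does not act on) the first
#'   iteration after which changes in (xc, yc, h) stay below
#'   `tol * max(1, h)`.
#' @param band_width width in pixels of the outside band over which the
#'   background mean `v` is computed (>= 1).
#' @param force_clip maximum per-point displacement in pixels per iteration;
#'   forces are clipped to `[-force_clip, force_clip]`.
#' @param contrast_eps minimum informative band contrast, as a fraction of
#'   the frame's robust dynamic range (5th-95th intensity percentile).  When
#'   |u - v| falls below this floor during a fit -- typically on a cold
#'   start deep inside a large lumen, where a thin band sees only lumen --
#'   the band width is doubled (up to the frame diagonal) before forces are
#'   evaluated.  Because the force law is quadratic in the contrast, a
#'   barely informative band would generate steps below the convergence
#'   tolerance; the relative floor keeps the rule invariant to the per-frame
#'   renormalization that heavy speckle induces.
#' @param r_min collapse guard for the circle radius (pixels).
#' @param h_min collapse guard for the rectangle height (pixels).
#' @param n_anneal number of iterations over which the rectangle width is
#'   annealed from `w_start` to `w_end`.
#' @param w_start,w_end initial and final rectangle width in pixels.
#' @return An object of class `evolution_params`.
#' @export
evolution_params <- function(alpha = 1, K = 90, max_iter = 5000,
                             rect_iter = 200, tol = 1e-4, band_width = 10,
                             force_clip = 2, contrast_eps = 0.5,
                             r_min = 2, h_min = 2,
                             n_anneal = 100, w_start = 15, w_end = 3) {
  stopifnot(alpha > 0, K >= 16, max_iter >= 1, rect_iter >= 1, tol > 0,
            band_width >= 1, force_clip > 0,
            contrast_eps >= 0, contrast_eps < 1,
            r_min > 0, h_min > 0, n_anneal >= 1, w_start >= w_end, w_end > 0)
  structure(
    list(alpha = alpha, K = as.integer(K), max_iter = as.integer(max_iter),
         rect_iter = as.integer(rect_iter), tol = tol,
         band_width = band_width, force_clip = force_clip,
         contrast_eps = contrast_eps, r_min = r_min, h_min = h_min,
         n_anneal = as.integer(n_anneal), w_start = w_start, w_end = w_end),
    class = "evolution_params")
}

#' @export
print.evolution_params <- function(x, ...) {
  cat("<evolution_params>\n")
  for (nm in names(x)) cat(sprintf("  %-12s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
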