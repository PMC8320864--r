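#' Paired AP-diameter tracks
#'
#' Pairs a reference (expert or ground-truth) AP-diameter series with an
#' estimated one, optionally with the reference AP-line centers and the
#' estimated shape centers, plus a valid-frame mask (lost or otherwise
#' unreliable frames are excluded from every metric).
#'
#' @param ref,est numeric AP-diameter series in cm, equal length.
#' @param ref_centers,est_centers optional n x 2 matrices of centers in cm.
#' @param valid logical mask of frames to include (default: all).
#' @return Object of class `paired_tracks`.
#' @export
paired_tracks <- function(ref, est, ref_centers = NULL, est_centers = NULL,
                          valid = NULL) {
  n <- length(ref)
  stopifnot(length(est) == n)
  if (is.null(valid)) valid <- rep(TRUE, n)
  stopifnot(length(valid) == n)
  if (!is.null(ref_centers))
    stopifnot(is.matrix(ref_centers), nrow(ref_centers) == n,
              ncol(ref_centers) == 2)
  if (!is.null(est_centers))
    stopifnot(is.matrix(est_centers), nrow(est_centers) == n,
              ncol(est_centers) == 2)
  structure(list(ref = ref, est = est, ref_centers = ref_centers,
                 est_centers = est_centers, valid = valid),
            class = "paired_tracks")
}

.valid_errors <- function(tracks) {
  stopifnot(inherits(tracks, "paired_tracks"))
  if (!any(tracks$valid)) stop("no valid frames")
  tracks$est[tracks$valid] - tracks$ref[tracks$valid]
}

#' AP-diameter track metrics
#'
#' Per-frame aggregate metrics between estimated and reference AP-diameter
#' tracks, computed over valid frames only: `rms_error` is the root mean
#' square of the per-frame differences, `max_abs_error` their largest
#' absolute value, `track_correlation` the Pearson product-moment
#' correlation of the two series, and `position_error` the mean Euclidean
#' distance between the estimated shape center and the reference AP-line
#' midpoint.
#'
#' @param tracks a [paired_tracks()] object.
#' @return A scalar: cm for `rms_error`, `max_abs_error` and
#'   `position_error`; unitless in \[-1, 1\] for `track_correlation`.
#' @export
rms_error <- function(tracks) {
  sqrt(mean(.valid_errors(tracks)^2))
}

#' @rdname rms_error
#' @export
max_abs_error <- function(tracks) {
  max(abs(.valid_errors(tracks)))
}

#' @rdname rms_error
#' @export
track_correlation <- function(tracks) {
  stopifnot(inherits(tracks, "paired_tracks"))
  if (sum(tracks$valid) < 2) stop("need at least 2 valid frames")
  r <- tracks$ref[tracks$valid]
  e <- tracks$est[tracks$valid]
  if (stats::sd(r) == 0 || stats::sd(e) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(r, e)
}

#' @rdname rms_error
#' @export
position_error <- function(tracks) {
  stopifnot(inherits(tracks, "paired_tracks"))
  if (is.null(tracks$ref_centers) || is.null(tracks$est_centers))
    stop("centers missing")
  if (!any(tracks$valid)) stop("no valid frames")
  d <- tracks$est_centers[tracks$valid, , drop = FALSE] -
       tracks$ref_centers[tracks$valid, , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Density histogram of the AP-diameter error
#'
#' Density-normalized histogram of the per-frame signed errors (estimated
#' minus reference), the empirical analogue of the error probability
#' distribution function; `sum(density * bin_width)` is 1.  Bins are
#' centered on zero error so an unbiased tracker peaks in the middle bin.
#'
#' @param tracks a [paired_tracks()] object.
#' @param bin_width histogram bin width in cm.
#' @return Data frame with columns `left`, `right`, `mid`, `count`,
#'   `density`.
#' @export
error_distribution <- function(tracks, bin_width = 0.02) {
  err <- .valid_errors(tracks)
  lo <- (round(min(err) / bin_width) - 0.5) * bin_width
  hi <- (round(max(err) / bin_width) + 0.5) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(err, breaks = breaks, plot = FALSE)
  data.frame(left = h$breaks[-length(h$breaks)], right = h$breaks[-1],
             mid = h$mids, count = h$counts, density = h$density)
}

#' Evaluate a tracking result against a reference track
#'
#' Convenience wrapper building [paired_tracks()] from a [track_sequence()]
#' result and a truth table (as written by [generate_clip()], or any table
#' with columns `ap_cm`, `xc`, `yc` in pixels) and computing the full metric
#' panel.  Lost frames are excluded via the valid mask and reported
#' separately.
#'
#' @param est a `track_result` data frame from [track_sequence()].
#' @param ref a reference data frame with columns `ap_cm`, `xc`, `yc`.
#' @param spacing pixel spacing in cm per pixel used to convert centers;
#'   taken from `attr(est, "spacing")` if absent.
#' @return Data frame with columns `metric`, `value`, `unit`.
#' @export
evaluate_tracks <- function(est, ref, spacing = NULL) {
  stopifnot(is.data.frame(est), is.data.frame(ref), nrow(est) == nrow(ref))
  if (is.null(spacing)) spacing <- attr(est, "spacing")
  if (is.null(spacing)) stop("spacing not supplied")
  tr <- paired_tracks(
    ref = ref$ap_cm, est = est$ap_cm,
    ref_centers = cbind(ref$xc, ref$yc) * spacing,
    est_centers = cbind(est$xc, est$yc) * spacing,
    valid = !est$lost)
  data.frame(
    metric = c("rms_error", "max_abs_error", "correlation",
               "position_error", "n_valid", "n_lost"),
    value = c(rms_error(tr), max_abs_error(tr), track_correlation(tr),
              position_error(tr), sum(tr$valid), sum(!tr$valid)),
    unit = c("cm", "cm", "unitless", "cm", "frames", "frames"))
}
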