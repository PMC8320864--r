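# Shared fixtures, built in code.

# a frame containing a filled disk: intensity `fg` inside, `bg` outside,
# hard edge (no smoothing) -- ground truth is the construction itself
disk_frame <- function(n = 64, cx = n / 2, cy = n / 2, r = 20,
                       fg = 1, bg = 0, spacing = 1) {
  xm <- matrix(seq_len(n), n, n, byrow = TRUE)
  ym <- matrix(seq_len(n), n, n)
  px <- ifelse((xm - cx)^2 + (ym - cy)^2 <= r^2, fg, bg)
  frame(px, spacing = spacing)
}

uniform_frame <- function(n = 64, value = 0.5, spacing = 1) {
  frame(matrix(value, n, n), spacing = spacing)
}

# dense polyline of an ellipse, for chord oracles
ellipse_poly <- function(x0, y0, a, b, angle = 0, n = 2000) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x0 + a * cos(t) * cos(angle) - b * sin(t) * sin(angle),
        y0 + a * cos(t) * sin(angle) + b * sin(t) * cos(angle))
}

# independent vertical-chord oracle: scan x positions, solve the conic's
# quadratic in y at each, refine the best by golden-section search
chord_scan_oracle <- function(geom, n_grid = 2001) {
  con <- geometry_to_conic(geom)
  a <- con[["a"]]; b <- con[["b"]]; cc <- con[["c"]]
  d <- con[["d"]]; e <- con[["e"]]
  chord_at <- function(x) {
    disc <- (b * x + e)^2 - 4 * cc * (a * x^2 + d * x - 1)
    sqrt(pmax(disc, 0)) / abs(cc)
  }
  xs <- seq(geom$x0 - geom$semi_major, geom$x0 + geom$semi_major,
            length.out = n_grid)
  x_best <- xs[which.max(chord_at(xs))]
  opt <- stats::optimize(chord_at, lower = x_best - geom$semi_major / 100,
                         upper = x_best + geom$semi_major / 100,
                         maximum = TRUE, tol = 1e-10)
  opt$objective
}

# brute-force numerical minimizer of the conic least-squares cost
# sum((a x^2 + b x y + c y^2 + d x + e y - 1)^2) -- the oracle for the
# closed-form fit; independent of the QR path
conic_cost <- function(A, pts) {
  r <- A[1] * pts[, 1]^2 + A[2] * pts[, 1] * pts[, 2] + A[3] * pts[, 2]^2 +
       A[4] * pts[, 1] + A[5] * pts[, 2] - 1
  sum(r^2)
}

brute_conic_fit <- function(pts) {
  # center/scale only to help the optimizer; cost compared in raw space
  best <- NULL
  for (start in list(c(0.01, 0, 0.01, 0, 0), c(0.001, 0, 0.001, 0.01, 0.01))) {
    o <- stats::optim(start, conic_cost, pts = pts, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best
}

# random valid ellipse geometries for property tests
random_geometry <- function() {
  ellipse_geometry(stats::runif(1, 30, 90), stats::runif(1, 30, 90),
                   semi_major = stats::runif(1, 10, 30),
                   semi_minor = stats::runif(1, 5, 10),
                   angle = stats::runif(1, -pi / 2 + 0.01, pi / 2))
}
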