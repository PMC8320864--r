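test_that("phantom config validates its invariants", {
  expect_error(phantom_config(lumen = 0.5, background = 0.5), "differ")
  expect_error(phantom_config(amplitude = 0.95))
  expect_error(phantom_config(n_frames = 0))
  expect_error(phantom_config(semi_axes = c(60, 60)), "exceeds frame")
})

test_that("collapse modulation scales the vertical chord as designed", {
  base <- phantom_config(amplitude = 0, n_frames = 3, sigma = 0)
  f1 <- make_clean_frame(base, 1)
  f3 <- make_clean_frame(base, 3)
  expect_identical(f1$frame$pixels, f3$frame$pixels)  # amplitude 0: static

  # phase pi/2 puts the sine at its maximum on frame 1:
  # vertical chord = (1 - amplitude) x baseline
  mod <- phantom_config(amplitude = 0.5, phase = pi / 2, n_frames = 1,
                        sigma = 0)
  fm <- make_clean_frame(mod, 1)
  expect_equal(fm$truth$ap_px, 0.5 * f1$truth$ap_px, tolerance = 1e-9)

  # unrotated ellipse: truth AP is twice the scaled vertical semi-axis
  cfg <- phantom_config(family = "ellipse", semi_axes = c(28, 25),
                        rotation = 0, amplitude = 0.4, n_frames = 10,
                        sigma = 0)
  for (t in c(1, 4, 10)) {
    m <- 1 - 0.4 * (1 + sin(2 * pi * (t - 1) / cfg$period)) / 2
    expect_equal(make_clean_frame(cfg, t)$truth$ap_px, 2 * 25 * m,
                 tolerance = 1e-9)
  }
})

test_that("recorded AP equals the contour's maximal vertical chord", {
  # chord-scan oracle: at integer-ish columns, intersect the polyline
  # with a vertical line; independent of the package's chord search
  scan_chord <- function(poly) {
    xs <- seq(min(poly[, 1]) + 0.01, max(poly[, 1]) - 0.01, by = 0.25)
    best <- 0
    for (x in xs) {
      x1 <- poly[, 1]; y1 <- poly[, 2]
      x2 <- poly[c(2:nrow(poly), 1), 1]; y2 <- poly[c(2:nrow(poly), 1), 2]
      hit <- (x1 - x) * (x2 - x) <= 0 & x1 != x2
      if (sum(hit) < 2) next
      tt <- (x - x1[hit]) / (x2[hit] - x1[hit])
      ys <- y1[hit] + tt * (y2[hit] - y1[hit])
      best <- max(best, max(ys) - min(ys))
    }
    best
  }
  for (fam in c("ellipse", "blob")) {
    cfg <- phantom_config(family = fam, rotation = 0.3, amplitude = 0.4,
                          n_frames = 8, sigma = 0, rng_seed = 17)
    for (t in c(1, 5, 8)) {
      cf <- make_clean_frame(cfg, t)
      expect_lt(abs(cf$truth$ap_px - scan_chord(cf$contour)), 0.1)
    }
  }
})

test_that("speckle field is unit-mean Rayleigh", {
  r <- speckle_field(c(1000, 1000), rng_seed = 123)
  expect_lt(abs(mean(r) - 1), 0.01)              # Monte-Carlo mean check
  # KS against the scale-free normalized Rayleigh CDF 1 - exp(-pi t^2 / 4)
  sub <- as.vector(r)[1:100000]
  ks <- suppressWarnings(
    stats::ks.test(sub, function(t) 1 - exp(-pi * t^2 / 4)))
  expect_gt(ks$p.value, 0.01)
  # reproducibility: same seed, bit-identical field
  expect_identical(r, speckle_field(c(1000, 1000), rng_seed = 123))
})

test_that("speckle severity: identity limit and monotone difficulty", {
  cfg <- phantom_config(sigma = 0, n_frames = 1, amplitude = 0)
  fr <- make_clean_frame(cfg, 1)$frame
  tiny <- apply_speckle(fr, sigma = 1e-6, rng_seed = 1)
  # sigma -> 0: output equals the input up to the contrast renormalization
  expect_lt(max(abs(tiny$pixels - ivctrack:::.stretch01(fr$pixels))), 1e-4)

  # noise-induced tracking difficulty is non-decreasing in sigma: measured
  # as the dispersion of the AP error about its mean (pooled over 10 seeds).
  # The tracker's small systematic bias (which speckle slightly dithers
  # away) would otherwise mask the noise contribution in raw RMS.
  disp_at <- function(sig) {
    errs <- unlist(lapply(1:10, function(s) {
      cfg <- phantom_config(sigma = sig, n_frames = 3, rotation = pi / 9,
                            rng_seed = 700 + s)
      g <- generate_frames(cfg)
      r <- track_sequence(g$frames, c(g$truth$xc[1], g$truth$yc[1]),
                          "rectangle", evolution_params())
      r$ap_cm - g$truth$ap_cm
    }))
    stats::sd(errs)
  }
  d1 <- disp_at(0.1); d3 <- disp_at(0.3); d6 <- disp_at(0.6)
  expect_lte(d1, d3)
  expect_lte(d3, d6)
})

test_that("artifacts: identity, shadow attenuation, dropout erases the rim", {
  cfg <- phantom_config(sigma = 0, n_frames = 1, amplitude = 0)
  fr <- make_clean_frame(cfg, 1)$frame
  expect_identical(apply_artifacts(fr)$pixels, fr$pixels)

  sh <- apply_artifacts(fr, shadow = list(x0 = 1, x1 = 40, y0 = 1, y1 = 128,
                                          attenuation = 0.5))
  expect_equal(sh$pixels[, 1:40], fr$pixels[, 1:40] * 0.5)
  expect_equal(sh$pixels[, 41:128], fr$pixels[, 41:128])

  # dropout at the top: edge contrast across the boundary inside the arc
  # drops below 10% of the contrast elsewhere
  dr <- apply_artifacts(fr, dropout = list(angle_deg = -90, span_deg = 60,
                                           depth_px = 4),
                        config = cfg, frame_index = 1)
  n <- 128
  xm <- matrix(seq_len(n), n, n, byrow = TRUE)
  ym <- matrix(seq_len(n), n, n)
  shp <- ivctrack:::.phantom_shape(cfg)
  d <- ivctrack:::.signed_dist(xm, ym, 64, 64, 1, shp$rfun)
  phi <- atan2(ym - 64, xm - 64)
  in_arc <- abs((phi + pi / 2 + pi) %% (2 * pi) - pi) < 15 * pi / 180
  edge_contrast <- function(img, sel) {
    abs(mean(img[sel & d > 0 & d <= 2]) - mean(img[sel & d < 0 & d >= -2]))
  }
  c_in <- edge_contrast(dr$pixels, in_arc)
  c_out <- edge_contrast(dr$pixels, !in_arc)
  expect_lt(c_in, 0.1 * c_out)
})

test_that("generate_clip writes frames plus aligned truth, reproducibly", {
  cfg <- phantom_config(n_frames = 4, rng_seed = 42)
  d1 <- file.path(tempdir(), "clip_a")
  d2 <- file.path(tempdir(), "clip_b")
  out1 <- generate_clip(cfg, d1)
  out2 <- generate_clip(cfg, d2)
  expect_length(out1$files, 4)
  expect_equal(nrow(out1$truth), 4)
  # reruns with the same seed are byte-identical
  for (i in 1:4)
    expect_identical(readBin(out1$files[i], "raw", 1e6),
                     readBin(out2$files[i], "raw", 1e6))
  expect_identical(readLines(file.path(d1, "truth.csv")),
                   readLines(file.path(d2, "truth.csv")))
  # frames round-trip through the reader
  frames <- read_frames(d1, spacing = cfg$spacing)
  expect_length(frames, 4)
  expect_equal(frames[[1]]$height, 128)
  unlink(c(d1, d2), recursive = TRUE)
})
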