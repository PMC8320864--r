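test_that("conic fit recovers canonical conics exactly", {
  t <- 2 * pi * (0:7) / 8
  circ <- cbind(cos(t), sin(t))
  A <- fit_conic_lsq(circ)
  expect_equal(unclass(A), c(a = 1, b = 0, c = 1, d = 0, e = 0),
               tolerance = 1e-9)

  ell <- cbind(2 * cos(t), sin(t))           # x^2/4 + y^2 = 1
  A2 <- fit_conic_lsq(ell)
  expect_equal(unclass(A2), c(a = 0.25, b = 0, c = 1, d = 0, e = 0),
               tolerance = 1e-9)

  expect_error(fit_conic_lsq(circ[1:4, ]), "at least 5")
  line <- cbind(1:8, 2 * (1:8) + 1)
  expect_error(fit_conic_lsq(line), "rank-deficient|degenerate")
})

test_that("conic fit equals a brute-force minimizer on noisy points", {
  withr::with_seed(99, {
    g <- ellipse_geometry(50, 60, 20, 9, angle = 0.5)
    pts <- ellipse_poly(g$x0, g$y0, g$semi_major, g$semi_minor, g$angle,
                        n = 12)
    pts <- pts + matrix(rnorm(24, 0, 0.3), 12, 2)
    A <- fit_conic_lsq(pts)
    o <- brute_conic_fit(pts)
    expect_lt(conic_cost(unclass(A), pts), o$value * (1 + 1e-6) + 1e-12)
  })
})

test_that("points exactly on an ellipse refit with near-zero residual", {
  withr::with_seed(5, {
    for (i in 1:10) {
      g <- random_geometry()
      pts <- ellipse_poly(g$x0, g$y0, g$semi_major, g$semi_minor, g$angle,
                          n = 24)
      A <- fit_conic_lsq(pts)
      expect_lt(conic_cost(unclass(A), pts), 1e-16)
    }
  })
})

test_that("conic/geometry conversions invert each other", {
  g0 <- conic_to_geometry(conic_vector(1, 0, 1, 0, 0))
  expect_equal(c(g0$x0, g0$y0), c(0, 0))
  expect_equal(c(g0$semi_major, g0$semi_minor), c(1, 1))
  expect_equal(g0$angle, 0)                   # circle: angle reported as 0

  g1 <- conic_to_geometry(conic_vector(0.25, 0, 1, 0, 0))
  expect_equal(g1$semi_major, 2)
  expect_equal(g1$semi_minor, 1)
  expect_equal(g1$angle, 0)                   # major axis along x

  withr::with_seed(21, {
    for (i in 1:20) {
      g <- random_geometry()
      g2 <- conic_to_geometry(geometry_to_conic(g))
      expect_equal(g2$x0, g$x0, tolerance = 1e-9)
      expect_equal(g2$y0, g$y0, tolerance = 1e-9)
      expect_equal(g2$semi_major, g$semi_major, tolerance = 1e-9)
      expect_equal(g2$semi_minor, g$semi_minor, tolerance = 1e-9)
      expect_equal(g2$angle, g$angle, tolerance = 1e-9)
    }
  })

  expect_error(conic_to_geometry(conic_vector(1, 0, -1, 0, 0)),
               "non-elliptical")
})

test_that("ellipse sampling matches circle sampling and has unit normals", {
  gc <- ellipse_geometry(10, 20, 5, 5, 0)
  sc <- sample_circle(circle_state(10, 20, 5), 36)
  se <- sample_ellipse(gc, 36)
  expect_equal(se$points, sc$points, tolerance = 1e-12)
  expect_equal(se$normals, sc$normals, tolerance = 1e-12)

  g <- ellipse_geometry(40, 50, 12, 7, 0)
  s <- sample_ellipse(g, 16)
  expect_equal(s$points[1, ], c(52, 50))      # parametric angle 0
  expect_equal(s$normals[1, ], c(1, 0))
  expect_equal(sqrt(rowSums(s$normals^2)), rep(1, 16), tolerance = 1e-12)
  # outward orientation: positive projection on the center-to-point vector
  rel <- sweep(s$points, 2, c(g$x0, g$y0))
  expect_true(all(rowSums(rel * s$normals) > 0))
})

test_that("evolve_points moves each point by its force along the normal", {
  s <- contour_samples(cbind(c(3, 10), c(4, 10)),
                       cbind(c(0.6, 1), c(0.8, 0)),
                       forces = c(1, -0.5))
  p <- evolve_points(s)
  expect_equal(p[1, ], c(3.6, 4.8))
  expect_equal(p[2, ], c(9.5, 10))
  s$forces <- c(0, 0)
  expect_equal(evolve_points(s), s$points)
})

test_that("max vertical chord of an ellipse: closed form vs oracles", {
  # axis-aligned: vertical semi-axis 1
  expect_equal(ellipse_ap_diameter(ellipse_geometry(0, 0, 2, 1, 0), 1), 2)
  # rotated 90 deg: the semi-major axis is vertical
  expect_equal(
    ellipse_ap_diameter(ellipse_geometry(0, 0, 2, 1, pi / 2), 1), 4)
  # 45 deg: against the grid-scan + golden-section oracle
  g45 <- ellipse_geometry(40, 40, 2, 1, pi / 4)
  expect_equal(ellipse_ap_diameter(g45, 1), chord_scan_oracle(g45),
               tolerance = 1e-6)
  # spacing scales linearly
  expect_equal(ellipse_ap_diameter(g45, 0.04),
               0.04 * ellipse_ap_diameter(g45, 1))
})

test_that("AP-diameter is translation invariant and scale equivariant", {
  withr::with_seed(31, {
    for (i in 1:10) {
      g <- random_geometry()
      ap <- ellipse_ap_diameter(g, 1)
      g_shift <- ellipse_geometry(g$x0 + 17.3, g$y0, g$semi_major,
                                  g$semi_minor, g$angle)
      expect_equal(ellipse_ap_diameter(g_shift, 1), ap, tolerance = 1e-12)
      k <- runif(1, 0.5, 2)
      g_scaled <- ellipse_geometry(g$x0, g$y0, k * g$semi_major,
                                   k * g$semi_minor, g$angle)
      expect_equal(ellipse_ap_diameter(g_scaled, 1), k * ap,
                   tolerance = 1e-9)
      # rotation -> 0 limit: twice the vertical semi-axis
      g0 <- ellipse_geometry(g$x0, g$y0, g$semi_major, g$semi_minor, 0)
      expect_equal(ellipse_ap_diameter(g0, 1), 2 * g$semi_minor,
                   tolerance = 1e-12)
    }
  })
})

test_that("active ellipse recovers a noise-free rotated ellipse phantom", {
  cfg <- phantom_config(family = "ellipse", semi_axes = c(25, 12),
                        rotation = 20 * pi / 180, sigma = 0, amplitude = 0,
                        n_frames = 1, image_size = 96,
                        center = c(48, 48), rim_amp = 0)
  cf <- make_clean_frame(cfg, 1)
  fit <- fit_ellipse(cf$frame, init_state(cf$frame, c(48, 48), "ellipse"),
                     evolution_params())
  expect_true(fit$diagnostics$converged)
  expect_lt(abs(fit$state$semi_major - 25), 1)
  expect_lt(abs(fit$state$semi_minor - 12), 1)
  expect_lt(sqrt((fit$state$x0 - 48)^2 + (fit$state$y0 - 48)^2), 1)
})

test_that("on a circular phantom the fitted axis ratio is near 1", {
  cfg <- phantom_config(family = "circle", semi_axes = c(20, 20),
                        sigma = 0, amplitude = 0, n_frames = 1,
                        image_size = 96, center = c(48, 48))
  cf <- make_clean_frame(cfg, 1)
  fit <- fit_ellipse(cf$frame, init_state(cf$frame, c(48, 48), "ellipse"),
                     evolution_params())
  expect_true(fit$diagnostics$converged)
  expect_lt(fit$state$semi_major / fit$state$semi_minor, 1.05)
})

test_that("uniform image leaves the ellipse unchanged", {
  fr <- uniform_frame(64, 0.5)
  init <- ellipse_geometry(32, 32, 8, 6, 0.3)
  fit <- fit_ellipse(fr, init, evolution_params())
  expect_true(fit$diagnostics$converged)
  expect_lte(fit$diagnostics$iterations, 2)
  expect_equal(fit$state$semi_major, 8)
  expect_equal(fit$state$x0, 32)
})

test_that("speckled ellipse phantoms: AP error within 2 px in >=90% of trials", {
  ok <- 0
  n_trials <- 50
  for (i in seq_len(n_trials)) {
    cfg <- phantom_config(family = "ellipse", semi_axes = c(25, 16),
                          rotation = 15 * pi / 180, sigma = 0.3,
                          amplitude = 0, n_frames = 1, rng_seed = 4000 + i)
    g <- generate_frames(cfg)
    fit <- fit_ellipse(g$frames[[1]],
                       init_state(g$frames[[1]], c(64, 64), "ellipse"),
                       evolution_params())
    err <- abs(ellipse_ap_diameter(fit$state, 1) - g$truth$ap_px[1])
    if (!fit$diagnostics$lost && err <= 2) ok <- ok + 1
  }
  expect_gte(ok, 0.9 * n_trials)
})
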