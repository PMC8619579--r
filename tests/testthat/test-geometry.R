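# Plane fitting, inter-plane angles, projections and direct ellipse fits.

make_ellipse_points <- function(a = 2, b = 1, n = 200, rot3 = NULL,
                                orientation = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-1L]
  P2 <- cbind(a * cos(t), b * sin(t))
  if (orientation != 0) {
    R <- matrix(c(cos(orientation), sin(orientation),
                  -sin(orientation), cos(orientation)), 2L, 2L)
    P2 <- P2 %*% t(R)
  }
  P <- cbind(P2, 0)
  if (!is.null(rot3)) P <- P %*% t(rot3)
  P
}

rot_x <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3L, 3L,
         byrow = TRUE)
}

test_that("plane fits recover exact and rotated planes", {
  P <- make_ellipse_points()
  pl <- fit_plane(P)
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-10)
  expect_equal(pl$residual_frac, 0, tolerance = 1e-12)
  expect_equal(sum(pl$p1 * pl$p2), 0, tolerance = 1e-10)
  expect_equal(sqrt(sum(pl$p1^2)), 1, tolerance = 1e-12)

  P30 <- make_ellipse_points(rot3 = rot_x(30))
  pl30 <- fit_plane(P30)
  truth <- rot_x(30)[, 3L]
  ang <- acos(min(1, abs(sum(pl30$normal * truth)))) * 180 / pi
  expect_lt(ang, 0.5)

  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_plane(line), "collinear")
})

test_that("plane angles follow hand geometry and are symmetric", {
  pl_z <- fit_plane(make_ellipse_points())
  pl_30 <- fit_plane(make_ellipse_points(rot3 = rot_x(30)))
  expect_equal(plane_angle(pl_z, pl_z), 0)
  expect_equal(plane_angle(pl_z, pl_30), 30, tolerance = 1e-6)
  expect_equal(plane_angle(pl_30, pl_z), plane_angle(pl_z, pl_30))
  # z = 0 against x = 0
  P_x <- make_ellipse_points()[, c(3, 1, 2)]
  pl_x <- fit_plane(P_x)
  expect_equal(plane_angle(pl_z, pl_x), 90, tolerance = 1e-8)
  expect_gte(plane_angle(pl_z, pl_30), 0)
  expect_lte(plane_angle(pl_z, pl_30), 90)
})

test_that("angle-frequency regression recovers linear structure", {
  freqs <- c(0, 50, 100, 150)
  reg <- angle_frequency_regression(0.3 * freqs, freqs)
  expect_equal(reg$slope, 0.3, tolerance = 1e-12)
  expect_equal(reg$r_squared, 1)

  set.seed(31)
  noisy <- 0.3 * freqs + rnorm(4, sd = 0.5)
  regn <- angle_frequency_regression(rep(noisy, 5), rep(freqs, 5))
  expect_lt(abs(regn$slope - 0.3) / 0.3, 0.1)

  # angles unrelated to frequency: R^2 stays near zero for large n
  low <- replicate(40, {
    f <- rep(c(0, 50, 100, 150), each = 25)
    a <- rnorm(length(f), mean = 20, sd = 5)
    angle_frequency_regression(a, f)$r_squared
  })
  expect_gt(mean(low < 0.2), 0.95)

  expect_error(angle_frequency_regression(c(1, 2), c(0, 50)), "distinct")
})

test_that("projection into plane coordinates is exact and idempotent", {
  P30 <- make_ellipse_points(a = 3, b = 1.5, rot3 = rot_x(30))
  pl <- fit_plane(P30)
  xy <- project_to_plane(P30, pl)
  # reconstruction from 2-D coordinates returns the in-plane points exactly
  back <- sweep(xy %*% rbind(pl$p1, pl$p2), 2L, -pl$centroid)
  expect_equal(back, P30, tolerance = 1e-10, ignore_attr = TRUE)
  centroid_only <- matrix(pl$centroid, 1L)
  expect_equal(as.numeric(project_to_plane(centroid_only, pl)), c(0, 0),
               tolerance = 1e-12)
  # projecting the reconstruction reproduces the same coordinates
  expect_equal(project_to_plane(back, pl), xy, tolerance = 1e-10)
})

test_that("direct least-squares ellipse fits are exact on noiseless conics", {
  P <- make_ellipse_points(a = 2, b = 1)[, 1:2]
  fit <- fit_ellipse(P)
  expect_equal(fit$long_axis, 2, tolerance = 1e-6)
  expect_equal(fit$short_axis, 1, tolerance = 1e-6)
  expect_equal(fit$center, c(0, 0), tolerance = 1e-8)
  expect_lt(fit$fit_residual, 1e-10)

  circ <- fit_ellipse(make_ellipse_points(a = 1, b = 1)[, 1:2])
  expect_equal(circ$long_axis, 1, tolerance = 1e-6)
  expect_equal(circ$short_axis, 1, tolerance = 1e-6)

  expect_error(fit_ellipse(cbind(1:10, 2 * (1:10))), "collinear")
  expect_error(fit_ellipse(P[1:4, ]), "6 points")
})

test_that("ellipse fits are rotation equivariant", {
  base <- make_ellipse_points(a = 2.5, b = 0.8)[, 1:2]
  f0 <- fit_ellipse(base)
  for (th in c(0.3, 1.1, 2.0)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
    fr <- fit_ellipse(base %*% t(R))
    expect_equal(fr$long_axis, f0$long_axis, tolerance = 1e-8)
    expect_equal(fr$short_axis, f0$short_axis, tolerance = 1e-8)
    d <- (fr$orientation - th - f0$orientation) %% pi
    expect_lt(min(d, pi - d), 1e-6)
  }
  expect_gte(f0$orientation, 0)
  expect_lt(f0$orientation, pi)
})

test_that("attractor statistics summarize per-condition axes", {
  same <- data.frame(condition = rep("a", 3L), long_axis = 2, short_axis = 1)
  s <- attractor_stats(same)
  expect_equal(s$var_a, 0)
  expect_equal(s$mean_a, 2)

  feats <- acceptance_features()
  stats <- attractor_stats(feats)
  ord <- match(c("acu_50", "acu_100", "acu_150"), stats$condition)
  expect_true(all(diff(stats$mean_a[ord]) > 0))

  single <- data.frame(condition = c("a", "a", "b"),
                       long_axis = c(1, 2, 3), short_axis = c(1, 1, 1))
  expect_error(attractor_stats(single), "at least 2")
})
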