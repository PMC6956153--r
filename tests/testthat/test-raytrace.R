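make_sphere_surface <- function(R = 8.5, a = 4, order = 8) {
  r <- rep(seq(0, a, length.out = 50), each = 36)
  phi <- rep(seq(0, 2 * pi, length.out = 37)[1:36], times = 50)
  nodes <- tibble::tibble(x = r * cos(phi), y = r * sin(phi))
  nodes$z <- -(R - sqrt(R^2 - nodes$x^2 - nodes$y^2))
  fit_surface(nodes, a, order)
}

test_that("Snell's law reproduces textbook angles and flags TIR", {
  expect_equal(snell(0, 1, 1.5), 0)
  expect_equal(snell(pi / 6, 1, 1.5), asin(0.5 / 1.5))
  expect_equal(snell(pi / 6, 1, 1.5) * 180 / pi, 19.4712, tolerance = 1e-4)
  expect_equal(snell(0.3, 1.4, 1.4), 0.3)
  expect_error(snell(1.2, 1.5, 1), class = "onlens_tir")
})

test_that("incidence angle folds to [0, pi/2] and ignores the normal's sign", {
  d <- c(0, 0, -1)
  expect_equal(incidence_angle(d, c(0, 0, 1)), 0)
  expect_equal(incidence_angle(d, c(0, 0, -1)), 0)
  n30 <- c(sin(pi / 6), 0, -cos(pi / 6))
  expect_equal(incidence_angle(d, n30), pi / 6)
  expect_equal(incidence_angle(d, -n30), pi / 6)
})

test_that("meridian rotation zeroes the normal's y component and is orthonormal", {
  n <- c(0, 1, -0.4)
  mr <- meridian_rotation(n)
  expect_equal(mr$theta, pi / 2)
  rotated <- as.numeric(mr$rotation %*% n)
  expect_lt(abs(rotated[2]), 1e-14)
  # inverse recovers the input
  back <- as.numeric(t(mr$rotation) %*% rotated)
  expect_lt(max(abs(back - n)), 1e-14)
  expect_equal(mr$rotation %*% t(mr$rotation), diag(3), tolerance = 1e-14)
})

test_that("refraction matches the closed-form vector Snell law on a sphere", {
  surf <- make_sphere_surface()
  set.seed(42)
  for (i in 1:25) {
    x0 <- runif(1, -2, 2); y0 <- runif(1, -2, 2)
    ray <- list(origin = c(x0, y0, 3), direction = c(0, 0, -1))
    out <- refract_ray(ray, surf, 1, 1.45)
    d_oracle <- oracle_vector_snell(
      c(0, 0, -1), out$normal, 1, 1.45
    )
    expect_lt(max(abs(out$direction - d_oracle)), 1e-10)
    # Snell identity at the event
    expect_lt(abs(sin(out$phi_in) - 1.45 * sin(out$phi_out)), 1e-12)
    expect_equal(sqrt(sum(out$direction^2)), 1, tolerance = 1e-12)
  }
})

test_that("normal incidence leaves the direction unchanged", {
  surf <- make_sphere_surface()
  ray <- list(origin = c(0, 0, 3), direction = c(0, 0, -1))
  out <- refract_ray(ray, surf, 1, 1.5)
  expect_equal(out$direction, c(0, 0, -1), tolerance = 1e-12)
  expect_equal(out$origin[3], 0, tolerance = 1e-5) # apex height of the fitted sphere
})

test_that("meridional rays stay in their meridian plane on a symmetric surface", {
  surf <- make_sphere_surface()
  for (az in c(0, 45, 120)) {
    d0 <- c(0, 0, -1)
    p0 <- c(2 * cos(az * pi / 180), 2 * sin(az * pi / 180), 3)
    out <- refract_ray(list(origin = p0, direction = d0), surf, 1, 1.4)
    # direction remains in the plane spanned by the meridian and z
    cross_z <- out$direction[1] * sin(az * pi / 180) - out$direction[2] * cos(az * pi / 180)
    expect_lt(abs(cross_z), 1e-9)
  }
})

test_that("a plano lens traces to near-zero power and a +5 D lens to its oracle", {
  g0 <- build_lens(tiny_spec(sph = 0, n_meridians = 90, n_radial = 101))
  tr0 <- trace_lens(g0, pupil_semi_aperture = 1)
  expect_lt(abs(tr0$power_D), 0.05)
  g5 <- build_lens(tiny_spec(sph = 5, n_meridians = 90, n_radial = 101))
  tr5 <- trace_lens(g5, pupil_semi_aperture = 1)
  expect_equal(tr5$power_D, lens_paraxial_power(g5)[1], tolerance = 0.05)
  expect_equal(tr5$power_D, 5, tolerance = 0.06)
  expect_equal(tr5$n_dropped, 0)
})

test_that("axis-crossing spread scales as the pupil squared (spherical aberration)", {
  g <- build_lens(tiny_spec(sph = 8, n_meridians = 90, n_radial = 101))
  s1 <- trace_lens(g, pupil_semi_aperture = 0.75)$spread_mm
  s2 <- trace_lens(g, pupil_semi_aperture = 1.5)$spread_mm
  expect_equal(s2 / s1, 4, tolerance = 0.35)
})

test_that("Snell identity and unit norms hold at every recorded event", {
  g <- build_lens(tiny_spec(sph = 6, n_meridians = 90, n_radial = 101))
  tr <- trace_lens(g, keep_events = TRUE)
  for (ev in tr$events) {
    id <- ev$n_in * sin(ev$phi_in) - ev$n_out * sin(ev$phi_out)
    expect_lt(max(abs(id)), 1e-12)
    expect_lt(max(abs(sqrt(rowSums(ev$d_out^2)) - 1)), 1e-12)
    expect_lt(max(abs(sqrt(rowSums(ev$normal^2)) - 1)), 1e-12)
  }
})

test_that("toric fan powers bracket the mean and recover both principal powers", {
  g <- build_lens(tiny_spec(sph = 0, cyl = 6, n_meridians = 180, n_radial = 101))
  tr <- trace_lens(g, toric_fans = TRUE)
  p1 <- tr$fans[[1]]$power_D # along the 90-degree axis: the steep meridian
  p2 <- tr$fans[[2]]$power_D
  expect_gt(p1, p2)
  expect_gte(max(p1, p2), tr$power_D)
  expect_lte(min(p1, p2), tr$power_D)
  pp <- lens_paraxial_power(g)
  expect_equal(p1, max(pp), tolerance = 0.1)
  expect_equal(p2, min(pp), tolerance = 0.1)
})

test_that("power and EPC bookkeeping converts focal lengths and differences", {
  tr <- list(power_D = 5, focal_mm = 200, spread_mm = 0.1, n_rays = 127, n_dropped = 0)
  out <- power_and_epc(tr, 5)
  expect_equal(out$epc_D, 0)
  out2 <- power_and_epc(tr, list(power_D = 5.5))
  expect_equal(out2$epc_D, -0.5)
  expect_equal(1000 / tr$focal_mm, 5)
})

test_that("trace diagnostics dump to CSV", {
  g <- build_lens(tiny_spec(sph = 2, n_meridians = 48, n_radial = 61))
  tr <- trace_lens(g)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(back), tr$n_rays)
  expect_true(all(c("x0", "y0", "crossing_z", "dropped") %in% names(back)))
})
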