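test_that("zone radii follow the base curve with +2/-2 mm offsets", {
  expect_equal(unname(zone_radii(8.5)), c(8.5, 10.5, 6.5))
  expect_equal(unname(zone_radii(9.0)), c(9.0, 11.0, 7.0))
  expect_error(zone_radii(2.0), class = "onlens_geometry_error")
})

test_that("zone centres make the tri-curve sag continuous at both joins", {
  radii <- zone_radii(8.5)
  centres <- zone_centres(radii, d1 = 8, d2 = 11.25)
  expect_equal(unname(centres["zc1"]), -8.5)
  b <- back_surface(lens_spec())
  for (xj in c(b$d1 / 2, b$d2 / 2)) {
    lo <- back_sag(xj - 1e-9, b)
    hi <- back_sag(xj + 1e-9, b)
    expect_lt(abs(hi - lo), 1e-8) # continuity at the zone joins
  }
  expect_error(
    zone_centres(zone_radii(3), d1 = 8, d2 = 11),
    class = "onlens_geometry_error"
  )
})

test_that("back sag matches the closed-form optic-zone sphere and is monotone", {
  b <- back_surface(lens_spec())
  expect_equal(back_sag(0, b), 0)
  expect_equal(back_sag(4, b), -8.5 + sqrt(8.5^2 - 16)) # = -1 exactly
  expect_equal(back_sag(4, b), -1)
  X <- seq(0, 7, length.out = 200)
  expect_true(all(diff(back_sag(X, b)) < 0))
  expect_error(back_sag(7.5, b), class = "onlens_out_of_range")
})

test_that("the power profile is the 180-degree-period cosine with maxima on the axis", {
  # plano-cyl: constant profile
  p0 <- power_profile(-3, 0)
  expect_true(all(p0$power_D == -3))
  p <- power_profile(-3, -1, cyl_axis = 90)
  expect_equal(attr(p, "pmax"), -3)
  expect_equal(attr(p, "pmin"), -4)
  expect_equal(attr(p, "pmean"), -3.5)
  expect_equal(attr(p, "pamp"), 0.5)
  argmax <- p$meridian_deg[p$power_D == max(p$power_D)]
  expect_setequal(argmax, c(90, 270))
  # period 180 degrees
  expect_equal(p$power_D[1:180], p$power_D[181:360], tolerance = 1e-12)
  # non-grid axis goes through the periodic cubic path and keeps the range
  pq <- power_profile(0, 5, cyl_axis = 37.3)
  expect_equal(max(pq$power_D), 5, tolerance = 1e-3)
  expect_equal(min(pq$power_D), 0, tolerance = 1e-3)
})

test_that("the front radius inverts the thick-lens power relation", {
  # zero power: Rf = Rb + Tc (n-1)/n, independent of unit conversions
  rf0 <- front_radius(0, 1.3920, 0.25, 8.5)
  expect_equal(rf0, 8.5 + 0.25 * (1.3920 - 1) / 1.3920, tolerance = 1e-12)
  # independent thick-lens oracle across the sweep range
  for (P in seq(-10, 20, by = 2.5)) {
    rf <- front_radius(P, 1.3739, 0.25, 8.5)
    expect_equal(paraxial_power(rf, 8.5, 0.25, 1.3739), P, tolerance = 0.02)
  }
  # continuity/monotonicity of Rf in power
  rf <- front_radius(seq(-10, 20, 0.5), 1.3739, 0.25, 8.5)
  expect_true(all(diff(rf) < 0))
  expect_error(
    front_radius(-1 / (8.5e-3) * (1.3739 - 1) / 1, 1.3739, 0.25, 8.5),
    class = "onlens_singular_power"
  )
})

test_that("front sag reduces to the spherical form and matches hand evaluation", {
  expect_equal(front_sag(0, 8.57, 0.25, 0.75), 0.25)
  X <- seq(0, 3, length.out = 10)
  expect_equal(
    front_sag(X, 8.57, 0.25, 1),
    0.25 - (8.57 - sqrt(8.57^2 - X^2)),
    tolerance = 1e-14
  )
  rf <- 8.5704
  hand <- 0.25 - (1 / 0.75) * (rf - sqrt(rf^2 - 0.75 * 9))
  expect_equal(front_sag(3, rf, 0.25, 0.75), hand, tolerance = 1e-12)
  expect_error(front_sag(9, 8.57, 0.25, 1), class = "onlens_aperture_error")
})

test_that("ballast thickens the lower half with the stated weighting profile", {
  tc <- 0.25
  expect_equal(ballast_profile(0, tc), tc)
  expect_equal(ballast_profile(pi / 2, tc), 0.8 * tc)
  expect_equal(ballast_profile(3 * pi / 2, tc), 2 * tc)
  g <- build_lens(tiny_spec(sph = 2, ballast = TRUE))
  k_edge <- length(g$X)
  j_up <- which(g$meridian_deg == 90)
  j_down <- which(g$meridian_deg == 270)
  expect_gt(g$thickness[j_down, k_edge], g$thickness[j_up, k_edge])
  # apex stays single-valued: no meridian dependence at X = 0
  expect_lt(diff(range(g$Zf[, 1])), 1e-12)
})

test_that("minimum-thickness enforcement inflates Tc in 0.01 mm steps with fixed front radii", {
  g <- build_lens(tiny_spec(sph = 20))
  expect_gte(min(g$thickness), 0.1)
  expect_gt(g$thickness_iterations, 0)
  expect_equal(g$Tc_final, 0.25 + 0.01 * g$thickness_iterations, tolerance = 1e-12)
  # front radii are those of the original design thickness
  expect_equal(g$Rf, front_radius(g$power_D, g$spec$index, 0.25, 8.5), tolerance = 1e-12)
  # idempotent on a satisfying lens
  g2 <- enforce_min_thickness(g)
  expect_equal(g2$Zf, g$Zf)
  expect_equal(g2$Tc_final, g$Tc_final)
  # a gentle lens is untouched
  g0 <- build_lens(tiny_spec(sph = -3))
  expect_equal(g0$thickness_iterations, 0)
  expect_equal(g0$Tc_final, 0.25)
})

test_that("built geometry is meridian-symmetric exactly when the design is", {
  gs <- build_lens(tiny_spec(sph = 4))
  expect_lt(max(apply(gs$Zf, 2, function(col) diff(range(col)))), 1e-10)
  gt <- build_lens(tiny_spec(cyl = 3))
  expect_gt(max(apply(gt$Zf, 2, function(col) diff(range(col)))), 1e-3)
  # back surface is rotationally symmetric by construction (single vector)
  expect_equal(length(gt$Zb), length(gt$X))
  # edge thickness meets Te where the design is symmetric
  expect_equal(unname(gs$thickness[1, length(gs$X)]), gs$spec$edge_thickness, tolerance = 1e-9)
})

test_that("every design across the sweep grid keeps back-surface continuity and valid thickness", {
  for (D in c(13.5, 14, 14.5)) {
    for (P in c(-10, 0, 20)) {
      g <- build_lens(tiny_spec(sph = P, diameter = D))
      b <- g$back
      for (xj in c(b$d1 / 2, b$d2 / 2)) {
        expect_lt(abs(back_sag(xj + 1e-9, b) - back_sag(xj - 1e-9, b)), 1e-8)
      }
      expect_gte(min(g$thickness), 0.1)
      # paraxial oracle per meridian on the as-designed thickness
      expect_equal(
        paraxial_power(g$Rf, 8.5, 0.25, g$spec$index),
        g$power_D,
        tolerance = 0.05
      )
    }
  }
})

test_that("lens geometry round-trips through the long tibble and CSV forms", {
  g <- build_lens(tiny_spec(sph = 1, n_meridians = 12, n_radial = 21))
  tbl <- tibble::as_tibble(g)
  expect_equal(nrow(tbl), 12 * 21)
  expect_named(tbl, c("meridian_deg", "X_mm", "Zb_mm", "Zf_mm", "thickness_mm"))
  f <- tempfile(fileext = ".csv")
  write_lens_csv(g, f)
  back <- read_lens_csv(f)
  expect_equal(nrow(back), nrow(tbl))
  expect_equal(back$Zf_mm, tbl$Zf_mm, tolerance = 1e-9)
  fobj <- tempfile(fileext = ".obj")
  write_lens_obj(g, fobj)
  expect_true(file.size(fobj) > 1000)
})
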