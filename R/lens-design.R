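#' Specify a tri-curve soft lens design
#'
#' All user-facing design parameters of one lens. The back surface is a
#' rotationally symmetric tri-curve (optic / transient / peripheral zones);
#' the front surface carries the refractive power per meridian (toric when
#' `cyl != 0`) through the thick-lens maker's relation.
#'
#' @param diameter Overall lens diameter D (mm).
#' @param optic_zone Optic zone diameter d1 (mm).
#' @param transient_zone Transient zone outer diameter d2 (mm). Not a
#'   reported quantity; defaults to the midpoint `(d1 + D) / 2`, splitting
#'   the non-optic annulus symmetrically.
#' @param base_curve Back optic zone radius Bc (mm).
#' @param sph,cyl Spherical and cylindrical powers (D).
#' @param cyl_axis Cylinder axis (deg): the meridians of maximum power.
#' @param index Lens refractive index (wet).
#' @param shape_factor Front-surface shape factor rho (1 = spherical).
#' @param centre_thickness Central thickness Tc (mm) before any
#'   minimum-thickness inflation.
#' @param edge_thickness Edge thickness Te (mm) met at X = D/2.
#' @param n_meridians,n_radial Grid resolution (meridians x radial stations).
#' @param ballast Apply the lower-lens prism ballast (see [apply_ballast()]).
#' @return A `lens_spec` list.
#' @export
lens_spec <- function(diameter = 14, optic_zone = 8, transient_zone = NULL,
                      base_curve = 8.5, sph = 0, cyl = 0, cyl_axis = 90,
                      index = 1.3739, shape_factor = 0.75,
                      centre_thickness = 0.25, edge_thickness = 0.4,
                      n_meridians = 360, n_radial = 101, ballast = FALSE) {
  if (is.null(transient_zone)) transient_zone <- (optic_zone + diameter) / 2
  if (!(optic_zone > 0 && optic_zone < transient_zone && transient_zone < diameter)) {
    abort("need 0 < optic_zone < transient_zone < diameter", class = "onlens_geometry_error")
  }
  if (base_curve <= 2) abort("base_curve must exceed 2 mm", class = "onlens_geometry_error")
  if (!(shape_factor > 0 && shape_factor <= 1)) abort("shape_factor must lie in (0, 1]")
  if (centre_thickness <= 0) abort("centre_thickness must be positive")
  if (!(index > 1 && index < 2)) abort("refractive index must lie in (1, 2)")
  structure(
    list(
      diameter = diameter, optic_zone = optic_zone, transient_zone = transient_zone,
      base_curve = base_curve, sph = sph, cyl = cyl, cyl_axis = cyl_axis,
      index = index, shape_factor = shape_factor,
      centre_thickness = centre_thickness, edge_thickness = edge_thickness,
      n_meridians = n_meridians, n_radial = n_radial, ballast = ballast
    ),
    class = "lens_spec"
  )
}

#' Tri-curve zone radii from the base curve
#'
#' The optic zone takes the base curve; the transient zone is 2 mm flatter
#' and the peripheral zone 2 mm steeper.
#'
#' @param base_curve Base curve Bc (mm), must exceed 2 mm.
#' @return Named vector `c(r1, r2, r3)` (mm).
#' @export
zone_radii <- function(base_curve) {
  if (!is.finite(base_curve) || base_curve <= 2) {
    abort("base_curve must exceed 2 mm (peripheral radius Bc - 2 must stay positive)",
      class = "onlens_geometry_error"
    )
  }
  c(r1 = base_curve, r2 = base_curve + 2, r3 = base_curve - 2)
}

#' Zone centre heights giving a continuous back sag
#'
#' Centres sit on the axis (x component zero); their heights are chosen so
#' the piecewise spherical sag is continuous at the two zone joins.
#'
#' @param radii Output of [zone_radii()].
#' @param d1,d2 Optic and transient zone diameters (mm).
#' @return Named vector `c(zc1, zc2, zc3)` (mm).
#' @export
zone_centres <- function(radii, d1, d2) {
  r1 <- radii[["r1"]]; r2 <- radii[["r2"]]; r3 <- radii[["r3"]]
  if (d1 / (2 * r1) > 1 || d1 / (2 * r2) > 1 || d2 / (2 * r2) > 1 || d2 / (2 * r3) > 1) {
    abort("zone diameter exceeds twice a zone radius (arcsin out of range)",
      class = "onlens_geometry_error"
    )
  }
  zc1 <- -r1
  zc2 <- zc1 - r2 * cos(asin(d1 / (2 * r2))) + r1 * cos(asin(d1 / (2 * r1)))
  zc3 <- zc2 - r3 * cos(asin(d2 / (2 * r3))) + r2 * cos(asin(d2 / (2 * r2)))
  c(zc1 = zc1, zc2 = zc2, zc3 = zc3)
}

# Cap angle (deg) at which a zone arc is continued by its tangent line.
# The peripheral arc (radius Bc - 2) cannot span the semi-diameter of any of
# the standard lens diameters, so the surface is extended tangentially once
# the local surface angle reaches this cap.
BACK_SURFACE_CAP_DEG <- 75

#' Back surface description
#'
#' Bundles zone radii, centres and extents for [back_sag()] and the
#' conformance solver.
#'
#' @param spec A [lens_spec()].
#' @return A `back_surface` list.
#' @export
back_surface <- function(spec) {
  radii <- zone_radii(spec$base_curve)
  centres <- zone_centres(radii, spec$optic_zone, spec$transient_zone)
  cap <- BACK_SURFACE_CAP_DEG * pi / 180
  x_cap <- radii[["r3"]] * sin(cap)
  structure(
    list(
      radii = radii, centres = centres,
      d1 = spec$optic_zone, d2 = spec$transient_zone, D = spec$diameter,
      cap_angle = cap, x_cap = x_cap
    ),
    class = "back_surface"
  )
}

#' Back surface sagittal height
#'
#' Piecewise spherical sag of the tri-curve back surface, apex at the
#' origin, anterior-positive z (so sag values are <= 0). Where the
#' peripheral-zone circle cannot reach (its radius is smaller than the lens
#' semi-diameter) the arc is continued by its tangent line from a 75-degree
#' cap angle.
#'
#' @param X Radial distances from the apex (mm), `0 <= X <= D/2`.
#' @param back A [back_surface()].
#' @return Sag Zb (mm), same length as `X`.
#' @export
back_sag <- function(X, back) {
  if (any(X < 0) || any(X > back$D / 2 + 1e-9)) {
    abort("X outside [0, D/2]", class = "onlens_out_of_range")
  }
  r <- back$radii; zc <- back$centres
  z <- numeric(length(X))
  in1 <- X <= back$d1 / 2
  in2 <- !in1 & X <= back$d2 / 2
  in3 <- !in1 & !in2 & X <= back$x_cap
  ext <- !in1 & !in2 & !in3
  z[in1] <- zc[["zc1"]] + sqrt(r[["r1"]]^2 - X[in1]^2)
  z[in2] <- zc[["zc2"]] + sqrt(r[["r2"]]^2 - X[in2]^2)
  z[in3] <- zc[["zc3"]] + sqrt(r[["r3"]]^2 - X[in3]^2)
  if (any(ext)) {
    z_cap <- zc[["zc3"]] + r[["r3"]] * cos(back$cap_angle)
    slope <- -tan(back$cap_angle)
    z[ext] <- z_cap + slope * (X[ext] - back$x_cap)
  }
  z
}

back_sag_slope <- function(X, back) {
  r <- back$radii
  slope <- numeric(length(X))
  in1 <- X <= back$d1 / 2
  in2 <- !in1 & X <= back$d2 / 2
  in3 <- !in1 & !in2 & X <= back$x_cap
  ext <- !in1 & !in2 & !in3
  slope[in1] <- -X[in1] / sqrt(r[["r1"]]^2 - X[in1]^2)
  slope[in2] <- -X[in2] / sqrt(r[["r2"]]^2 - X[in2]^2)
  slope[in3] <- -X[in3] / sqrt(r[["r3"]]^2 - X[in3]^2)
  slope[ext] <- -tan(back$cap_angle)
  slope
}

#' Per-meridian power profile of a sphero-cylindrical prescription
#'
#' The power across 360 meridians follows a cosine between
#' `Pmax = max(SPH + CYL, SPH)` and `Pmin = min(SPH + CYL, SPH)` with a
#' period of 180 degrees in meridian angle (two full cosine cycles over the
#' lens), circularly shifted so the maxima sit on the cylinder axis
#' meridians.
#'
#' @param sph,cyl Spherical and cylindrical powers (D).
#' @param cyl_axis Axis (deg) of the maximum-power meridians.
#' @param n_meridians Number of equally spaced meridians.
#' @return Tibble `meridian_deg`, `power_D` with attributes `pmax`, `pmin`,
#'   `pmean`, `pamp`.
#' @export
power_profile <- function(sph, cyl, cyl_axis = 90, n_meridians = 360) {
  pmax_ <- max(sph + cyl, sph)
  pmin_ <- min(sph + cyl, sph)
  pmean <- (pmax_ + pmin_) / 2
  pamp <- pmax_ - pmean
  phi <- seq(0, 360, length.out = n_meridians + 1)[seq_len(n_meridians)]
  theta <- 2 * phi * pi / 180 # theta spans [0, 4pi): period pi in meridian angle
  p0 <- pamp * cos(theta) + pmean
  # shift the maxima from meridian 0 to the cylinder axis
  if (pamp != 0 && cyl_axis %% 360 != 0) {
    step <- 360 / n_meridians
    if (abs(cyl_axis / step - round(cyl_axis / step)) < 1e-9) {
      k <- round(cyl_axis / step) %% n_meridians
      p0 <- p0[((seq_len(n_meridians) - 1 - k) %% n_meridians) + 1]
    } else {
      # periodic piecewise-cubic resampling on the circle
      phi_ext <- c(phi - 360, phi, phi + 360)
      p_ext <- rep(p0, 3)
      p0 <- spline(phi_ext, p_ext, xout = (phi - cyl_axis) %% 360, method = "fmm")$y
    }
  }
  out <- tibble::tibble(meridian_deg = phi, power_D = p0)
  attr(out, "pmax") <- pmax_
  attr(out, "pmin") <- pmin_
  attr(out, "pmean") <- pmean
  attr(out, "pamp") <- pamp
  out
}

#' Front surface radius from the thick-lens maker's relation
#'
#' Inverts the thick-lens power of the (front radius, back radius, centre
#' thickness, index) system for the front radius giving the requested
#' meridian power. Powers are diopters (1/m); radii and thickness mm.
#'
#' @param power_D Meridian power(s) (D).
#' @param index Lens refractive index.
#' @param centre_thickness Tc (mm).
#' @param back_radius Back optic zone radius R1b (mm).
#' @return Front radius(es) Rf (mm).
#' @export
front_radius <- function(power_D, index, centre_thickness, back_radius) {
  n <- index
  tc <- centre_thickness / 1000
  rb <- back_radius / 1000
  den <- n * rb * power_D + n * (n - 1)
  if (any(abs(den) < 1e-9)) {
    abort("singular meridian power: lens maker denominator vanishes",
      class = "onlens_singular_power"
    )
  }
  1000 * (tc * (n - 1)^2 + n * (n - 1) * rb) / den
}

#' Paraxial thick-lens power of a surface pair
#'
#' Independent paraxial check: the power of a lens in air with front radius
#' `rf`, back radius `rb` (both centres posterior to their surfaces),
#' thickness `tc` and index `n`.
#'
#' @param rf,rb Front and back radii (mm).
#' @param tc Centre thickness (mm).
#' @param n Refractive index.
#' @return Power (D).
#' @export
paraxial_power <- function(rf, rb, tc, n) {
  p1 <- (n - 1) / (rf / 1000)
  p2 <- (1 - n) / (rb / 1000)
  p1 + p2 - (tc / 1000 / n) * p1 * p2
}

#' Front surface sagittal height
#'
#' Shape-factor-generalised sag measured from the front apex at height Tc:
#' `Zf = Tc - (Rf - sqrt(Rf^2 - rho X^2)) / rho`. `rho = 1` is the
#' spherical sag.
#'
#' @param X Radial distances (mm).
#' @param rf Front radius (mm).
#' @param centre_thickness Apex height Tc (mm).
#' @param shape_factor rho in (0, 1].
#' @return Heights Zf (mm).
#' @export
front_sag <- function(X, rf, centre_thickness, shape_factor) {
  arg <- rf^2 - shape_factor * X^2
  if (any(arg < 0)) {
    abort("front sag undefined: rho X^2 exceeds Rf^2 inside requested aperture",
      class = "onlens_aperture_error"
    )
  }
  centre_thickness - (rf - sqrt(arg)) / shape_factor
}

# cubic Hermite on [x1, x2] through (y1, y1p) -> (y2, y2p)
hermite_blend <- function(x, x1, x2, y1, y2, y1p, y2p = 0) {
  h <- x2 - x1
  u <- (x - x1) / h
  h00 <- (1 + 2 * u) * (1 - u)^2
  h10 <- u * (1 - u)^2
  h01 <- u^2 * (3 - 2 * u)
  h11 <- u^2 * (u - 1)
  h00 * y1 + h10 * h * y1p + h01 * y2 + h11 * h * y2p
}

# Front heights matrix (meridians x radial stations) for given per-meridian
# front radii and centre thickness. Inside the optic zone the analytic sag is
# used; beyond it the *thickness* is blended by a cubic Hermite from its
# value/slope at the optic-zone edge to the edge thickness Te at X = D/2.
front_heights <- function(X, rf, tc, spec, back, zb) {
  rho <- spec$shape_factor
  x1 <- spec$optic_zone / 2
  M <- length(rf)
  in_opt <- X <= x1 + 1e-12
  Xo <- X[in_opt]
  Xp <- X[!in_opt]
  arg_o <- outer(rf^2, rho * Xo^2, "-")
  if (any(arg_o < 0)) {
    abort("front sag undefined within the optic zone", class = "onlens_aperture_error")
  }
  zf <- matrix(NA_real_, M, length(X))
  zf[, in_opt] <- tc - (rf - sqrt(arg_o)) / rho
  if (length(Xp)) {
    zb1 <- back_sag(x1, back)
    zb1p <- back_sag_slope(x1, back)
    t1 <- (tc - (rf - sqrt(rf^2 - rho * x1^2)) / rho) - zb1
    t1p <- (-x1 / sqrt(rf^2 - rho * x1^2)) - zb1p
    zbp <- back_sag(Xp, back)
    # vectorised over meridians: rows are meridians, columns peripheral X
    tper <- t(vapply(
      seq_len(M),
      function(j) {
        hermite_blend(Xp, x1, spec$diameter / 2, t1[j], spec$edge_thickness, t1p[j])
      },
      numeric(length(Xp))
    ))
    zf[, !in_opt] <- sweep(tper, 2, zbp, "+")
  }
  zf
}

#' Ballast thickness profile
#'
#' The per-meridian characteristic thickness `Tj = Tc (1 - W sin(theta))`
#' with weighting `W = 0.2` over the upper half (`0 <= theta <= pi`) and
#' `W = 1` over the lower half, so the lower lens is thickened (prism
#' ballast) to stabilise toric orientation.
#'
#' @param theta_rad Meridian angles (rad).
#' @param centre_thickness Tc (mm).
#' @return Thickness values Tj (mm).
#' @export
ballast_profile <- function(theta_rad, centre_thickness) {
  th <- theta_rad %% (2 * pi)
  w <- ifelse(th <= pi, 0.2, 1.0)
  centre_thickness * (1 - w * sin(th))
}

#' Apply the prism ballast to a lens geometry
#'
#' Adds the ballast thickness excess `Tj(theta) - Tc` to the front surface,
#' tapered linearly with `X / (D/2)` so it vanishes at the apex (a
#' per-meridian constant offset would make the apex height multivalued) and
#' reaches the full profile value at the lens edge.
#'
#' @param geom A `lens_geometry` from [build_lens()].
#' @return The geometry with ballasted front surface and updated thickness.
#' @export
apply_ballast <- function(geom) {
  theta <- geom$meridian_deg * pi / 180
  excess <- ballast_profile(theta, geom$Tc_final) - geom$Tc_final
  taper <- geom$X / (geom$spec$diameter / 2)
  geom$Zf <- geom$Zf + outer(excess, taper)
  geom$thickness <- geom$Zf - matrix(geom$Zb, nrow(geom$Zf), ncol(geom$Zf), byrow = TRUE)
  geom$ballast_applied <- TRUE
  geom
}

#' Inflate the centre thickness until a minimum thickness holds
#'
#' High plus powers make the front surface cut into the back surface; the
#' remedy is to add 0.01 mm to the centre thickness, re-elevate the front
#' surface with unchanged front curvatures, and repeat until the thickness
#' everywhere exceeds 0.1 mm.
#'
#' @param geom A `lens_geometry`.
#' @param min_thickness Minimum allowed thickness (mm).
#' @param step Centre-thickness increment per iteration (mm).
#' @param max_iter Iteration guard.
#' @return The geometry, possibly thicker, with `Tc_final` and
#'   `thickness_iterations` updated. Front radii are untouched.
#' @export
enforce_min_thickness <- function(geom, min_thickness = 0.1, step = 0.01, max_iter = 200) {
  it <- 0
  while (min(geom$thickness) < min_thickness) {
    it <- it + 1
    if (it > max_iter) {
      abort("minimum-thickness iteration did not terminate: design infeasible",
        class = "onlens_design_infeasible"
      )
    }
    geom$Tc_final <- geom$Tc_final + step
    geom$Zf <- front_heights(geom$X, geom$Rf, geom$Tc_final, geom$spec, geom$back, geom$Zb)
    if (isTRUE(geom$ballast_applied)) {
      theta <- geom$meridian_deg * pi / 180
      excess <- ballast_profile(theta, geom$Tc_final) - geom$Tc_final
      geom$Zf <- geom$Zf + outer(excess, geom$X / (geom$spec$diameter / 2))
    }
    geom$thickness <- geom$Zf - matrix(geom$Zb, nrow(geom$Zf), ncol(geom$Zf), byrow = TRUE)
  }
  geom$thickness_iterations <- (geom$thickness_iterations %||% 0) + it
  geom
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the full lens geometry
#'
#' Composes the design chain: zone radii and centres, the back sag grid, the
#' per-meridian power profile, front radii from the thick-lens relation,
#' front sag (with the peripheral thickness blend to Te), optional ballast,
#' and the minimum-thickness iteration.
#'
#' @param spec A [lens_spec()].
#' @return A `lens_geometry` list: `meridian_deg` (M), `X` (K radial
#'   stations), `Zb` (K), `Zf` (M x K), `Rf` (M), `power_D` (M),
#'   `thickness` (M x K), `Tc_final`, plus the spec and back-surface
#'   description.
#' @export
build_lens <- function(spec) {
  stopifnot(inherits(spec, "lens_spec"))
  back <- back_surface(spec)
  X <- seq(0, spec$diameter / 2, length.out = spec$n_radial)
  Zb <- back_sag(X, back)
  prof <- power_profile(spec$sph, spec$cyl, spec$cyl_axis, spec$n_meridians)
  rf <- front_radius(prof$power_D, spec$index, spec$centre_thickness, spec$base_curve)
  Zf <- front_heights(X, rf, spec$centre_thickness, spec, back, Zb)
  geom <- structure(
    list(
      spec = spec, back = back,
      meridian_deg = prof$meridian_deg, X = X, Zb = Zb, Zf = Zf,
      Rf = rf, power_D = prof$power_D,
      thickness = Zf - matrix(Zb, nrow(Zf), ncol(Zf), byrow = TRUE),
      Tc_final = spec$centre_thickness,
      thickness_iterations = 0,
      ballast_applied = FALSE
    ),
    class = "lens_geometry"
  )
  if (isTRUE(spec$ballast)) geom <- apply_ballast(geom)
  enforce_min_thickness(geom)
}

#' Paraxial power of an as-built lens
#'
#' Thick-lens power per meridian using the final (possibly inflated) centre
#' thickness. The ray tracer measures the focal length from the back apex,
#' so its paraxial limit is the *back vertex* power
#' `P_equiv / (1 - (Tc/n) P_front)`; traced powers are validated against
#' that oracle. Contact lens prescriptions are quoted as back vertex powers.
#'
#' @param geom A `lens_geometry`.
#' @param type `"back_vertex"` (default, matches the traced measurement) or
#'   `"equivalent"` (thick-lens equivalent power).
#' @return Numeric vector of per-meridian paraxial powers (D).
#' @export
lens_paraxial_power <- function(geom, type = c("back_vertex", "equivalent")) {
  type <- match.arg(type)
  n <- geom$spec$index
  p_equiv <- paraxial_power(geom$Rf, geom$spec$base_curve, geom$Tc_final, n)
  if (type == "equivalent") {
    return(p_equiv)
  }
  p1 <- (n - 1) / (geom$Rf / 1000)
  p_equiv / (1 - (geom$Tc_final / 1000 / n) * p1)
}

#' @export
print.lens_geometry <- function(x, ...) {
  cat(sprintf(
    "<lens_geometry> D = %.1f mm, Bc = %.2f mm, SPH %+.2f / CYL %+.2f D @ %g, n = %.4f\n",
    x$spec$diameter, x$spec$base_curve, x$spec$sph, x$spec$cyl, x$spec$cyl_axis, x$spec$index
  ))
  cat(sprintf(
    "  Tc %.3f mm (%d thickening steps), min thickness %.3f mm, grid %d x %d\n",
    x$Tc_final, x$thickness_iterations, min(x$thickness),
    length(x$meridian_deg), length(x$X)
  ))
  invisible(x)
}

#' Long-format node table of a lens geometry
#'
#' @param x A `lens_geometry`.
#' @param ... Unused.
#' @return Tibble `meridian_deg`, `X_mm`, `Zb_mm`, `Zf_mm`, `thickness_mm`.
#' @export
as_tibble.lens_geometry <- function(x, ...) {
  M <- length(x$meridian_deg); K <- length(x$X)
  tibble::tibble(
    meridian_deg = rep(x$meridian_deg, times = K),
    X_mm = rep(x$X, each = M),
    Zb_mm = rep(x$Zb, each = M),
    Zf_mm = as.vector(x$Zf),
    thickness_mm = as.vector(x$thickness)
  )
}

#' Write / read a lens geometry node table as CSV
#'
#' @param geom A `lens_geometry`.
#' @param path File path.
#' @return `write_lens_csv()` returns `path` invisibly; `read_lens_csv()`
#'   the node tibble.
#' @export
write_lens_csv <- function(geom, path) {
  readr::write_csv(tibble::as_tibble(geom), path)
  invisible(path)
}

#' @rdname write_lens_csv
#' @export
read_lens_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Export lens surfaces as a Wavefront OBJ mesh
#'
#' Triangulated front and back surfaces for quick visual inspection in any
#' mesh viewer.
#'
#' @param geom A `lens_geometry`.
#' @param path Output `.obj` path.
#' @return `path`, invisibly.
#' @export
write_lens_obj <- function(geom, path) {
  phi <- geom$meridian_deg * pi / 180
  M <- length(phi); K <- length(geom$X)
  verts <- function(zmat_or_vec, front) {
    z <- if (front) geom$Zf else matrix(geom$Zb, M, K, byrow = TRUE)
    x <- outer(cos(phi), geom$X)
    y <- outer(sin(phi), geom$X)
    cbind(as.vector(x), as.vector(y), as.vector(z))
  }
  v <- rbind(verts(NULL, TRUE), verts(NULL, FALSE))
  idx <- function(j, k, off) off + (k - 1) * M + j # column-major over (meridian, radius)
  faces <- list()
  for (off in c(0, M * K)) {
    for (k in seq_len(K - 1)) {
      j <- seq_len(M)
      jn <- c(seq_len(M)[-1], 1)
      a <- idx(j, k, off); b <- idx(jn, k, off)
      cc <- idx(jn, k + 1, off); d <- idx(j, k + 1, off)
      faces[[length(faces) + 1]] <- cbind(a, b, cc)
      faces[[length(faces) + 1]] <- cbind(a, cc, d)
    }
  }
  f <- do.call(rbind, faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# onlenspower lens mesh", con)
  writeLines(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}
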