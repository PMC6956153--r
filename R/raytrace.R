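#' Angle of incidence between a ray and a surface normal
#'
#' Folded to `[0, pi/2]` via the absolute dot product, so the result does
#' not depend on the normal's sign convention.
#'
#' @param direction Unit ray direction (length-3).
#' @param normal Unit surface normal (length-3).
#' @return Angle (rad).
#' @export
incidence_angle <- function(direction, normal) {
  acos(pmin(1, abs(sum(direction * normal))))
}

#' Snell's law for the refraction angle
#'
#' @param phi_in Incidence angle (rad).
#' @param n_in,n_out Refractive indices of the incident and transmitting
#'   media.
#' @return Refraction angle (rad). Total internal reflection raises a
#'   condition of class `onlens_tir`.
#' @export
snell <- function(phi_in, n_in, n_out) {
  if (n_in <= 0 || n_out <= 0) abort("refractive indices must be positive")
  arg <- n_in / n_out * sin(phi_in)
  if (arg > 1) {
    abort("total internal reflection: refraction angle undefined", class = "onlens_tir")
  }
  asin(arg)
}

#' Meridian angle and z-rotation of a surface normal
#'
#' The meridian angle is `atan2(Ny, Nx)`; the returned rotation (about the
#' z axis) zeroes the normal's y component, taking the refraction event
#' into its meridian plane.
#'
#' @param normal Normal vector (length-3; need not be unit).
#' @return List with `theta` (rad) and the 3 x 3 orthonormal `rotation`.
#' @export
meridian_rotation <- function(normal) {
  theta <- if (abs(normal[1]) < 1e-300 && abs(normal[2]) < 1e-300) {
    0
  } else {
    atan2(normal[2], normal[1])
  }
  rot <- rbind(
    c(cos(theta), sin(theta), 0),
    c(-sin(theta), cos(theta), 0),
    c(0, 0, 1)
  )
  list(theta = theta, rotation = rot)
}

# closed-form vector Snell refraction: the independent oracle for the
# rotation construction. n_o must oppose the incoming direction.
snell_vector <- function(d, n_o, n_in, n_out) {
  eta <- n_in / n_out
  cos_in <- -sum(d * n_o)
  sin2_out <- eta^2 * (1 - cos_in^2)
  if (sin2_out > 1) abort("total internal reflection", class = "onlens_tir")
  eta * d + (eta * cos_in - sqrt(1 - sin2_out)) * n_o
}

# Refracted direction by the meridian-rotation construction: rotate the
# event into the normal's meridian plane (zeroing N_y), rotate the
# propagation direction within the plane of incidence by (phi_out - phi_in),
# rotate back. Cross-checked against the closed-form vector Snell law at
# every event.
refract_direction <- function(d, n_surf, n_in, n_out, check_tol = 1e-8) {
  n_o <- if (sum(d * n_surf) > 0) -n_surf else n_surf
  mer <- meridian_rotation(n_o)
  R <- mer$rotation
  d_r <- as.numeric(R %*% d)
  n_r <- as.numeric(R %*% n_o)
  phi_in <- incidence_angle(d_r, n_r)
  phi_out <- snell(phi_in, n_in, n_out)
  # in-plane polar rotation: decompose d into the normal direction and the
  # tangential unit within the incidence plane, then set the new angle
  tang <- d_r - sum(d_r * n_r) * n_r
  tn <- sqrt(sum(tang^2))
  if (tn < 1e-14) {
    d_out_r <- d_r # normal incidence: direction unchanged
  } else {
    tang <- tang / tn
    d_out_r <- sin(phi_out) * tang - cos(phi_out) * n_r
  }
  d_out <- as.numeric(t(R) %*% d_out_r)
  oracle <- snell_vector(d, n_o, n_in, n_out)
  if (max(abs(d_out - oracle)) > check_tol) {
    abort("refraction construction disagrees with vector Snell law",
      class = "onlens_trace_error"
    )
  }
  list(
    direction = d_out, phi_in = phi_in, phi_out = phi_out,
    normal = n_o, theta_mer = mer$theta
  )
}

# Damped Newton intersection of a ray with a fitted surface along t >= 0.
intersect_surface <- function(p, d, surface, tol = 1e-10, max_iter = 60) {
  g_fun <- function(t) {
    q <- p + t * d
    surface_height(surface, q[1], q[2]) - q[3]
  }
  # initial guess: intersection with the apex plane
  t <- (p[3] - surface_height(surface, p[1], p[2])) / max(-d[3], 1e-6)
  if (!is.finite(t) || t < 0) t <- 0
  for (i in seq_len(max_iter)) {
    q <- p + t * d
    if (sqrt(q[1]^2 + q[2]^2) > surface$aperture) {
      abort("ray left the fitted aperture", class = "onlens_miss")
    }
    g <- surface_height(surface, q[1], q[2]) - q[3]
    if (abs(g) < tol) {
      return(list(t = t, point = q))
    }
    grad <- surface_gradient(surface, q[1], q[2])
    dg <- grad$fx * d[1] + grad$fy * d[2] - d[3]
    step <- -g / dg
    if (!is.finite(step)) abort("degenerate ray-surface intersection", class = "onlens_miss")
    if (abs(step) > surface$aperture) step <- sign(step) * surface$aperture
    t <- t + step
  }
  abort("ray-surface intersection did not converge", class = "onlens_miss")
}

#' Refract a single ray at a fitted surface
#'
#' Finds the ray-surface intersection, evaluates the implicit-surface
#' normal, and refracts via the meridian-rotation construction (validated
#' at run time against the closed-form vector Snell law).
#'
#' @param ray List with `origin` and unit `direction` (length-3 each).
#' @param surface An `optical_surface` from [fit_surface()].
#' @param n_in,n_out Refractive indices either side of the surface.
#' @return The refracted ray (origin at the intersection) with event fields
#'   `phi_in`, `phi_out`, `normal`, `theta_mer`.
#' @export
refract_ray <- function(ray, surface, n_in, n_out) {
  hit <- intersect_surface(ray$origin, ray$direction, surface)
  nrm <- as.numeric(surface_normal(surface, hit$point[1], hit$point[2]))
  ref <- refract_direction(ray$direction, nrm, n_in, n_out)
  list(
    origin = hit$point, direction = ref$direction,
    phi_in = ref$phi_in, phi_out = ref$phi_out,
    normal = ref$normal, theta_mer = ref$theta_mer
  )
}

#' Hexapolar launch grid
#'
#' @param semi_aperture Pupil semi-aperture (mm).
#' @param n_rings Number of rings (6 rings = 127 rays including the chief
#'   ray).
#' @return Tibble `x0`, `y0`.
#' @export
hexapolar_grid <- function(semi_aperture, n_rings = 6) {
  pts <- list(c(0, 0))
  for (k in seq_len(n_rings)) {
    r <- semi_aperture * k / n_rings
    ang <- seq(0, 2 * pi, length.out = 6 * k + 1)[seq_len(6 * k)]
    pts[[k + 1]] <- cbind(r * cos(ang), r * sin(ang))
  }
  m <- do.call(rbind, pts)
  tibble::tibble(x0 = m[, 1], y0 = m[, 2])
}

# Batched ray-surface Newton intersection. P, D are n x 3 matrices; rays
# whose iterate leaves the fitted aperture (or fails to converge) are
# flagged as misses.
intersect_surface_batch <- function(P, D, surface, tol = 1e-10, max_iter = 60) {
  n <- nrow(P)
  t <- (P[, 3] - surface_height(surface, P[, 1], P[, 2])) / pmax(-D[, 3], 1e-6)
  t[!is.finite(t) | t < 0] <- 0
  ok <- rep(TRUE, n)
  active <- rep(TRUE, n)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    Q <- P + t * D
    r <- sqrt(Q[, 1]^2 + Q[, 2]^2)
    out <- active & r > surface$aperture
    if (any(out)) {
      ok[out] <- FALSE
      active[out] <- FALSE
    }
    if (!any(active)) break
    i <- which(active)
    g <- surface_height(surface, Q[i, 1], Q[i, 2]) - Q[i, 3]
    conv <- abs(g) < tol
    active[i[conv]] <- FALSE
    i <- i[!conv]
    if (!length(i)) break
    grad <- surface_gradient(surface, Q[i, 1], Q[i, 2])
    dg <- grad$fx * D[i, 1] + grad$fy * D[i, 2] - D[i, 3]
    step <- -g[!conv] / dg
    step[!is.finite(step)] <- 0
    step <- pmin(pmax(step, -surface$aperture), surface$aperture)
    t[i] <- t[i] + step
  }
  ok[active] <- FALSE # non-converged
  list(t = t, points = P + t * D, ok = ok)
}

# Batched refraction: same in-plane construction as refract_direction(),
# row-wise, cross-checked against the closed-form vector Snell law.
refract_batch <- function(D, N, n_in, n_out, check_tol = 1e-8) {
  s <- rowSums(D * N)
  sgn <- ifelse(s > 0, -1, 1)
  No <- N * sgn
  cos_in <- pmin(1, -rowSums(D * No))
  eta <- n_in / n_out
  sin2_out <- eta^2 * (1 - cos_in^2)
  tir <- sin2_out > 1
  cos_out <- sqrt(pmax(0, 1 - pmin(sin2_out, 1)))
  tang <- D + cos_in * No
  tn <- sqrt(rowSums(tang^2))
  unit_t <- tang / ifelse(tn < 1e-14, 1, tn)
  Dout <- sqrt(pmin(sin2_out, 1)) * unit_t - cos_out * No
  normal_inc <- tn < 1e-14
  if (any(normal_inc)) Dout[normal_inc, ] <- D[normal_inc, ]
  oracle <- eta * D + (eta * cos_in - cos_out) * No
  bad <- !tir & apply(abs(Dout - oracle), 1, max) > check_tol
  bad[is.na(bad)] <- FALSE
  if (any(bad)) {
    abort("refraction construction disagrees with vector Snell law",
      class = "onlens_trace_error"
    )
  }
  list(
    D = Dout, tir = tir, normal = No,
    phi_in = acos(cos_in), phi_out = asin(sqrt(pmin(sin2_out, 1)))
  )
}

#' Trace a parallel ray bundle through a lens
#'
#' Launches a hexapolar grid of rays parallel to the optical axis
#' (direction `(0, 0, -1)` in the anterior-positive frame), refracts each
#' at the front (air to lens) and back (lens to air) fitted surfaces, and
#' takes each ray's axial crossing as its point of closest approach to the
#' optical axis. The focal length is the mean crossing distance from the
#' back apex; power is its reciprocal (1000/f for f in mm, lens in air).
#' Refraction is cross-checked against the closed-form vector Snell law at
#' every event.
#'
#' @param front,back `optical_surface` fits of the two lens interfaces.
#' @param n_lens Lens refractive index (air assumed on both sides).
#' @param pupil_semi_aperture Bundle semi-aperture (mm).
#' @param n_rings Hexapolar rings (6 = 127 rays).
#' @param keep_events Keep per-event data for invariant checks.
#' @return A `lens_trace`: `power_D`, `focal_mm` (Inf for an afocal
#'   bundle), `spread_mm` (SD of finite crossings), per-ray tibble `rays`,
#'   and optionally `events` (per-surface refraction data).
#' @export
trace_bundle <- function(front, back, n_lens, pupil_semi_aperture = 1.5,
                         n_rings = 6, keep_events = FALSE) {
  grid <- hexapolar_grid(pupil_semi_aperture, n_rings)
  tr <- trace_bundle_impl(grid, front, back, n_lens, keep_events)
  tr$pupil <- pupil_semi_aperture
  tr
}

trace_bundle_impl <- function(grid, front, back, n_lens, keep_events = FALSE) {
  n <- nrow(grid)
  z0 <- surface_height(front, 0, 0) + 5
  P <- cbind(grid$x0, grid$y0, rep(z0, n))
  D <- cbind(rep(0, n), rep(0, n), rep(-1, n))
  reason <- rep(NA_character_, n)

  h1 <- intersect_surface_batch(P, D, front)
  reason[!h1$ok] <- "miss"
  N1 <- surface_normal(front, h1$points[, 1], h1$points[, 2])
  r1 <- refract_batch(D, N1, 1, n_lens)
  reason[is.na(reason) & r1$tir] <- "tir"

  h2 <- intersect_surface_batch(h1$points, r1$D, back)
  reason[is.na(reason) & !h2$ok] <- "miss"
  N2 <- surface_normal(back, h2$points[, 1], h2$points[, 2])
  r2 <- refract_batch(r1$D, N2, n_lens, 1)
  reason[is.na(reason) & r2$tir] <- "tir"

  dropped <- !is.na(reason)
  p <- h2$points
  d <- r2$D
  dr2 <- d[, 1]^2 + d[, 2]^2
  afocal <- dr2 < 1e-24
  tstar <- ifelse(afocal, 0, -(p[, 1] * d[, 1] + p[, 2] * d[, 2]) / pmax(dr2, 1e-300))
  q <- p + tstar * d
  crossing_z <- ifelse(afocal, Inf, q[, 3])
  miss_distance <- ifelse(afocal, sqrt(p[, 1]^2 + p[, 2]^2), sqrt(q[, 1]^2 + q[, 2]^2))
  crossing_z[dropped] <- NA_real_
  miss_distance[dropped] <- NA_real_

  rays <- tibble::tibble(
    x0 = grid$x0, y0 = grid$y0, crossing_z = crossing_z,
    miss_distance = miss_distance, dropped = dropped, reason = reason
  )
  events <- if (keep_events) {
    list(
      first = list(
        point = h1$points, normal = r1$normal, d_in = D, d_out = r1$D,
        phi_in = r1$phi_in, phi_out = r1$phi_out, n_in = 1, n_out = n_lens
      ),
      second = list(
        point = h2$points, normal = r2$normal, d_in = r1$D, d_out = r2$D,
        phi_in = r2$phi_in, phi_out = r2$phi_out, n_in = n_lens, n_out = 1
      )
    )
  } else {
    NULL
  }
  ok <- rays[!rays$dropped, ]
  if (nrow(ok) < 10) {
    abort("fewer than 10 rays survived the trace", class = "onlens_trace_error")
  }
  apex_z <- surface_height(back, 0, 0)
  # focal length = distance from the back apex to the average axis
  # intersection of the rays that define one (the chief ray and afocal
  # rays do not); power is its reciprocal
  finite <- is.finite(ok$crossing_z)
  if (!any(finite)) {
    focal <- Inf
    power <- 0
  } else {
    focal <- apex_z - mean(ok$crossing_z[finite])
    power <- if (is.finite(focal) && abs(focal) > 1e-9) 1000 / focal else 0
  }
  spread <- if (sum(finite) > 1) sd(ok$crossing_z[finite]) else 0
  structure(
    list(
      power_D = power, focal_mm = focal, apex_z = apex_z,
      spread_mm = spread,
      crossing_mean_mm = if (any(finite)) mean(ok$crossing_z[finite]) else NA_real_,
      n_rays = nrow(rays), n_dropped = sum(rays$dropped),
      rays = rays, events = if (keep_events) events else NULL,
      n_lens = n_lens, pupil = NA_real_
    ),
    class = "lens_trace"
  )
}

#' @export
print.lens_trace <- function(x, ...) {
  cat(sprintf(
    "<lens_trace> power %.4f D (f = %.2f mm), spread %.3g mm, %d/%d rays\n",
    x$power_D, x$focal_mm, x$spread_mm, x$n_rays - x$n_dropped, x$n_rays
  ))
  invisible(x)
}

# node clouds (x, y, z tibbles) of the two interfaces of an (un)conformed lens
lens_node_cloud <- function(obj) {
  if (inherits(obj, "conformed_lens")) {
    phi <- obj$meridian_deg * pi / 180
    M <- length(phi); K <- length(obj$s)
    xb <- matrix(obj$xb, M, K, byrow = TRUE)
    zb <- matrix(obj$zb, M, K, byrow = TRUE)
    list(
      front = tibble::tibble(
        x = as.vector(obj$xf * cos(phi)), y = as.vector(obj$xf * sin(phi)),
        z = as.vector(obj$zf)
      ),
      back = tibble::tibble(
        x = as.vector(xb * cos(phi)), y = as.vector(xb * sin(phi)),
        z = as.vector(zb)
      )
    )
  } else if (inherits(obj, "lens_geometry")) {
    phi <- obj$meridian_deg * pi / 180
    M <- length(phi); K <- length(obj$X)
    Xm <- matrix(obj$X, M, K, byrow = TRUE)
    Zb <- matrix(obj$Zb, M, K, byrow = TRUE)
    list(
      front = tibble::tibble(
        x = as.vector(Xm * cos(phi)), y = as.vector(Xm * sin(phi)),
        z = as.vector(obj$Zf)
      ),
      back = tibble::tibble(
        x = as.vector(Xm * cos(phi)), y = as.vector(Xm * sin(phi)),
        z = as.vector(Zb)
      )
    )
  } else {
    abort("expected a lens_geometry or conformed_lens")
  }
}

#' Trace a meridional ray fan
#'
#' Launches rays in a single meridian plane (both sides of the axis);
#' meridional rays of a surface symmetric about that plane stay in it and
#' intersect the optical axis exactly, which makes the fan power the
#' natural per-meridian measure for toric lenses.
#'
#' @inheritParams trace_bundle
#' @param azimuth_deg Meridian plane azimuth (deg).
#' @param n_points Ray heights across the pupil diameter.
#' @return A `lens_trace`.
#' @export
trace_fan <- function(front, back, n_lens, azimuth_deg,
                      pupil_semi_aperture = 1.5, n_points = 40) {
  h <- pupil_semi_aperture * seq(-1, 1, length.out = n_points + 1)
  h <- h[h != 0]
  az <- azimuth_deg * pi / 180
  grid <- tibble::tibble(x0 = h * cos(az), y0 = h * sin(az))
  tr <- trace_bundle_points(grid, front, back, n_lens)
  # fan power as the average per-ray vergence: every meridional ray has a
  # well-defined focus, and averaging vergences stays stable for near-plano
  # meridians where the mean crossing position diverges
  ok <- tr$rays[!tr$rays$dropped, ]
  fin <- is.finite(ok$crossing_z)
  if (any(fin)) {
    tr$power_D <- mean(1000 / (tr$apex_z - ok$crossing_z[fin]))
    tr$focal_mm <- if (abs(tr$power_D) > 1e-9) 1000 / tr$power_D else Inf
  }
  tr$pupil <- pupil_semi_aperture
  tr$azimuth_deg <- azimuth_deg
  tr
}

# shared implementation: trace a given launch grid (used by trace_bundle
# and trace_fan)
trace_bundle_points <- function(grid, front, back, n_lens, keep_events = FALSE) {
  trace_bundle_impl(grid, front, back, n_lens, keep_events)
}

#' Fit both interfaces of a lens and trace it
#'
#' Convenience wrapper: builds the front/back node clouds of an undeformed
#' or conformed lens, fits Zernike surfaces over the optic-zone aperture,
#' and traces a parallel bundle.
#'
#' @param obj A `lens_geometry` or `conformed_lens`.
#' @param n_lens Lens refractive index; defaults to the design index (or
#'   the conforming material's index).
#' @param pupil_semi_aperture,n_rings Bundle settings (see
#'   [trace_bundle()]).
#' @param fit_aperture Surface-fit aperture (mm); default the optic-zone
#'   semi-diameter.
#' @param order Zernike radial order.
#' @param keep_events Keep per-event refraction data.
#' @param toric_fans Trace the two principal meridional fans (at the
#'   cylinder axis and 90 degrees away) and average their powers, instead
#'   of the hexapolar bundle. The natural measure for toric lenses, whose
#'   skew bundle rays do not intersect the axis; selected automatically by
#'   [simulate_epc()] when `cyl != 0`.
#' @return A `lens_trace` with the two `optical_surface` fits attached as
#'   `$front` / `$back` (for `toric_fans = TRUE` the two fan traces are
#'   attached as `$fans` and `power_D` is their mean).
#' @export
trace_lens <- function(obj, n_lens = NULL, pupil_semi_aperture = 1.5,
                       n_rings = 6, fit_aperture = NULL, order = 8,
                       keep_events = FALSE, toric_fans = FALSE) {
  spec <- if (inherits(obj, "conformed_lens")) obj$lens$spec else obj$spec
  if (is.null(n_lens)) n_lens <- spec$index
  if (is.null(fit_aperture)) fit_aperture <- spec$optic_zone / 2
  nodes <- lens_node_cloud(obj)
  front <- fit_surface(nodes$front, fit_aperture, order)
  back <- fit_surface(nodes$back, fit_aperture, order)
  if (toric_fans) {
    f1 <- trace_fan(front, back, n_lens, spec$cyl_axis, pupil_semi_aperture)
    f2 <- trace_fan(front, back, n_lens, spec$cyl_axis + 90, pupil_semi_aperture)
    tr <- f1
    tr$power_D <- (f1$power_D + f2$power_D) / 2
    tr$focal_mm <- if (abs(tr$power_D) > 1e-9) 1000 / tr$power_D else Inf
    tr$fans <- list(f1, f2)
    tr$rays <- dplyr::bind_rows(f1$rays, f2$rays)
    tr$n_rays <- f1$n_rays + f2$n_rays
    tr$n_dropped <- f1$n_dropped + f2$n_dropped
  } else {
    tr <- trace_bundle(front, back, n_lens, pupil_semi_aperture, n_rings, keep_events)
  }
  tr$front <- front
  tr$back <- back
  tr
}

#' Effective power change from two traces
#'
#' EPC is the traced power of the conformed lens minus the baseline power —
#' by default the traced power of the undeformed lens under identical pupil
#' and ray settings (isolating the conformance effect); alternatively the
#' labelled (nominal) power.
#'
#' @param traced A `lens_trace` of the conformed lens.
#' @param baseline A `lens_trace` of the undeformed lens, or a number (the
#'   labelled power in D).
#' @return One-row tibble: `power_conformed_D`, `power_baseline_D`,
#'   `epc_D`, `focal_mm`, `spread_mm`, `n_rays`.
#' @export
power_and_epc <- function(traced, baseline) {
  base_p <- if (is.numeric(baseline)) baseline else baseline$power_D
  tibble::tibble(
    power_conformed_D = traced$power_D,
    power_baseline_D = base_p,
    epc_D = traced$power_D - base_p,
    focal_mm = traced$focal_mm,
    spread_mm = traced$spread_mm,
    n_rays = traced$n_rays - traced$n_dropped
  )
}

#' Per-ray diagnostics dump
#'
#' @param trace A `lens_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(trace$rays, path)
  invisible(path)
}
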