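#' Bending stiffness number of a fitted lens
#'
#' Dimensionless ratio of the lens's plate bending stiffness
#' `E t^3 / (12 (1 - nu^2))` to the load-times-span scale `(P1 + P2) a^3`,
#' in the spirit of beam/plate flexure: large S means the lens resists the
#' fitting pressures and keeps its shape, small S means it drapes onto the
#' cornea. The conformance weight is `w = S / (1 + S)`.
#'
#' @param material Anything [get_material()] accepts (`modulus` in MPa,
#'   `poisson` used).
#' @param mean_thickness Mean lens thickness t-bar (mm).
#' @param semi_diameter Lens semi-diameter a (mm).
#' @param loads A [load_case()].
#' @return Stiffness number S (dimensionless; `Inf` when total pressure is
#'   zero).
#' @export
stiffness_number <- function(material, mean_thickness, semi_diameter, loads) {
  mat <- get_material(material)
  if (mean_thickness <= 0 || semi_diameter <= 0) {
    abort("mean thickness and semi-diameter must be positive")
  }
  p_MPa <- (loads$tear_pressure_Pa + loads$eyelid_pressure_Pa) * 1e-6
  if (p_MPa == 0) {
    return(Inf)
  }
  mat$modulus * mean_thickness^3 /
    (12 * (1 - mat$poisson^2) * p_MPa * semi_diameter^3)
}

# Piecewise description of the back meridian as tangent angle vs arc length.
# Each zone arc has constant curvature, so psi(s) is linear per segment
# (with slope jumps at zone joins); the tangential extension has constant
# psi. Returns segment table and the arc length of each radial station.
back_arc_segments <- function(back, X) {
  r <- back$radii
  half <- back$D / 2
  breaks_x <- c(back$d1 / 2, back$d2 / 2, min(back$x_cap, half), half)
  segs <- list()
  s0 <- 0
  # zone arcs: start/end surface angles alpha (psi = -alpha)
  a_prev_end <- 0
  starts_x <- c(0, breaks_x[1], breaks_x[2])
  ends_x <- c(breaks_x[1], breaks_x[2], breaks_x[3])
  radii <- c(r[["r1"]], r[["r2"]], r[["r3"]])
  for (i in 1:3) {
    a0 <- asin(starts_x[i] / radii[i])
    a1 <- asin(ends_x[i] / radii[i])
    len <- radii[i] * (a1 - a0)
    segs[[i]] <- list(
      s0 = s0, s1 = s0 + len, psi0 = -a0, dpsi = -1 / radii[i], x0 = starts_x[i]
    )
    s0 <- s0 + len
  }
  if (back$x_cap < half) {
    len <- (half - back$x_cap) / cos(back$cap_angle)
    segs[[4]] <- list(
      s0 = s0, s1 = s0 + len, psi0 = -back$cap_angle, dpsi = 0, x0 = back$x_cap
    )
    s0 <- s0 + len
  }
  # arc length of each station
  s_of_x <- function(x) {
    out <- numeric(length(x))
    for (k in seq_along(x)) {
      xi <- x[k]
      if (xi <= breaks_x[1]) {
        out[k] <- r[["r1"]] * asin(xi / r[["r1"]])
      } else if (xi <= breaks_x[2]) {
        out[k] <- segs[[2]]$s0 + r[["r2"]] * (asin(xi / r[["r2"]]) - asin(breaks_x[1] / r[["r2"]]))
      } else if (xi <= breaks_x[3] + 1e-12 && xi <= back$x_cap) {
        out[k] <- segs[[3]]$s0 + r[["r3"]] * (asin(min(xi / r[["r3"]], 1)) - asin(breaks_x[2] / r[["r3"]]))
      } else {
        out[k] <- segs[[4]]$s0 + (xi - back$x_cap) / cos(back$cap_angle)
      }
    }
    out
  }
  list(segments = segs, s_total = s0, s_nodes = s_of_x(X))
}

# Integrate a unit-speed plane curve whose tangent angle is piecewise linear
# in arc length: closed-form sine/cosine antiderivatives per segment.
integrate_psi_curve <- function(segments, w, Rc, s_eval) {
  # blended segment coefficients: psi(s) = a_i + b_i (s - s0_i)
  n_seg <- length(segments)
  a <- b <- s0s <- s1s <- numeric(n_seg)
  for (i in seq_len(n_seg)) {
    sg <- segments[[i]]
    a[i] <- w * sg$psi0 + (1 - w) * (-sg$s0 / Rc)
    b[i] <- w * sg$dpsi + (1 - w) * (-1 / Rc)
    s0s[i] <- sg$s0; s1s[i] <- sg$s1
  }
  seg_step <- function(x0, z0, ai, bi, ds) {
    if (abs(bi) < 1e-12) {
      list(x = x0 + cos(ai + bi * ds / 2) * ds, z = z0 + sin(ai + bi * ds / 2) * ds)
    } else {
      list(
        x = x0 + (sin(ai + bi * ds) - sin(ai)) / bi,
        z = z0 - (cos(ai + bi * ds) - cos(ai)) / bi
      )
    }
  }
  # start point of every segment
  xs <- zs <- numeric(n_seg)
  xs[1] <- 0; zs[1] <- 0
  if (n_seg > 1) {
    for (i in seq_len(n_seg - 1)) {
      p <- seg_step(xs[i], zs[i], a[i], b[i], s1s[i] - s0s[i])
      xs[i + 1] <- p$x; zs[i + 1] <- p$z
    }
  }
  idx <- findInterval(s_eval, s0s, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  ds <- s_eval - s0s[idx]
  small <- abs(b[idx]) < 1e-12
  x <- z <- numeric(length(s_eval))
  if (any(small)) {
    i <- which(small)
    x[i] <- xs[idx[i]] + cos(a[idx[i]]) * ds[i]
    z[i] <- zs[idx[i]] + sin(a[idx[i]]) * ds[i]
  }
  if (any(!small)) {
    i <- which(!small)
    bi <- b[idx[i]]; ai <- a[idx[i]]
    x[i] <- xs[idx[i]] + (sin(ai + bi * ds[i]) - sin(ai)) / bi
    z[i] <- zs[idx[i]] - (cos(ai + bi * ds[i]) - cos(ai)) / bi
  }
  list(x = x, z = z, psi = a[idx] + b[idx] * ds)
}

#' Normal thickness map of a lens
#'
#' Distance from each back-surface node along the local back-surface normal
#' to the front surface (per meridian), found by a fixed-point iteration on
#' the interpolated front meridian. This is the thickness that is preserved
#' during conformance; the axial map `Zf - Zb` overstates it where the
#' surface is inclined.
#'
#' @param lens A `lens_geometry`.
#' @return Matrix (meridians x stations) of normal thicknesses (mm).
#' @export
normal_thickness <- function(lens) {
  psi0 <- atan(back_sag_slope(lens$X, lens$back))
  sin0 <- sin(psi0); cos0 <- cos(psi0)
  M <- nrow(lens$Zf)
  half <- lens$spec$diameter / 2
  tn <- matrix(0, M, length(lens$X))
  for (j in seq_len(M)) {
    fz <- stats::splinefun(lens$X, lens$Zf[j, ], method = "fmm")
    t_ax <- lens$thickness[j, ]
    # Newton on g(u) = f(x(u)) - Zb - u cos(psi), x(u) = X - u sin(psi)
    u <- t_ax * cos0
    for (it in 1:12) {
      x_eval <- pmin(pmax(lens$X - u * sin0, 0), half)
      gval <- fz(x_eval) - lens$Zb - u * cos0
      gp <- -fz(x_eval, deriv = 1) * sin0 - cos0
      step <- -gval / gp
      step[!is.finite(step)] <- 0
      u <- pmin(pmax(u + step, 0), 3 * t_ax + 0.5)
    }
    # where the normal exits through the lens edge there is no intersection;
    # fall back to the first-order estimate t_axial * cos(psi)
    x_eval <- lens$X - u * sin0
    res <- abs(fz(pmin(pmax(x_eval, 0), half)) - lens$Zb - u * cos0)
    bad <- !is.finite(u) | res > 1e-8 | x_eval > half | x_eval < 0
    u[bad] <- (t_ax * cos0)[bad]
    tn[j, ] <- u
  }
  tn
}

#' Conform a lens to the corneal model
#'
#' Stiffness-weighted, arc-length-preserving surrogate for the on-eye
#' contact solution. Per meridian the back surface and the corneal sphere
#' are parameterised by arc length from the apex; their tangent angles are
#' blended as `psi = w psi_lens + (1 - w) psi_cornea` with
#' `w = S / (1 + S)` from [stiffness_number()], and the unit-speed curve is
#' re-integrated (in closed form, since both tangent-angle functions are
#' piecewise linear in arc length), which preserves meridional arc length
#' exactly. The front surface follows by offsetting along the local normal
#' by the local (axial) thickness map — thickness is preserved, consistent
#' with near-incompressibility. Nodes that penetrate the cornea are
#' projected radially onto it.
#'
#' @param lens A `lens_geometry` from [build_lens()].
#' @param cornea A [cornea_model()].
#' @param material Anything [get_material()] accepts. `modulus = Inf` gives
#'   the rigid limit (lens unchanged), `modulus = 0` the full drape.
#' @param loads A [load_case()].
#' @param w Optional explicit conformance weight in `[0, 1]`, overriding the
#'   stiffness-derived value.
#' @return A `conformed_lens`: back curve (`s`, `xb`, `zb`, `psi`, shared by
#'   all meridians), front node matrices `xf`, `zf` (meridians x stations),
#'   the weight `w`, stiffness number `S`, and the inputs.
#' @export
conform <- function(lens, cornea, material, loads = load_case(), w = NULL) {
  stopifnot(inherits(lens, "lens_geometry"), inherits(cornea, "cornea_model"))
  mat <- get_material(material)
  if (lens$spec$diameter / 2 > cornea$Rc) {
    abort("lens semi-diameter exceeds the corneal model aperture",
      class = "onlens_geometry_error"
    )
  }
  S <- stiffness_number(mat, mean(lens$thickness), lens$spec$diameter / 2, loads)
  if (is.null(w)) w <- if (is.infinite(S)) 1 else S / (1 + S)
  if (w < 0 || w > 1) abort("conformance weight w must lie in [0, 1]")

  arc <- back_arc_segments(lens$back, lens$X)
  M <- length(lens$meridian_deg)
  if (w == 1) {
    # rigid limit: the lens keeps its shape exactly (no projection — a rigid
    # lens rests on the cornea rather than conforming to it)
    xb <- lens$X; zb <- lens$Zb
    psi <- numeric(length(lens$X))
    for (i in seq_along(arc$segments)) {
      sg <- arc$segments[[i]]
      sel <- arc$s_nodes >= sg$s0 - 1e-12 & arc$s_nodes <= sg$s1 + 1e-12
      psi[sel] <- sg$psi0 + sg$dpsi * (arc$s_nodes[sel] - sg$s0)
    }
    xf <- matrix(lens$X, M, length(lens$X), byrow = TRUE)
    zf <- lens$Zf
  } else {
    cur <- integrate_psi_curve(arc$segments, w, cornea$Rc, arc$s_nodes)
    xb <- cur$x; zb <- cur$z; psi <- cur$psi

    # impenetrability: project nodes inside the corneal sphere back onto it
    rad <- sqrt(xb^2 + (zb + cornea$Rc)^2)
    pen <- rad < cornea$Rc - 1e-12
    if (any(pen)) {
      scale <- cornea$Rc / rad[pen]
      xb[pen] <- xb[pen] * scale
      zb[pen] <- (zb[pen] + cornea$Rc) * scale - cornea$Rc
    }
    if (any(diff(xb) <= 0)) {
      abort("conformed meridian self-intersects (radial coordinate not monotone)",
        class = "onlens_conformance_failure"
      )
    }

    # front surface: transport the *normal* thickness of the original lens
    # (distance from each back node along its normal to the front surface)
    # along the conformed normals; thickness is preserved, and the
    # construction reproduces the original front exactly in the rigid limit
    tn <- normal_thickness(lens)
    sin_psi <- matrix(sin(psi), M, length(psi), byrow = TRUE)
    cos_psi <- matrix(cos(psi), M, length(psi), byrow = TRUE)
    xf <- matrix(xb, M, length(xb), byrow = TRUE) - tn * sin_psi
    zf <- matrix(zb, M, length(zb), byrow = TRUE) + tn * cos_psi
  }

  structure(
    list(
      lens = lens, cornea = cornea, material = mat, loads = loads,
      meridian_deg = lens$meridian_deg,
      s = arc$s_nodes, xb = xb, zb = zb, psi = psi,
      xf = xf, zf = zf, w = w, S = S
    ),
    class = "conformed_lens"
  )
}

#' @export
print.conformed_lens <- function(x, ...) {
  cat(sprintf(
    "<conformed_lens> %s on %.1f D cornea: S = %.3g, w = %.3g, apex clearance %.2g mm\n",
    x$material$material, x$cornea$K, x$S, x$w, sqrt(x$xb[1]^2 + (x$zb[1] + x$cornea$Rc)^2) - x$cornea$Rc
  ))
  invisible(x)
}

#' RMS deviation of the conformed back surface from the cornea
#'
#' @param conf A `conformed_lens`.
#' @return RMS over back nodes of the signed distance to the corneal sphere
#'   (mm).
#' @export
conform_rms_to_cornea <- function(conf) {
  d <- sqrt(conf$xb^2 + (conf$zb + conf$cornea$Rc)^2) - conf$cornea$Rc
  sqrt(mean(d^2))
}

#' Signed clearance of the conformed back surface over the cornea
#'
#' @param conf A `conformed_lens`.
#' @return Numeric vector of per-node signed distances (mm, negative =
#'   penetration).
#' @export
conform_clearance <- function(conf) {
  sqrt(conf$xb^2 + (conf$zb + conf$cornea$Rc)^2) - conf$cornea$Rc
}

#' Chord-sum arc length of a sampled meridian
#'
#' @param x,z Node coordinates along one meridian (mm).
#' @return Total polyline length (mm).
#' @export
meridian_arc_length <- function(x, z) {
  sum(sqrt(diff(x)^2 + diff(z)^2))
}
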