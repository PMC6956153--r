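#' Zernike term index table
#'
#' All disk polynomial terms up to a radial order: `n` radial degree, `m`
#' signed azimuthal frequency (positive = cosine, negative = sine).
#'
#' @param order Maximum radial order.
#' @return Tibble with columns `n`, `m`.
#' @export
zernike_indices <- function(order) {
  out <- list()
  for (n in 0:order) {
    for (m in seq(-n, n, by = 2)) {
      out[[length(out) + 1]] <- c(n, m)
    }
  }
  mat <- do.call(rbind, out)
  tibble::tibble(n = mat[, 1], m = mat[, 2])
}

# radial polynomial coefficients of rho^(n-2k), k = 0..(n-|m|)/2
zernike_radial_coefs <- function(n, m) {
  m <- abs(m)
  k <- 0:((n - m) / 2)
  (-1)^k * factorial(n - k) /
    (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k))
}

# Design matrices of Zernike values and their u/v partial derivatives on the
# unit disk. Azimuthal factors cos(m phi) rho^m and sin(m phi) rho^m are the
# harmonic polynomials Re/Im[(u + i v)^m], built by recursion, so values and
# gradients are polynomial-exact (no trigonometry of atan2).
zernike_design <- function(u, v, order, derivatives = FALSE) {
  idx <- zernike_indices(order)
  npt <- length(u)
  rho2 <- u^2 + v^2
  # harmonic polynomials A_m = Re[(u+iv)^m], B_m = Im[(u+iv)^m]
  A <- list(rep(1, npt)); B <- list(rep(0, npt))
  for (m in seq_len(order)) {
    A[[m + 1]] <- A[[m]] * u - B[[m]] * v
    B[[m + 1]] <- A[[m]] * v + B[[m]] * u
  }
  nt <- nrow(idx)
  Z <- matrix(0, npt, nt)
  Zu <- Zv <- if (derivatives) matrix(0, npt, nt) else NULL
  for (t in seq_len(nt)) {
    n <- idx$n[t]; m <- idx$m[t]; am <- abs(m)
    ck <- zernike_radial_coefs(n, m)
    js <- (n - am - 2 * (seq_along(ck) - 1)) / 2 # powers of rho^2
    radial <- rep(0, npt)
    dradial <- rep(0, npt) # d/d(rho2) of radial part
    for (i in seq_along(ck)) {
      p <- js[i]
      radial <- radial + ck[i] * rho2^p
      if (derivatives && p > 0) dradial <- dradial + ck[i] * p * rho2^(p - 1)
    }
    ang <- if (m >= 0) A[[am + 1]] else B[[am + 1]]
    Z[, t] <- radial * ang
    if (derivatives) {
      if (am == 0) {
        dang_u <- rep(0, npt); dang_v <- rep(0, npt)
      } else if (m >= 0) {
        dang_u <- am * A[[am]]; dang_v <- -am * B[[am]]
      } else {
        dang_u <- am * B[[am]]; dang_v <- am * A[[am]]
      }
      Zu[, t] <- dradial * 2 * u * ang + radial * dang_u
      Zv[, t] <- dradial * 2 * v * ang + radial * dang_v
    }
  }
  list(Z = Z, Zu = Zu, Zv = Zv, indices = idx)
}

#' Fit a smooth optical surface to a lens node cloud
#'
#' Least-squares Zernike (disk polynomial) expansion of the height function
#' `z = f(x, y)` over a circular aperture, giving an analytic gradient for
#' refraction. Nodes outside the aperture are ignored.
#'
#' @param nodes Data frame with columns `x`, `y`, `z` (mm).
#' @param aperture_radius Fit aperture semi-diameter (mm).
#' @param order Maximum radial order (default 8).
#' @return An `optical_surface` with coefficients, the aperture, and the
#'   residual RMS (mm) over the fitted nodes.
#' @export
fit_surface <- function(nodes, aperture_radius, order = 8) {
  stopifnot(all(c("x", "y", "z") %in% names(nodes)))
  r <- sqrt(nodes$x^2 + nodes$y^2)
  keep <- r <= aperture_radius * (1 + 1e-9)
  nodes <- nodes[keep, , drop = FALSE]
  nt <- nrow(zernike_indices(order))
  if (nrow(nodes) < max(100, nt)) {
    abort("too few nodes inside the aperture to fit a surface",
      class = "onlens_fit_error"
    )
  }
  u <- nodes$x / aperture_radius
  v <- nodes$y / aperture_radius
  des <- zernike_design(u, v, order)
  qrd <- qr(des$Z)
  if (qrd$rank < ncol(des$Z)) {
    abort("rank-deficient surface fit (nodes do not span the aperture)",
      class = "onlens_fit_error"
    )
  }
  coefs <- qr.coef(qrd, nodes$z)
  resid <- nodes$z - des$Z %*% coefs
  structure(
    list(
      coef = as.numeric(coefs), order = order, aperture = aperture_radius,
      rms = sqrt(mean(resid^2)), n_nodes = nrow(nodes)
    ),
    class = "optical_surface"
  )
}

#' @export
print.optical_surface <- function(x, ...) {
  cat(sprintf(
    "<optical_surface> order %d over %.2f mm aperture, %d nodes, residual RMS %.2e mm\n",
    x$order, x$aperture, x$n_nodes, x$rms
  ))
  invisible(x)
}

#' Evaluate a fitted surface
#'
#' @param surface An `optical_surface`.
#' @param x,y Coordinates (mm).
#' @return `surface_height()`: heights z (mm). `surface_gradient()`: list
#'   with `fx`, `fy`.
#' @export
surface_height <- function(surface, x, y) {
  des <- zernike_design(x / surface$aperture, y / surface$aperture, surface$order)
  as.numeric(des$Z %*% surface$coef)
}

#' @rdname surface_height
#' @export
surface_gradient <- function(surface, x, y) {
  des <- zernike_design(x / surface$aperture, y / surface$aperture,
    surface$order,
    derivatives = TRUE
  )
  list(
    fx = as.numeric(des$Zu %*% surface$coef) / surface$aperture,
    fy = as.numeric(des$Zv %*% surface$coef) / surface$aperture
  )
}

#' Unit normal of the implicit surface F(x, y, z) = f(x, y) - z
#'
#' `N = grad F / |grad F| = (fx, fy, -1) / norm`; the z component is never
#' zero, so the normal is always defined.
#'
#' @inheritParams surface_height
#' @return Matrix with one row per point, columns `nx`, `ny`, `nz`.
#' @export
surface_normal <- function(surface, x, y) {
  g <- surface_gradient(surface, x, y)
  nrm <- sqrt(g$fx^2 + g$fy^2 + 1)
  cbind(nx = g$fx / nrm, ny = g$fy / nrm, nz = -1 / nrm)
}

#' Export surface coefficients as JSON
#'
#' @param surface An `optical_surface`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface_json <- function(surface, path) {
  idx <- zernike_indices(surface$order)
  jsonlite::write_json(
    list(
      order = surface$order, aperture_mm = surface$aperture,
      rms_mm = surface$rms,
      terms = tibble::tibble(n = idx$n, m = idx$m, coef = surface$coef)
    ),
    path,
    digits = NA, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
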