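# low-resolution lens spec for fast unit tests; acceptance tests use the
# full default resolution
tiny_spec <- function(sph = 0, cyl = 0, diameter = 14, n_meridians = 48,
                      n_radial = 61, ...) {
  lens_spec(
    diameter = diameter, sph = sph, cyl = cyl,
    n_meridians = n_meridians, n_radial = n_radial, ...
  )
}

rigid_material <- function() {
  list(
    material = "rigid", modulus = Inf, modulus_sd = NA_real_, poisson = 0.49,
    refractive_index = 1.3739, water_content = NA_real_, modulus_source = "custom"
  )
}

# independent closed-form vector Snell refraction used as the oracle for
# the package's rotation-based construction
oracle_vector_snell <- function(d, n_surf, n_in, n_out) {
  n_o <- if (sum(d * n_surf) > 0) -n_surf else n_surf
  eta <- n_in / n_out
  cos_in <- -sum(d * n_o)
  sin2_out <- eta^2 * (1 - cos_in^2)
  eta * d + (eta * cos_in - sqrt(1 - sin2_out)) * n_o
}
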