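#' Rigid spherical corneal model
#'
#' The anterior eye is modelled as a rigid sphere whose front radius follows
#' the keratometric conversion `Rc = 337.5 / K`, with a constant corneal
#' thickness carried only for finite-element export (the conformance
#' surrogate uses the front surface alone).
#'
#' @param K Keratometric curvature (D); 43.7 D is the population-average
#'   value the lens designs are fitted to.
#' @param thickness_um Corneal thickness (micrometres) between the two
#'   parallel model surfaces.
#' @return A `cornea_model` list with `K`, `Rc` (mm), `thickness_um`,
#'   `rigid = TRUE`.
#' @export
cornea_model <- function(K = 43.7, thickness_um = 545) {
  if (K <= 0) abort("corneal curvature must be positive")
  structure(
    list(K = K, Rc = KERATOMETRIC_CONSTANT / K, thickness_um = thickness_um, rigid = TRUE),
    class = "cornea_model"
  )
}

#' Corneal sagittal height in the lens frame
#'
#' Spherical sag of radius Rc, apex aligned with the lens back apex,
#' anterior-positive z (values <= 0).
#'
#' @param X Radial distances from the apex (mm), `X <= Rc`.
#' @param cornea A [cornea_model()].
#' @return Sag (mm).
#' @export
cornea_sag <- function(X, cornea) {
  if (any(X > cornea$Rc)) {
    abort("X beyond the corneal radius", class = "onlens_out_of_range")
  }
  -(cornea$Rc - sqrt(cornea$Rc^2 - X^2))
}

#' On-eye load case
#'
#' The two uniform pressures acting on the fitted lens: the tear-film
#' surface-tension pressure P1 (applied between lens back and cornea front)
#' and the eyelid pressure P2 (applied to the lens front). Friction is
#' recorded for finite-element export; the conformance surrogate is
#' frictionless.
#'
#' @param tear_pressure_Pa P1 in pascals (default 0.0436 Pa = 43.6 mPa).
#' @param eyelid_pressure_mmHg P2 in mmHg (default 8.0 mmHg = 1066.58 Pa).
#' @param friction Contact friction coefficient.
#' @return A `load_case` list with `tear_pressure_Pa`, `eyelid_pressure_Pa`,
#'   `eyelid_pressure_mmHg`, `friction`.
#' @export
load_case <- function(tear_pressure_Pa = 0.0436, eyelid_pressure_mmHg = 8.0,
                      friction = 0.01) {
  if (tear_pressure_Pa < 0 || eyelid_pressure_mmHg < 0 || friction < 0) {
    abort("load case values must be non-negative")
  }
  structure(
    list(
      tear_pressure_Pa = tear_pressure_Pa,
      eyelid_pressure_mmHg = eyelid_pressure_mmHg,
      eyelid_pressure_Pa = eyelid_pressure_mmHg * PA_PER_MMHG,
      friction = friction
    ),
    class = "load_case"
  )
}
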