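#' Describe a rectangular tensile strip
#'
#' Hydrogel strips are lathed to a nominal 0.55 mm thickness and cut from
#' hydrated discs; the initial cross-section `A0 = width * thickness` turns
#' recorded forces into engineering stresses.
#'
#' @param length_mm Initial gauge length L0 (mm).
#' @param width_mm Strip width (mm). The strip width is a fixture free
#'   parameter, not a reported value; 5 mm is a realistic cut width.
#' @param thickness_mm Strip thickness (mm).
#' @return A `tensile_sample` list with `L0`, `width`, `thickness`, `A0`.
#' @export
tensile_sample <- function(length_mm = 20, width_mm = 5, thickness_mm = 0.55) {
  if (!all(is.finite(c(length_mm, width_mm, thickness_mm))) ||
      any(c(length_mm, width_mm, thickness_mm) <= 0)) {
    abort("tensile sample dimensions must all be positive", class = "onlens_invalid_sample")
  }
  structure(
    list(
      L0 = length_mm, width = width_mm, thickness = thickness_mm,
      A0 = width_mm * thickness_mm
    ),
    class = "tensile_sample"
  )
}

check_records <- function(records) {
  needed <- c("time_s", "force_N", "length_mm")
  if (!all(needed %in% names(records))) {
    abort(paste0(
      "tensile records need columns ", paste(needed, collapse = ", ")
    ))
  }
  records
}

#' Engineering stress from recorded forces
#'
#' Divides each recorded force by the strip's initial cross-section area,
#' giving engineering (not true) stress in MPa (N/mm^2).
#'
#' @param records Tibble of tensile records with columns `time_s`, `force_N`,
#'   `length_mm`.
#' @param sample A [tensile_sample()].
#' @return `records` with a `stress_MPa` column appended.
#' @export
compute_stress <- function(records, sample) {
  check_records(records)
  if (!inherits(sample, "tensile_sample") || !is.finite(sample$A0) || sample$A0 <= 0) {
    abort("sample cross-section A0 must be positive", class = "onlens_invalid_sample")
  }
  dplyr::mutate(tibble::as_tibble(records), stress_MPa = .data$force_N / sample$A0)
}

#' Engineering strain from recorded lengths
#'
#' Strain is the length change over the initial gauge length,
#' `(L1 - L0) / L0` (dimensionless engineering strain).
#'
#' @inheritParams compute_stress
#' @return `records` with a `strain` column appended.
#' @export
compute_strain <- function(records, sample) {
  check_records(records)
  if (!inherits(sample, "tensile_sample") || sample$L0 <= 0) {
    abort("sample gauge length L0 must be positive", class = "onlens_invalid_sample")
  }
  dplyr::mutate(tibble::as_tibble(records), strain = (.data$length_mm - sample$L0) / sample$L0)
}

#' Stress-strain curve from raw tensile records
#'
#' @inheritParams compute_stress
#' @return A tibble with ascending `strain` and `stress_MPa`.
#' @export
tensile_curve <- function(records, sample) {
  out <- compute_strain(compute_stress(records, sample), sample)
  out <- dplyr::arrange(out, .data$strain)
  dplyr::select(out, "strain", "stress_MPa")
}

#' Fit the elastic modulus as the stress-strain gradient
#'
#' Ordinary least squares of stress on strain over the supplied (optionally
#' windowed) curve; the slope is the elastic modulus E in MPa. Hydrogels are
#' close to linear over in-vivo load ranges, so the default uses every point.
#'
#' @param curve Tibble with `strain` and `stress_MPa` columns (see
#'   [tensile_curve()]).
#' @param strain_window Optional `c(min, max)` strain window restricting the
#'   fit.
#' @return A `modulus_fit` object; see [tidy()] and [glance()] methods.
#' @export
fit_modulus <- function(curve, strain_window = NULL) {
  if (!all(c("strain", "stress_MPa") %in% names(curve))) {
    abort("curve needs 'strain' and 'stress_MPa' columns")
  }
  if (!is.null(strain_window)) {
    curve <- dplyr::filter(
      curve,
      .data$strain >= strain_window[1], .data$strain <= strain_window[2]
    )
  }
  if (nrow(curve) < 2 || length(unique(curve$strain)) < 2) {
    abort("need at least two distinct strain values to fit a modulus",
      class = "onlens_fit_error"
    )
  }
  fit <- lm(stress_MPa ~ strain, data = curve)
  # summary.lm warns on numerically perfect fits; those are a legitimate
  # input here (noise-free synthetic data)
  sm_all <- suppressWarnings(summary(fit))
  sm <- sm_all$coefficients
  structure(
    list(
      modulus = unname(coef(fit)[["strain"]]),
      se = unname(sm["strain", "Std. Error"]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      intercept_se = unname(sm["(Intercept)", "Std. Error"]),
      r_squared = sm_all$r.squared,
      n = nrow(curve),
      fit = fit
    ),
    class = "modulus_fit"
  )
}

#' @export
print.modulus_fit <- function(x, ...) {
  cat(sprintf(
    "<modulus_fit> E = %.4g MPa (SE %.3g), intercept %.3g MPa, n = %d\n",
    x$modulus, x$se, x$intercept, x$n
  ))
  invisible(x)
}

#' @export
tidy.modulus_fit <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("intercept_MPa", "modulus_MPa"),
    estimate = c(x$intercept, x$modulus),
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' @export
glance.modulus_fit <- function(x, ...) {
  tibble::tibble(
    modulus_MPa = x$modulus, se_MPa = x$se, intercept_MPa = x$intercept,
    r.squared = x$r_squared, n = x$n
  )
}

#' Average per-strip moduli into a material value
#'
#' Materials are characterised by testing several strips and averaging the
#' per-strip gradients; the spread across strips is reported as an SD,
#' matching the usual "mean +/- SD" presentation.
#'
#' @param fits List of `modulus_fit` objects (one per strip).
#' @return One-row tibble with `modulus_MPa`, `sd_MPa`, `n_samples`.
#' @export
average_modulus <- function(fits) {
  e <- vapply(fits, function(f) f$modulus, numeric(1))
  tibble::tibble(
    modulus_MPa = mean(e),
    sd_MPa = if (length(e) > 1) sd(e) else NA_real_,
    n_samples = length(e)
  )
}

#' Generate synthetic force-extension records
#'
#' Emulates a constant-strain-rate (10% per minute) uniaxial test of a
#' linear-elastic strip: stress follows `E * strain` plus optional additive
#' Gaussian noise, inverted to forces through the initial cross-section and
#' to instantaneous lengths through the gauge length.
#'
#' @param material Anything [get_material()] accepts; its `modulus` is the
#'   generating E (MPa).
#' @param sample A [tensile_sample()].
#' @param n_points Number of records.
#' @param strain_max Final strain (default 0.10, the in-vivo-scale range the
#'   modulus is fitted over).
#' @param strain_rate Strain per second (default 10% per minute).
#' @param noise_sd Additive stress noise SD in MPa (0 = noise-free).
#' @param seed Optional integer seed for reproducible noise.
#' @return Tibble of records: `time_s`, `force_N`, `length_mm`.
#' @export
synth_tensile <- function(material, sample = tensile_sample(), n_points = 200,
                          strain_max = 0.10, strain_rate = 0.10 / 60,
                          noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  mat <- get_material(material)
  strain <- seq(0, strain_max, length.out = n_points)
  stress <- mat$modulus * strain
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
      on.exit(
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
        add = TRUE
      )
      set.seed(seed)
    }
    stress <- stress + stats::rnorm(n_points, sd = noise_sd)
  }
  tibble::tibble(
    time_s = strain / strain_rate,
    force_N = stress * sample$A0,
    length_mm = sample$L0 * (1 + strain)
  )
}

#' Read / write tensile record CSV files
#'
#' Plain CSV with header columns `time_s`, `force_N`, `length_mm`.
#'
#' @param path File path.
#' @return `read_tensile_csv()` returns a record tibble; `write_tensile_csv()`
#'   returns `path` invisibly.
#' @export
read_tensile_csv <- function(path) {
  check_records(readr::read_csv(path, show_col_types = FALSE))
}

#' @param records Record tibble (columns `time_s`, `force_N`, `length_mm`).
#' @rdname read_tensile_csv
#' @export
write_tensile_csv <- function(records, path) {
  readr::write_csv(check_records(records)[, c("time_s", "force_N", "length_mm")], path)
  invisible(path)
}

#' One-call modulus recovery from records
#'
#' Convenience composition of [compute_stress()], [compute_strain()] and
#' [fit_modulus()].
#'
#' @inheritParams compute_stress
#' @inheritParams fit_modulus
#' @return A `modulus_fit`.
#' @export
modulus_from_records <- function(records, sample, strain_window = NULL) {
  fit_modulus(tensile_curve(records, sample), strain_window = strain_window)
}
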