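#' Built-in hydrogel material catalogue
#'
#' The four lens materials carried by the package: a 77% water-content clear
#' hydrogel, blue and clear 74.5% silicone hydrogels, and a 64% clear
#' hydrogel. Each entry holds both the manufacturer-quoted tensile modulus
#' and the modulus measured under in-vivo-scale loads, the wet refractive
#' index, and the Poisson ratio (0.49, near-incompressible) used in the
#' conformance model. Simulations default to the measured modulus.
#'
#' @return A tibble with one row per material and columns `material`, `base`,
#'   `water_content` (%), `refractive_index` (wet), `modulus_measured` (MPa),
#'   `modulus_measured_sd` (MPa, spread across the three tested strips),
#'   `modulus_manufacturer` (MPa) and `poisson`.
#' @export
#' @examples
#' hydrogel_materials()
hydrogel_materials <- function() {
  tibble::tibble(
    material = c("H77p0-Clear", "SiH74p5-Blue", "SiH74p5-Clear", "H64p0-Clear"),
    base = c("hydrogel", "silicone hydrogel", "silicone hydrogel", "hydrogel"),
    water_content = c(77, 74.5, 74.5, 64),
    refractive_index = c(1.3739, 1.3753, 1.3749, 1.3920),
    modulus_measured = c(0.195, 0.277, 0.279, 0.457),
    modulus_measured_sd = c(0.027, 0.019, 0.010, 0.013),
    modulus_manufacturer = c(0.17, 0.35, 0.35, 0.37),
    poisson = 0.49
  )
}

#' Look up one material from the catalogue
#'
#' @param material Material name (prefix match against the catalogue is
#'   accepted, e.g. `"H77p0"`), or a list already carrying `modulus`,
#'   `poisson` and `refractive_index` (returned unchanged), or a single
#'   number interpreted as a modulus in MPa with catalogue-default
#'   `poisson = 0.49` and index 1.3739.
#' @param modulus_source `"measured"` (default) or `"manufacturer"`: which
#'   modulus column becomes the active `modulus`.
#' @return A list with fields `material`, `modulus` (MPa), `modulus_sd`,
#'   `poisson`, `refractive_index`, `water_content`, `modulus_source`.
#' @export
get_material <- function(material, modulus_source = c("measured", "manufacturer")) {
  modulus_source <- match.arg(modulus_source)
  if (is.list(material) && !is.null(material$modulus)) {
    return(material)
  }
  if (is.numeric(material)) {
    return(list(
      material = sprintf("custom-E%.3g", material), modulus = material,
      modulus_sd = NA_real_, poisson = 0.49, refractive_index = 1.3739,
      water_content = NA_real_, modulus_source = "custom"
    ))
  }
  cat_tbl <- hydrogel_materials()
  hit <- which(startsWith(tolower(cat_tbl$material), tolower(material)))
  if (length(hit) != 1) {
    abort(paste0(
      "material '", material, "' does not match exactly one catalogue entry; ",
      "known: ", paste(cat_tbl$material, collapse = ", ")
    ))
  }
  row <- cat_tbl[hit, ]
  list(
    material = row$material,
    modulus = if (modulus_source == "measured") row$modulus_measured else row$modulus_manufacturer,
    modulus_sd = if (modulus_source == "measured") row$modulus_measured_sd else NA_real_,
    poisson = row$poisson,
    refractive_index = row$refractive_index,
    water_content = row$water_content,
    modulus_source = modulus_source
  )
}

#' Export the material catalogue
#'
#' @param path Output file; format from extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_materials <- function(path) {
  tbl <- hydrogel_materials()
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tbl, path, digits = NA, pretty = TRUE)
  } else {
    readr::write_csv(tbl, path)
  }
  invisible(path)
}
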