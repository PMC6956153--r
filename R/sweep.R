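#' Configuration for a factorial EPC sweep
#'
#' @param materials Character vector of catalogue material names.
#' @param types Lens types: `"spherical"` (power in SPH) and/or
#'   `"cylindrical"` (power in CYL at the given axis, SPH = 0).
#' @param powers Power grid (D).
#' @param diameters Lens diameters (mm).
#' @param cornea_K Corneal curvature (D).
#' @param loads A [load_case()].
#' @param pupil_semi_aperture,n_rings Ray bundle settings.
#' @param fit_order Zernike radial order for surface fits.
#' @param n_meridians,n_radial Lens grid resolution.
#' @param ballast Apply the prism ballast during lens build.
#' @param modulus_source `"measured"` or `"manufacturer"` moduli.
#' @param baseline `"traced"` (undeformed lens traced identically; default)
#'   or `"labelled"` (nominal power) as the EPC reference.
#' @param cyl_axis Cylinder axis (deg) for cylindrical sweeps.
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(materials = hydrogel_materials()$material,
                         types = c("spherical", "cylindrical"),
                         powers = seq(-10, 20, by = 1),
                         diameters = c(13.5, 14.0, 14.5),
                         cornea_K = 43.7,
                         loads = load_case(),
                         pupil_semi_aperture = 1.5, n_rings = 6,
                         fit_order = 8,
                         n_meridians = 360, n_radial = 101,
                         ballast = FALSE,
                         modulus_source = "measured",
                         baseline = "traced",
                         cyl_axis = 90) {
  types <- match.arg(types, c("spherical", "cylindrical"), several.ok = TRUE)
  structure(
    list(
      materials = materials, types = types, powers = powers,
      diameters = diameters, cornea_K = cornea_K, loads = loads,
      pupil_semi_aperture = pupil_semi_aperture, n_rings = n_rings,
      fit_order = fit_order, n_meridians = n_meridians, n_radial = n_radial,
      ballast = ballast, modulus_source = modulus_source,
      baseline = baseline, cyl_axis = cyl_axis
    ),
    class = "sweep_config"
  )
}

#' Read a sweep configuration from YAML
#'
#' Top-level keys mirror the [sweep_config()] arguments; `loads` may be a
#' mapping with `tear_pressure_Pa`, `eyelid_pressure_mmHg`, `friction`.
#'
#' @param path YAML file path.
#' @return A `sweep_config`.
#' @export
read_sweep_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$loads)) y$loads <- do.call(load_case, y$loads)
  do.call(sweep_config, y)
}

#' Simulate the EPC of a single (material, power, type, diameter) cell
#'
#' The full chain for one lens: build the tri-curve geometry with the
#' material's refractive index, conform it to the cornea under the load
#' case, trace the conformed and undeformed lenses with identical settings,
#' and difference the traced powers.
#'
#' @param material Catalogue material name (or [get_material()] input).
#' @param power Lens power (D): SPH for spherical, CYL for cylindrical.
#' @param type `"spherical"` or `"cylindrical"`.
#' @param diameter Lens diameter (mm).
#' @param cornea A [cornea_model()].
#' @param loads A [load_case()].
#' @param config Optional `sweep_config` supplying the remaining settings.
#' @return One-row tibble with the cell labels, `epc_D`, traced powers,
#'   conformance weight `w` and stiffness number `S`.
#' @export
simulate_epc <- function(material, power, type = c("spherical", "cylindrical"),
                         diameter = 14, cornea = cornea_model(),
                         loads = load_case(), config = sweep_config()) {
  type <- match.arg(type)
  mat <- get_material(material, config$modulus_source)
  spec <- lens_spec(
    diameter = diameter,
    sph = if (type == "spherical") power else 0,
    cyl = if (type == "cylindrical") power else 0,
    cyl_axis = config$cyl_axis,
    index = mat$refractive_index,
    n_meridians = config$n_meridians, n_radial = config$n_radial,
    ballast = config$ballast
  )
  geom <- build_lens(spec)
  conf <- conform(geom, cornea, mat, loads)
  fans <- type == "cylindrical"
  tr_base <- trace_lens(geom,
    pupil_semi_aperture = config$pupil_semi_aperture,
    n_rings = config$n_rings, order = config$fit_order, toric_fans = fans
  )
  tr_conf <- trace_lens(conf,
    pupil_semi_aperture = config$pupil_semi_aperture,
    n_rings = config$n_rings, order = config$fit_order, toric_fans = fans
  )
  base <- if (identical(config$baseline, "labelled")) power else tr_base
  res <- power_and_epc(tr_conf, base)
  tibble::tibble(
    material = mat$material, type = type, diameter = diameter, power = power,
    epc_D = res$epc_D,
    power_conformed_D = res$power_conformed_D,
    power_baseline_D = res$power_baseline_D,
    w = conf$w, S = conf$S,
    tc_final = geom$Tc_final
  )
}

#' Run the factorial EPC sweep
#'
#' Iterates [simulate_epc()] over the full material x type x diameter x
#' power grid of the configuration. Cell failures are recorded (with the
#' condition message) rather than fatal; the sweep aborts only if every
#' cell fails. The sweep is deterministic: identical configurations give
#' identical tables.
#'
#' @param config A [sweep_config()].
#' @param progress Emit a message per completed grid slice.
#' @return An `epc_table` tibble in long format with one row per cell and a
#'   `within_acceptable` flag (`|EPC| <= 0.25` D).
#' @export
run_sweep <- function(config = sweep_config(), progress = FALSE) {
  cornea <- cornea_model(config$cornea_K)
  grid <- tidyr::expand_grid(
    material = config$materials, type = config$types,
    diameter = config$diameters, power = config$powers
  )
  rows <- purrr::pmap(grid, function(material, type, diameter, power) {
    out <- tryCatch(
      simulate_epc(material, power, type, diameter, cornea, config$loads, config),
      error = function(e) {
        tibble::tibble(
          material = material, type = type, diameter = diameter, power = power,
          epc_D = NA_real_, power_conformed_D = NA_real_,
          power_baseline_D = NA_real_, w = NA_real_, S = NA_real_,
          tc_final = NA_real_, error = conditionMessage(e)
        )
      }
    )
    if (progress) {
      message(sprintf(
        "%s %s D=%.1f P=%+g -> EPC %s",
        material, type, diameter, power,
        if (is.na(out$epc_D[1])) "failed" else sprintf("%.4f D", out$epc_D[1])
      ))
    }
    out
  })
  tbl <- dplyr::bind_rows(rows)
  if (!"error" %in% names(tbl)) tbl$error <- NA_character_
  if (all(!is.na(tbl$error))) {
    abort(paste0(
      "all sweep cells failed; first error: ", tbl$error[1]
    ))
  }
  tbl <- acceptability(tbl)
  class(tbl) <- c("epc_table", class(tbl))
  tbl
}

#' Split an EPC table at the 5 D region boundary
#'
#' EPC behaves differently below and above 5 D; analyses are run per
#' region, with the boundary power assigned to the upper region.
#'
#' @param table An `epc_table` (or any tibble with a `power` column).
#' @param threshold Region boundary (D).
#' @return Named list `lower` (`power < threshold`) and `upper`
#'   (`power >= threshold`).
#' @export
region_split <- function(table, threshold = 5) {
  list(
    lower = dplyr::filter(table, .data$power < threshold),
    upper = dplyr::filter(table, .data$power >= threshold)
  )
}

# pooled-variance two-sample t-test, kept as an explicit formula so the
# degenerate zero-variance case can be handled by its limit
pooled_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) abort("need >= 2 observations per group")
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  df <- nx + ny - 2
  if (sp2 <= 0) {
    # limit: identical constants -> indistinguishable; separated constants -> certain
    p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    return(list(t = if (p == 1) 0 else Inf * sign(mean(x) - mean(y)), df = df, p = p, degenerate = TRUE))
  }
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df), degenerate = FALSE)
}

#' Pairwise material t-tests on EPC values
#'
#' Pooled-variance two-sample t-tests comparing the EPC values of every
#' material pair, separately per lens type and diameter (EPC values pooled
#' over the powers present in the table — split regions first with
#' [region_split()]). Welch's correction is available via `welch = TRUE`.
#' No multiple-testing correction is applied.
#'
#' @param table An `epc_table` (sub)table.
#' @param alpha Significance level for the `significant` flag.
#' @param welch Use Welch's unequal-variance test instead of the pooled
#'   test.
#' @return Long tibble: `type`, `diameter`, `material_1`, `material_2`,
#'   `t`, `df`, `p_value`, `significant`, `degenerate`.
#' @export
pairwise_ttests <- function(table, alpha = 0.05, welch = FALSE) {
  table <- dplyr::filter(table, !is.na(.data$epc_D))
  combos <- dplyr::distinct(table, .data$type, .data$diameter)
  out <- purrr::pmap(combos, function(type, diameter) {
    sub <- table[table$type == type & table$diameter == diameter, ]
    mats <- unique(sub$material)
    if (length(mats) < 2) return(NULL)
    pairs <- utils::combn(mats, 2, simplify = FALSE)
    purrr::map(pairs, function(pr) {
      x <- sub$epc_D[sub$material == pr[1]]
      y <- sub$epc_D[sub$material == pr[2]]
      res <- if (welch) {
        tt <- stats::t.test(x, y, var.equal = FALSE)
        list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE)
      } else {
        pooled_t_test(x, y)
      }
      tibble::tibble(
        type = type, diameter = diameter,
        material_1 = pr[1], material_2 = pr[2],
        t = res$t, df = res$df, p_value = res$p,
        significant = res$p <= alpha, degenerate = res$degenerate
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(out)
}

#' Pearson correlation of EPC with lens power
#'
#' Per (material, type, diameter) Pearson r of EPC against power over the
#' supplied (sub)table. A zero-variance EPC gives a missing value, not 0.
#'
#' @param table An `epc_table` (sub)table.
#' @return Tibble `material`, `type`, `diameter`, `r`, `n`.
#' @export
correlations <- function(table) {
  table <- dplyr::filter(table, !is.na(.data$epc_D))
  out <- table |>
    dplyr::group_by(.data$material, .data$type, .data$diameter) |>
    dplyr::summarise(
      r = {
        if (dplyr::n() < 3 || sd(.data$epc_D) == 0 || sd(.data$power) == 0) {
          NA_real_
        } else {
          cor(.data$power, .data$epc_D)
        }
      },
      n = dplyr::n(),
      .groups = "drop"
    )
  out
}

#' Flag clinically acceptable EPC values
#'
#' A cell is acceptable when `|EPC| <= 0.25` D — the trial-lens increment
#' used in clinical fitting (boundary inclusive).
#'
#' @param table An EPC tibble.
#' @param threshold Acceptability bound (D).
#' @return The table with a logical `within_acceptable` column.
#' @export
acceptability <- function(table, threshold = 0.25) {
  dplyr::mutate(table, within_acceptable = abs(.data$epc_D) <= threshold)
}

#' Largest contiguous acceptable power interval per material
#'
#' @param table An `epc_table` with `within_acceptable` set.
#' @return Tibble `material`, `type`, `diameter`, `power_from`, `power_to`,
#'   `n_powers` describing the longest contiguous run of acceptable powers.
#' @export
acceptable_range <- function(table) {
  tbl <- dplyr::filter(table, !is.na(.data$epc_D))
  groups <- dplyr::group_split(
    dplyr::group_by(tbl, .data$material, .data$type, .data$diameter)
  )
  purrr::map_dfr(groups, function(g) {
    g <- dplyr::arrange(g, .data$power)
    head_cols <- tibble::tibble(
      material = g$material[1], type = g$type[1], diameter = g$diameter[1]
    )
    ok <- g$within_acceptable
    if (!any(ok)) {
      return(dplyr::bind_cols(head_cols, tibble::tibble(
        power_from = NA_real_, power_to = NA_real_, n_powers = 0L
      )))
    }
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    best <- which(runs$values)[which.max(runs$lengths[runs$values])]
    dplyr::bind_cols(head_cols, tibble::tibble(
      power_from = g$power[starts[best]],
      power_to = g$power[ends[best]],
      n_powers = runs$lengths[best]
    ))
  })
}

#' Write sweep outputs to a directory
#'
#' Emits the long EPC table, region-wise pairwise t-tests, region-wise
#' correlations (all CSV), an EPC-versus-power figure per lens type, and
#' the run configuration as YAML. Re-running with the same table and
#' configuration reproduces identical CSVs.
#'
#' @param table An `epc_table` from [run_sweep()].
#' @param outdir Output directory (created if missing).
#' @param config The `sweep_config` used (stored alongside, optional).
#' @return Invisible character vector of the files written.
#' @export
report <- function(table, outdir, config = NULL) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- character()
  p <- file.path(outdir, "epc.csv")
  readr::write_csv(dplyr::select(table, -dplyr::any_of("error")), p)
  files <- c(files, p)
  regions <- region_split(table)
  stats_tt <- dplyr::bind_rows(
    dplyr::mutate(pairwise_ttests(regions$lower), region = "power < 5 D"),
    dplyr::mutate(pairwise_ttests(regions$upper), region = "power >= 5 D")
  )
  p <- file.path(outdir, "ttests.csv")
  readr::write_csv(stats_tt, p)
  files <- c(files, p)
  stats_r <- dplyr::bind_rows(
    dplyr::mutate(correlations(regions$lower), region = "power < 5 D"),
    dplyr::mutate(correlations(regions$upper), region = "power >= 5 D")
  )
  p <- file.path(outdir, "correlations.csv")
  readr::write_csv(stats_r, p)
  files <- c(files, p)
  for (ty in unique(table$type)) {
    p <- file.path(outdir, paste0("epc_", ty, ".png"))
    gg <- autoplot.epc_table(dplyr::filter(table, .data$type == ty))
    ggplot2::ggsave(p, gg, width = 9, height = 4, dpi = 150)
    files <- c(files, p)
  }
  if (!is.null(config)) {
    p <- file.path(outdir, "config.yaml")
    cfg <- config
    cfg$loads <- unclass(cfg$loads)
    yaml::write_yaml(unclass(cfg), p)
    files <- c(files, p)
  }
  # note: no multiple-testing correction is applied to the t-tests
  invisible(files)
}
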