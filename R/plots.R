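#' Plot EPC against lens power
#'
#' One line per material, faceted by diameter (and by lens type if several
#' are present), with the clinically acceptable band |EPC| <= 0.25 D shown
#' as dashed guides.
#'
#' @param object An `epc_table` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epc_table <- function(object, ...) {
  tbl <- dplyr::filter(object, !is.na(.data$epc_D))
  gg <- ggplot2::ggplot(tbl, ggplot2::aes(
    x = .data$power, y = .data$epc_D, colour = .data$material
  )) +
    ggplot2::geom_hline(yintercept = c(-0.25, 0.25), linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "Lens power (D)", y = "Effective power change (D)",
      colour = "Material"
    ) +
    ggplot2::theme_minimal()
  if (length(unique(tbl$type)) > 1) {
    gg + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$type),
      cols = ggplot2::vars(.data$diameter), labeller = ggplot2::label_both
    )
  } else {
    gg + ggplot2::facet_wrap(ggplot2::vars(.data$diameter), labeller = ggplot2::label_both)
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a meridian power profile
#'
#' @param profile Output of [power_profile()].
#' @return A ggplot object.
#' @export
plot_power_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$meridian_deg, y = .data$power_D)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Meridian angle (deg)", y = "Meridian power (D)") +
    ggplot2::theme_minimal()
}

#' Plot lens cross-section meridians
#'
#' Back and front surface heights along one meridian (and, for a conformed
#' lens, the corneal surface).
#'
#' @param obj A `lens_geometry` or `conformed_lens`.
#' @param meridian_deg Meridian to draw (nearest grid meridian is used).
#' @return A ggplot object.
#' @export
plot_meridian <- function(obj, meridian_deg = 0) {
  if (inherits(obj, "conformed_lens")) {
    j <- which.min(abs(obj$meridian_deg - meridian_deg))
    df <- dplyr::bind_rows(
      tibble::tibble(x = obj$xb, z = obj$zb, surface = "back (conformed)"),
      tibble::tibble(x = obj$xf[j, ], z = obj$zf[j, ], surface = "front (conformed)"),
      tibble::tibble(
        x = obj$lens$X, z = cornea_sag(obj$lens$X, obj$cornea), surface = "cornea"
      )
    )
  } else {
    j <- which.min(abs(obj$meridian_deg - meridian_deg))
    df <- dplyr::bind_rows(
      tibble::tibble(x = obj$X, z = obj$Zb, surface = "back"),
      tibble::tibble(x = obj$X, z = obj$Zf[j, ], surface = "front")
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z, colour = .data$surface)) +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "X (mm)", y = "z (mm)", colour = NULL) +
    ggplot2::theme_minimal()
}
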