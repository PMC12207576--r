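# ggplot2 quick-look plots for the result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_col geom_point geom_tile
#'   geom_vline geom_hline labs facet_wrap scale_fill_viridis_c theme_minimal
NULL

#' Plot a density profile
#' @param object A `density_profile`.
#' @param regions Optional [region_spec()] whose boundaries are drawn.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.density_profile <- function(object, regions = NULL, ...) {
  g <- ggplot(as_tibble(object), aes(x = .data$z, y = .data$density)) +
    geom_line() +
    labs(x = "z, distance from silica surface (nm)",
         y = expression(rho ~ (nm^-3)),
         title = paste0("Density profile: ", attr(object, "species"))) +
    theme_minimal()
  if (!is.null(regions)) {
    g <- g + geom_vline(xintercept = c(regions$z_bp_end,
                                       regions$z_bulk_start),
                        linetype = "dashed", colour = "grey50")
    if (!is.na(regions$z_sp)) {
      g <- g + geom_vline(xintercept = regions$z_sp, colour = "firebrick",
                          linetype = "dotted")
    }
  }
  g
}

#' Plot a bonded-phase contact profile
#' @param object A `contact_profile`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.contact_profile <- function(object, ...) {
  ggplot(as_tibble(object) |> filter(!is.na(.data$c_bp)),
         aes(x = .data$z, y = .data$c_bp)) +
    geom_line() + geom_point(size = 0.6) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "firebrick") +
    labs(x = "z (nm)", y = expression(C[BP](z)),
         title = sprintf("Bonded-phase contacts (r_BP = %.2f nm)",
                         attr(object, "r_bp"))) +
    theme_minimal()
}

#' Plot a hydrogen-bond profile
#' @param object An `hbond_profile`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.hbond_profile <- function(object, ...) {
  long <- as_tibble(object) |>
    select("z", "hb_functional", "hb_pi", "hb_total") |>
    tidyr::pivot_longer(-"z", names_to = "kind", values_to = "hb") |>
    filter(!is.na(.data$hb))
  ggplot(long, aes(x = .data$z, y = .data$hb, colour = .data$kind)) +
    geom_line() +
    labs(x = "z (nm)", y = "HB per analyte molecule",
         colour = NULL, title = "Solute-solvent hydrogen bonds") +
    theme_minimal()
}

#' Plot an orientation distribution
#' @param object An `orientation_profile`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.orientation_profile <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$z, y = .data$cos_phi, fill = .data$p)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "z (nm)", y = expression(cos ~ phi), fill = "p",
         title = "Analyte orientation distribution") +
    theme_minimal()
}

#' Plot partner density profiles
#' @param object A `partner_density_profile`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.partner_density_profile <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$z, y = .data$density, colour = .data$species)) +
    geom_line() +
    facet_wrap(~peak) +
    labs(x = "z (nm)", y = expression(rho[partner] ~ (nm^-3)),
         colour = NULL,
         title = "Hydrogen-bond partner densities by analyte peak") +
    theme_minimal()
}
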