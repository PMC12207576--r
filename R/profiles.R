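# Species density profiles on the distance-from-surface axis and the
# partitioning/adsorption peak decomposition.

.bin_centers <- function(hw, bin) {
  edges <- seq(0, hw + bin, by = bin)
  edges[-length(edges)] + bin / 2
}

# selected per-(frame, molecule) or per-particle z positions for a profile
.profile_positions <- function(frames, top = NULL, role = "analyte",
                               compound = NULL,
                               site_rule = c("com", "ring_com", "site"),
                               site_name = NULL) {
  site_rule <- match.arg(site_rule)
  frames <- fold_to_surface(frames)
  p <- frames$particles |> filter(.data$role == !!role)
  if (!is.null(compound)) {
    if (is.null(top)) abort("compound selection needs a topology")
    mids <- top$molecule_id[top$compound == compound]
    p <- p |> filter(.data$molecule_id %in% mids)
  }
  if (nrow(p) == 0) {
    abort("empty selection: no particles match the role/compound selector")
  }
  if (site_rule == "com") {
    .molecule_com(p, frames$box) |> select("frame", "molecule_id", "z")
  } else if (site_rule == "site") {
    if (is.null(site_name)) abort("site rule 'site' needs site_name")
    out <- p |> filter(.data$site_name == !!site_name)
    if (nrow(out) == 0) abort(paste0("empty selection: no site ", site_name))
    out |> select("frame", "molecule_id", "z")
  } else {
    if (is.null(top)) abort("ring-com selection needs a topology")
    rings <- top |> filter(lengths(.data$ring_ids) > 0)
    rings <- rings[rings$molecule_id %in% unique(p$molecule_id), ]
    if (nrow(rings) == 0) abort("empty selection: no aromatic rings")
    ring_tbl <- purrr::map_dfr(seq_len(nrow(rings)), function(i) {
      purrr::map_dfr(seq_along(rings$ring_ids[[i]]), function(r) {
        tibble(molecule_id = rings$molecule_id[i], ring = r,
               particle_id = rings$ring_ids[[i]][[r]])
      })
    })
    p |>
      dplyr::inner_join(ring_tbl, by = c("molecule_id", "particle_id")) |>
      group_by(.data$frame, .data$molecule_id, .data$ring) |>
      summarise(z = mean(.data$z), .groups = "drop") |>
      select("frame", "molecule_id", "z")
  }
}

#' Species density profile vs distance from the silica surface
#'
#' Histograms the selected positions (molecule centers of mass, aromatic
#' ring centers of mass, or a named site) in 0.05 nm bins of folded z and
#' converts counts to number densities: count / (Lx * Ly * bin_width *
#' n_surfaces * n_frames), with both pore surfaces pooled.
#'
#' @param frames A `slitpore_frames` object (slab geometry; folded
#'   internally if needed).
#' @param top Topology (needed for compound or ring-com selections).
#' @param role Particle role to select.
#' @param compound Optional compound filter (via the topology).
#' @param site_rule `"com"` (default), `"ring_com"` or `"site"`.
#' @param site_name Site name when `site_rule = "site"`.
#' @param regions A [region_spec()] (supplies the bin width).
#' @return A `density_profile` tibble with columns `z` (bin centers, nm),
#'   `density` (nm^-3) and `n` (raw counts).
#' @export
density_profile <- function(frames, top = NULL, role = "analyte",
                            compound = NULL,
                            site_rule = c("com", "ring_com", "site"),
                            site_name = NULL, regions = region_spec()) {
  stopifnot(inherits(frames, "slitpore_frames"))
  if (frames$geometry != "slab") abort("density_profile needs slab geometry")
  site_rule <- match.arg(site_rule)
  pos <- .profile_positions(frames, top, role, compound, site_rule, site_name)
  hw <- pore_half_width(frames)
  bin <- regions$bin_width
  n_frames <- dplyr::n_distinct(frames$particles$frame)
  centers <- .bin_centers(hw, bin)
  idx <- pmin(floor(pos$z / bin) + 1L, length(centers))
  counts <- tabulate(idx, nbins = length(centers))
  area <- frames$box[1] * frames$box[2]
  out <- tibble(z = centers, n = counts,
                density = counts / (area * bin * 2 * n_frames))
  attr(out, "bin_width") <- bin
  attr(out, "area") <- area
  attr(out, "n_frames") <- n_frames
  attr(out, "n_surfaces") <- 2L
  attr(out, "species") <- compound %||% role
  class(out) <- c("density_profile", class(out))
  out
}

#' Decompose an analyte density profile into surface, partitioning and
#' adsorption contributions
#'
#' The inter-peak boundary between the partitioning peak (bonded-phase
#' region) and the adsorption peak (interfacial region) is located as the
#' minimum of the 3-bin moving-average smoothed profile inside
#' `[z_bp_end - 0.15, z_bp_end + 0.25]`; if the minimum sits on the window
#' edge (no interior minimum) the region border `z_bp_end` itself is used.
#' Fractions are the normalised density mass at z <= z_sp in the three
#' windows (z <= surface_z_max | surface_z_max < z <= boundary |
#' boundary < z <= z_sp). The silica-surface peak is reported separately
#' and merged into the partitioning fraction for the two-way split
#' (`adsorption_fraction`), since the adsorption contribution is defined
#' against the total stationary-phase density.
#'
#' @param profile An analyte `density_profile`.
#' @param regions A [region_spec()] with `z_sp` set.
#' @param surface_z_max Outer edge of the silica-surface peak window (nm).
#' @return A `peak_decomposition` object.
#' @export
decompose_peaks <- function(profile, regions, surface_z_max = 0.55) {
  stopifnot(inherits(profile, "density_profile"))
  if (is.na(regions$z_sp)) abort("regions$z_sp must be set (see stationary_phase_limit)")
  z <- profile$z
  dens <- profile$density
  sp_mask <- z <= regions$z_sp
  if (sum(dens[sp_mask]) <= 0) {
    abort("undefined decomposition: no analyte density at z <= z_sp")
  }
  sm <- as.numeric(stats::filter(dens, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- dens[is.na(sm)]
  win <- which(z >= regions$z_bp_end - 0.15 & z <= regions$z_bp_end + 0.25)
  if (length(win) >= 3) {
    k <- win[which.min(sm[win])]
    interior <- k != win[1] && k != win[length(win)]
    boundary_z <- if (interior) z[k] else regions$z_bp_end
  } else {
    boundary_z <- regions$z_bp_end
  }
  m_surface <- sum(dens[z <= surface_z_max & sp_mask])
  m_part <- sum(dens[z > surface_z_max & z <= boundary_z & sp_mask])
  m_ads <- sum(dens[z > boundary_z & sp_mask])
  tot <- m_surface + m_part + m_ads
  fr <- c(surface = m_surface, partitioning = m_part, adsorption = m_ads) / tot
  structure(list(
    boundary_z = boundary_z,
    surface_z_max = surface_z_max,
    z_sp = regions$z_sp,
    fractions = fr,
    adsorption_fraction = unname(fr["adsorption"]),
    partitioning_fraction_two_way = unname(fr["surface"] + fr["partitioning"])
  ), class = "peak_decomposition")
}

#' @export
print.peak_decomposition <- function(x, ...) {
  cat("<peak_decomposition> boundary at z =", signif(x$boundary_z, 4),
      "nm, z_sp =", signif(x$z_sp, 4), "nm\n")
  cat(sprintf("  surface %.3f | partitioning %.3f | adsorption %.3f\n",
              x$fractions["surface"], x$fractions["partitioning"],
              x$fractions["adsorption"]))
  invisible(x)
}

#' @export
tidy.peak_decomposition <- function(x, ...) {
  tibble(peak = names(x$fractions), fraction = unname(x$fractions),
         boundary_z = x$boundary_z, z_sp = x$z_sp)
}

#' Write a density profile as TSV (z_center, value, species)
#' @param profile A `density_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(
    tibble(z_center = profile$z, value = profile$density,
           species = attr(profile, "species")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
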