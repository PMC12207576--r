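# Distance-criterion solute-solvent hydrogen bonds: detection (functional
# groups and pi systems), per-z profiles, stationary-phase averages, partner
# density profiles and the neat-water hydrogen-bond requirement.

# solvent atom classification: which atoms can satisfy a criterion
.h_atoms <- c("HW1", "HW2", "H_Me")
.key_atoms <- c(W = "OW", MeOH = "O_Me", ACN = "N_ACN")
.species_of <- c(OW = "W", HW1 = "W", HW2 = "W",
                 O_Me = "MeOH", H_Me = "MeOH", CH3_Me = "MeOH",
                 N_ACN = "ACN", C_ACN = "ACN", CH3_ACN = "ACN")

#' Hydrogen-bond distance criteria
#'
#' Pure distance criteria `r <= r_HB` keyed by (solute site class, solvent
#' species), with the partner atom each pair is measured to: solute donor
#' hydrogens to the solvent key atom (O of W/MeOH, N of ACN), solute
#' acceptor atoms to solvent hydrogens, and aromatic-ring centers of mass
#' (pi systems) to solvent hydrogens. The pi cutoffs (0.30 nm to W
#' hydrogens, 0.32 nm to MeOH hydrogens) are established values; the
#' functional-group defaults are plausible placeholders and should be
#' replaced by system-specific per-pair cutoffs when available - they are
#' user-replaceable precisely because no validated table ships here.
#'
#' @param donor_w,donor_meoh,donor_acn Solute-donor-H cutoffs (nm).
#' @param acceptor_w,acceptor_meoh Solute-acceptor cutoffs (nm).
#' @param pi_w,pi_meoh Aromatic-com-to-solvent-H cutoffs (nm).
#' @return A criteria tibble (`site_class`, `species`, `partner_atom`,
#'   `r_hb`).
#' @export
hbond_criteria <- function(donor_w = 0.245, donor_meoh = 0.245,
                           donor_acn = 0.255, acceptor_w = 0.245,
                           acceptor_meoh = 0.245, pi_w = 0.30,
                           pi_meoh = 0.32) {
  out <- tibble(
    site_class = c("donor", "donor", "donor", "acceptor", "acceptor",
                   "pi", "pi"),
    species = c("W", "MeOH", "ACN", "W", "MeOH", "W", "MeOH"),
    partner_atom = c("key", "key", "key", "H", "H", "H", "H"),
    r_hb = c(donor_w, donor_meoh, donor_acn, acceptor_w, acceptor_meoh,
             pi_w, pi_meoh)
  )
  if (any(out$r_hb <= 0.15 | out$r_hb >= 0.45)) {
    abort("hydrogen-bond cutoffs must lie in (0.15, 0.45) nm")
  }
  out
}

# solute site table of one frame: positions, classes, labels, analyte ids.
# Vectorised: point sites by one match() over particle ids, ring centers of
# mass by rowsum over a ring key (with minimum-image unwrap in x,y).
.solute_sites <- function(p, top, box, z_periodic = FALSE) {
  if (!"half" %in% names(p)) p$half <- NA_integer_
  an_top <- top |> filter(.data$role == "analyte")
  if (nrow(an_top) == 0) return(NULL)

  don_ids <- unlist(an_top$donor_ids)
  acc_ids <- unlist(an_top$acceptor_ids)
  point <- tibble(
    molecule_id = c(rep(an_top$molecule_id, lengths(an_top$donor_ids)),
                    rep(an_top$molecule_id, lengths(an_top$acceptor_ids))),
    site_class = c(rep("donor", length(don_ids)),
                   rep("acceptor", length(acc_ids))),
    site_label = as.character(c(don_ids, acc_ids)))
  idx <- match(c(don_ids, acc_ids), p$particle_id)
  point$x <- p$x[idx]; point$y <- p$y[idx]
  point$z <- p$z[idx]; point$half <- p$half[idx]

  n_rings <- lengths(an_top$ring_ids)
  rings <- NULL
  if (sum(n_rings) > 0) {
    with_r <- which(n_rings > 0)
    ring_list <- unlist(an_top$ring_ids[with_r], recursive = FALSE)
    ring_mol <- rep(an_top$molecule_id[with_r], n_rings[with_r])
    ring_no <- unlist(lapply(n_rings[with_r], seq_len))
    ids <- unlist(ring_list)
    key <- rep(seq_along(ring_list), lengths(ring_list))
    j <- match(ids, p$particle_id)
    x0 <- p$x[j][!duplicated(key)][key]
    y0 <- p$y[j][!duplicated(key)][key]
    dx <- p$x[j] - x0; dx <- dx - box[1] * round(dx / box[1])
    dy <- p$y[j] - y0; dy <- dy - box[2] * round(dy / box[2])
    cnt <- as.numeric(table(key))
    zc <- if (z_periodic) {
      z0 <- p$z[j][!duplicated(key)][key]
      dz <- p$z[j] - z0; dz <- dz - box[3] * round(dz / box[3])
      .wrap(z0[!duplicated(key)] + as.numeric(rowsum(dz, key)) / cnt, box[3])
    } else {
      as.numeric(rowsum(p$z[j], key)) / cnt
    }
    rings <- tibble(
      molecule_id = ring_mol,
      site_class = "pi",
      site_label = paste0("pi", ring_no),
      x = .wrap(x0[!duplicated(key)] + as.numeric(rowsum(dx, key)) / cnt,
                box[1]),
      y = .wrap(y0[!duplicated(key)] + as.numeric(rowsum(dy, key)) / cnt,
                box[2]),
      z = zc,
      half = p$half[j][!duplicated(key)])
  }
  out <- bind_rows(point, rings)
  if (nrow(out) == 0) NULL else out
}

#' Detect solute-solvent hydrogen bonds
#'
#' Applies the distance criteria to every (solute site, solvent atom) pair
#' of every frame, boundary inclusive, with minimum-image distances in the
#' periodic directions. A solute site may bind several partner molecules -
#' each (site, partner molecule) pair is one row, so per-molecule
#' hydrogen-bond numbers can exceed one; when two atoms of one solvent
#' molecule satisfy the same criterion only the closer one is kept.
#'
#' @param frames A `slitpore_frames` object (slab or bulk geometry).
#' @param top Topology with donor/acceptor/ring annotations.
#' @param criteria A criteria table from [hbond_criteria()]. Every site
#'   class annotated in the topology must have at least one criteria row.
#' @return An `hbond_table` tibble: one row per detected bond with the
#'   solute site, partner molecule/species, pair distance, the analyte
#'   center-of-mass z and the partner key-atom z (folded; NA for bulk
#'   geometry).
#' @export
detect_hbonds <- function(frames, top, criteria = hbond_criteria()) {
  stopifnot(inherits(frames, "slitpore_frames"))
  slab <- frames$geometry == "slab"
  if (slab) frames <- fold_to_surface(frames)
  an_top <- top |> filter(.data$role == "analyte")
  annotated <- unique(c(
    if (sum(lengths(an_top$donor_ids)) > 0) "donor",
    if (sum(lengths(an_top$acceptor_ids)) > 0) "acceptor",
    if (sum(lengths(an_top$ring_ids)) > 0) "pi"))
  for (cls in annotated) {
    if (!any(criteria$site_class == cls)) {
      abort(paste0("configuration error: no criteria for site class '",
                   cls, "'"))
    }
  }
  pw <- if (slab) 2 * pore_half_width(frames) else NA
  box <- frames$box
  an_part <- frames$particles |> filter(.data$role == "analyte")
  if (nrow(an_part) == 0) abort("no analyte molecules in frames")
  coms <- .molecule_com(an_part, box, z_periodic = !slab)

  res <- list()
  by_frame <- split(frames$particles, frames$particles$frame)
  for (p in by_frame) {
    fr <- p$frame[1]
    sites <- .solute_sites(p, top, box, z_periodic = !slab)
    if (is.null(sites)) next
    solv <- p |> filter(.data$role %in% c("water", "organic_solvent"))
    if (nrow(solv) == 0) next
    solv$species <- unname(.species_of[solv$site_name])
    solv$atom_type <- ifelse(solv$site_name %in% .h_atoms, "H",
                             ifelse(solv$site_name %in% .key_atoms, "key",
                                    "none"))
    cand <- solv |> filter(.data$atom_type != "none")
    d <- min_image_dist(
      as.matrix(sites[, c("x", "y", "z")]),
      as.matrix(cand[, c("x", "y", "z")]),
      box, geometry = frames$geometry,
      halves_p = if (slab) sites$half else NULL,
      halves_q = if (slab) cand$half else NULL,
      pore_width = pw)
    key_z <- solv |> filter(.data$atom_type == "key")
    for (ci in seq_len(nrow(criteria))) {
      si <- which(sites$site_class == criteria$site_class[ci])
      pj <- which(cand$species == criteria$species[ci] &
                    cand$atom_type == criteria$partner_atom[ci])
      if (length(si) == 0 || length(pj) == 0) next
      hits <- which(d[si, pj, drop = FALSE] <= criteria$r_hb[ci],
                    arr.ind = TRUE)
      if (nrow(hits) == 0) next
      s_idx <- si[hits[, 1]]
      p_idx <- pj[hits[, 2]]
      pmid <- cand$molecule_id[p_idx]
      # one bond per (solute site, partner molecule): if both hydrogens of
      # a water reach the site, keep the closer atom only
      dist_hit <- d[cbind(s_idx, p_idx)]
      o <- order(dist_hit)
      keep <- o[!duplicated(paste(s_idx[o], pmid[o]))]
      keep <- sort(keep)
      s_idx <- s_idx[keep]; p_idx <- p_idx[keep]; pmid <- pmid[keep]
      res[[length(res) + 1L]] <- tibble(
        frame = fr, time = p$time[1],
        molecule_id = sites$molecule_id[s_idx],
        site_class = sites$site_class[s_idx],
        site_label = sites$site_label[s_idx],
        kind = ifelse(sites$site_class[s_idx] == "pi", "pi", "functional"),
        partner_molecule_id = pmid,
        partner_species = cand$species[p_idx],
        distance = d[cbind(s_idx, p_idx)],
        partner_z = if (slab) {
          key_z$z[match(pmid, key_z$molecule_id)]
        } else NA_real_)
    }
  }
  out <- if (length(res) > 0) bind_rows(res) else tibble(
    frame = integer(0), time = numeric(0), molecule_id = integer(0),
    site_class = character(0), site_label = character(0),
    kind = character(0), partner_molecule_id = integer(0),
    partner_species = character(0), distance = numeric(0),
    partner_z = numeric(0))
  out <- left_join(out,
                   coms |> select("frame", "molecule_id",
                                  analyte_z = "z"),
                   by = c("frame", "molecule_id"))
  if (!slab) out$analyte_z <- NA_real_
  attr(out, "n_frames") <- dplyr::n_distinct(frames$particles$frame)
  attr(out, "geometry") <- frames$geometry
  attr(out, "box") <- box
  attr(out, "time_span") <- diff(range(frames$particles$time)) +
    ifelse(dplyr::n_distinct(frames$particles$time) > 1,
           min(diff(sort(unique(frames$particles$time)))), 0)
  class(out) <- c("hbond_table", class(out))
  out
}

#' Per-(frame, molecule) analyte positions
#'
#' Folded center-of-mass positions of every analyte molecule - the visit
#' table that hydrogen-bond and orientation profiles normalise against.
#'
#' @param frames A slab `slitpore_frames` object.
#' @return A tibble: `frame`, `time`, `molecule_id`, `z`, `half`.
#' @export
analyte_positions <- function(frames) {
  frames <- fold_to_surface(frames)
  an <- frames$particles |> filter(.data$role == "analyte")
  if (nrow(an) == 0) abort("no analyte molecules in frames")
  .molecule_com(an, frames$box) |>
    select("frame", "time", "molecule_id", "z", "half")
}

#' Hydrogen bonds per analyte molecule vs z
#'
#' Mean number of detected hydrogen bonds per analyte molecule visit in
#' each z bin of the analyte center of mass, with the functional-group and
#' pi contributions reported separately and summed. Bins without visits
#' are missing (NA).
#'
#' @param tbl An `hbond_table` from [detect_hbonds()] (slab geometry).
#' @param visits Visit table from [analyte_positions()].
#' @param regions A [region_spec()] (bin width).
#' @param hw Pore half-width (nm); inferred from the visits when omitted.
#' @return An `hbond_profile` tibble: `z`, `hb_functional`, `hb_pi`,
#'   `hb_total`, `n_visits`.
#' @export
hbond_profile <- function(tbl, visits, regions = region_spec(), hw = NULL) {
  stopifnot(inherits(tbl, "hbond_table"))
  bin <- regions$bin_width
  hw <- hw %||% (ceiling(max(visits$z) / bin) * bin)
  centers <- .bin_centers(hw, bin)
  vis_i <- pmin(floor(visits$z / bin) + 1L, length(centers))
  n_visits <- tabulate(vis_i, nbins = length(centers))
  if (nrow(tbl) == 0) {
    warn("empty hydrogen-bond table: profile is all-missing")
  }
  cnt <- function(rows) {
    if (nrow(rows) == 0) return(numeric(length(centers)))
    i <- pmin(floor(rows$analyte_z / bin) + 1L, length(centers))
    tabulate(i, nbins = length(centers))
  }
  fg <- cnt(tbl |> filter(.data$kind == "functional"))
  pp <- cnt(tbl |> filter(.data$kind == "pi"))
  out <- tibble(
    z = centers,
    hb_functional = ifelse(n_visits > 0, fg / n_visits, NA_real_),
    hb_pi = ifelse(n_visits > 0, pp / n_visits, NA_real_),
    n_visits = n_visits)
  out$hb_total <- out$hb_functional + out$hb_pi
  attr(out, "bin_width") <- bin
  class(out) <- c("hbond_profile", class(out))
  out
}

#' Stationary-phase hydrogen-bond summary
#'
#' The analyte-density-weighted mean hydrogen bonds per molecule over
#' z <= z_SP (same weighting rule as the contact average), the fraction of
#' the bulk-liquid hydrogen bonds recovered in the stationary phase, and
#' the water contribution to the detected bonds in the stationary phase
#' and in the bulk region.
#'
#' @param profile An `hbond_profile`.
#' @param analyte_density Analyte `density_profile` on the same bins.
#' @param z_sp Stationary-phase limit (nm).
#' @param hb_bulk Bulk-liquid hydrogen bonds per molecule (input; > 0).
#' @param tbl The `hbond_table` (for the species-resolved contributions).
#' @param regions A [region_spec()] (bulk region start).
#' @return An `hbond_summary` object.
#' @export
hbond_summary <- function(profile, analyte_density, z_sp, hb_bulk, tbl,
                          regions = region_spec()) {
  stopifnot(inherits(profile, "hbond_profile"))
  if (!is.na(hb_bulk) && hb_bulk <= 0) {
    abort("recovery undefined: hb_bulk must be > 0")
  }
  j <- dplyr::inner_join(
    tibble(z = round(profile$z, 6), hb = profile$hb_total),
    tibble(z = round(analyte_density$z, 6), rho = analyte_density$density),
    by = "z") |>
    filter(.data$z <= z_sp, .data$rho > 0)
  if (nrow(j) == 0 || sum(j$rho) <= 0) {
    abort("undefined average: no analyte density at z <= z_sp")
  }
  if (any(is.na(j$hb))) {
    abort("missing hydrogen-bond bins with nonzero analyte density")
  }
  hb_sp <- sum(j$hb * j$rho) / sum(j$rho)
  wc <- function(rows) {
    if (nrow(rows) == 0) return(NA_real_)
    mean(rows$partner_species == "W")
  }
  structure(list(
    hb_sp = hb_sp,
    hb_bulk = hb_bulk,
    recovery = if (is.na(hb_bulk)) NA_real_ else hb_sp / hb_bulk,
    w_contribution_sp = wc(tbl |> filter(.data$analyte_z <= z_sp)),
    w_contribution_bulk = wc(tbl |>
                               filter(.data$analyte_z > regions$z_bulk_start))
  ), class = "hbond_summary")
}

#' @export
print.hbond_summary <- function(x, ...) {
  cat("<hbond_summary>\n")
  cat(sprintf("  <HB>_SP = %.3f | bulk = %s | recovery = %s\n",
              x$hb_sp,
              ifelse(is.na(x$hb_bulk), "NA", sprintf("%.3f", x$hb_bulk)),
              ifelse(is.na(x$recovery), "NA", sprintf("%.3f", x$recovery))))
  cat(sprintf("  W contribution: SP %.3f | bulk %s\n",
              x$w_contribution_sp,
              ifelse(is.na(x$w_contribution_bulk), "NA",
                     sprintf("%.3f", x$w_contribution_bulk))))
  invisible(x)
}

#' @export
tidy.hbond_summary <- function(x, ...) {
  tibble(statistic = c("hb_sp", "hb_bulk", "recovery", "w_contribution_sp",
                       "w_contribution_bulk"),
         value = c(x$hb_sp, x$hb_bulk, x$recovery, x$w_contribution_sp,
                   x$w_contribution_bulk))
}

#' Hydrogen-bond partner density profiles by analyte peak
#'
#' Number densities (atoms per nm^3) of the engaged partner key atoms (O of
#' W, O of MeOH, N of ACN), binned by the partner's own z and conditioned
#' on the peak holding the analyte's center of mass: partitioning
#' (z <= boundary, surface window included) or adsorption
#' (boundary < z <= z_SP). Rows whose analyte sits beyond z_SP are excluded
#' and tallied in the `excluded_rows` attribute.
#'
#' @param tbl An `hbond_table` (slab geometry).
#' @param decomposition A `peak_decomposition` (supplies boundary and z_SP).
#' @param regions A [region_spec()] (bin width).
#' @param hw Pore half-width (nm); inferred from the table when omitted.
#' @return A `partner_density_profile` tibble: `z`, `species`, `peak`,
#'   `density`, `n`.
#' @export
partner_density <- function(tbl, decomposition, regions = region_spec(),
                            hw = NULL) {
  stopifnot(inherits(tbl, "hbond_table"),
            inherits(decomposition, "peak_decomposition"))
  if (attr(tbl, "geometry") != "slab") abort("partner_density needs slab data")
  bin <- regions$bin_width
  box <- attr(tbl, "box")
  n_frames <- attr(tbl, "n_frames")
  hw <- hw %||% (ceiling(max(c(tbl$partner_z, 1)) / bin) * bin)
  centers <- .bin_centers(hw, bin)
  keep <- tbl |> filter(.data$analyte_z <= decomposition$z_sp)
  excluded <- nrow(tbl) - nrow(keep)
  keep$peak <- ifelse(keep$analyte_z <= decomposition$boundary_z,
                      "partitioning", "adsorption")
  out <- keep |>
    mutate(bin_i = pmin(floor(.data$partner_z / bin) + 1L,
                        length(centers))) |>
    group_by(.data$partner_species, .data$peak, .data$bin_i) |>
    summarise(n = n(), .groups = "drop") |>
    mutate(z = centers[.data$bin_i],
           density = .data$n / (box[1] * box[2] * bin * 2 * n_frames),
           species = .data$partner_species) |>
    select("z", "species", "peak", "density", "n") |>
    arrange(.data$species, .data$peak, .data$z)
  attr(out, "excluded_rows") <- excluded
  attr(out, "bin_width") <- bin
  class(out) <- c("partner_density_profile", class(out))
  out
}

#' Integrated partner density over a z window
#'
#' Integrates the partner density profile over a window (default
#' 1.5-2.25 nm, where the majority of adsorption-peak hydrogen-bond
#' partners reside), per species and peak.
#'
#' @param pd A `partner_density_profile`.
#' @param window Length-2 z window (nm).
#' @return A tibble: `species`, `peak`, `area` (atoms per nm^2).
#' @export
integrate_partner_density <- function(pd, window = c(1.5, 2.25)) {
  stopifnot(inherits(pd, "partner_density_profile"))
  bin <- attr(pd, "bin_width")
  pd |>
    filter(.data$z >= window[1], .data$z <= window[2]) |>
    group_by(.data$species, .data$peak) |>
    summarise(area = sum(.data$density) * bin, .groups = "drop")
}

#' Hydrogen-bond requirement in neat water
#'
#' Mean solute-water hydrogen bonds per analyte molecule over a neat-water
#' bulk ensemble (HB_solute-W,max), with the functional-group and pi
#' contributions reported separately.
#'
#' @param frames A bulk `slitpore_frames` object.
#' @param top Topology with site annotations.
#' @param criteria Criteria table.
#' @return An `hb_max` object: `total`, `functional`, `pi`,
#'   `n_molecule_frames`.
#' @export
hb_max_neat_water <- function(frames, top, criteria = hbond_criteria()) {
  stopifnot(inherits(frames, "slitpore_frames"))
  if (frames$geometry != "bulk") {
    abort("geometry error: hb_max needs bulk (non-slab) frames")
  }
  n_an <- sum(top$role == "analyte")
  if (n_an == 0) abort("no analyte molecules in topology")
  tbl <- detect_hbonds(frames, top, criteria)
  n_mf <- n_an * dplyr::n_distinct(frames$particles$frame)
  fg <- sum(tbl$kind == "functional") / n_mf
  pp <- sum(tbl$kind == "pi") / n_mf
  structure(list(total = fg + pp, functional = fg, pi = pp,
                 n_molecule_frames = n_mf),
            class = "hb_max")
}

#' @export
print.hb_max <- function(x, ...) {
  cat(sprintf(
    "<hb_max> HB_solute-W,max = %.3f (functional %.3f + pi %.3f) over %d molecule-frames\n",
    x$total, x$functional, x$pi, x$n_molecule_frames))
  invisible(x)
}
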