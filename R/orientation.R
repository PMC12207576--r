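# Analyte orientation: cos(phi) between the solute-specific molecular
# vector and the surface normal (pointing from the surface into the pore),
# resolved in z, and density-weighted preferential orientations per peak.

#' Orientation distribution vs distance from the surface
#'
#' For every analyte visit, cos(phi) is the dot product of the unit
#' molecular vector (topology tail -> head; a tail id of 0 uses the first
#' aromatic ring's center of mass) with the unit surface normal pointing
#' into the pore. Frames folded from the upper surface flip the normal, so
#' cos(phi) > 0 always means the head points toward the bulk liquid and
#' cos(phi) < 0 toward the silica surface. The distribution is histogrammed
#' in 0.05 nm z bins x 0.1-wide cos(phi) bins and normalised per z slice.
#'
#' @param frames A slab `slitpore_frames` object.
#' @param top Topology; only molecules with vector endpoints contribute.
#' @param regions A [region_spec()] (z bin width).
#' @param cos_bin cos(phi) bin width.
#' @return An `orientation_profile` tibble: `z`, `cos_phi` (bin centers),
#'   `p` (probability within the z slice), `n` (visits in the cell).
#' @export
orientation_profile <- function(frames, top, regions = region_spec(),
                                cos_bin = 0.1) {
  frames <- fold_to_surface(frames)
  an_top <- top |> filter(.data$role == "analyte",
                          !is.na(.data$vector_head_id))
  if (nrow(an_top) == 0) {
    abort("no analyte molecule with a molecular vector in the topology")
  }
  box <- frames$box
  vis <- analyte_positions(frames)
  p <- frames$particles

  heads <- p[p$particle_id %in% an_top$vector_head_id,
             c("frame", "molecule_id", "x", "y", "z")]
  names(heads)[3:5] <- c("hx", "hy", "hz")

  # tails: either a named particle or (tail id 0) the first aromatic ring's
  # center of mass
  part_tail <- an_top |> filter(.data$vector_tail_id > 0)
  ring_tail <- an_top |> filter(.data$vector_tail_id == 0)
  tails <- list()
  if (nrow(part_tail) > 0) {
    tt <- p[p$particle_id %in% part_tail$vector_tail_id,
            c("frame", "molecule_id", "x", "y", "z")]
    names(tt)[3:5] <- c("tx", "ty", "tz")
    tails[[1]] <- tt
  }
  if (nrow(ring_tail) > 0) {
    ring_ids <- lapply(ring_tail$ring_ids, `[[`, 1)
    rr <- p[p$particle_id %in% unlist(ring_ids), ]
    key <- factor(paste(rr$frame, rr$molecule_id, sep = "\r"),
                  levels = unique(paste(rr$frame, rr$molecule_id,
                                        sep = "\r")))
    first <- !duplicated(key)
    ref <- match(key, key[first])
    dx <- rr$x - rr$x[first][ref]
    dy <- rr$y - rr$y[first][ref]
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    cnt <- as.numeric(table(key))
    tails[[length(tails) + 1L]] <- tibble(
      frame = rr$frame[first], molecule_id = rr$molecule_id[first],
      tx = rr$x[first] + as.numeric(rowsum(dx, key)) / cnt,
      ty = rr$y[first] + as.numeric(rowsum(dy, key)) / cnt,
      tz = as.numeric(rowsum(rr$z, key)) / cnt)
  }
  ori <- dplyr::inner_join(heads, bind_rows(tails),
                           by = c("frame", "molecule_id"))
  dx <- ori$hx - ori$tx
  dy <- ori$hy - ori$ty
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  # folded z of head and tail are distances to the same plane, so the folded
  # difference already carries the flipped normal for the upper pore half
  dz <- ori$hz - ori$tz
  len <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(len < 1e-9)) abort("zero-length molecular vector")
  ori <- tibble(frame = ori$frame, molecule_id = ori$molecule_id,
                cos_phi = dz / len) |>
    left_join(vis |> select("frame", "molecule_id", "z"),
              by = c("frame", "molecule_id"))
  bin <- regions$bin_width
  hw <- pore_half_width(frames)
  zc <- .bin_centers(hw, bin)
  cc <- seq(-1 + cos_bin / 2, 1 - cos_bin / 2, by = cos_bin)
  ori <- ori |>
    mutate(zi = pmin(floor(.data$z / bin) + 1L, length(zc)),
           ci = pmin(floor((.data$cos_phi + 1) / cos_bin) + 1L, length(cc)))
  grid <- ori |>
    dplyr::count(.data$zi, .data$ci) |>
    group_by(.data$zi) |>
    mutate(p = .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(z = zc[.data$zi], cos_phi = cc[.data$ci]) |>
    select("z", "cos_phi", "p", "n") |>
    arrange(.data$z, .data$cos_phi)
  attr(grid, "bin_width") <- bin
  attr(grid, "cos_bin") <- cos_bin
  attr(grid, "z_centers") <- zc
  class(grid) <- c("orientation_profile", class(grid))
  grid
}

#' Per-z mean of cos(phi)
#'
#' Slice means of the orientation histogram (probability-weighted bin
#' centers).
#'
#' @param profile An `orientation_profile`.
#' @return A tibble: `z`, `mean_cos`, `n`.
#' @export
orientation_means <- function(profile) {
  stopifnot(inherits(profile, "orientation_profile"))
  profile |>
    group_by(.data$z) |>
    summarise(mean_cos = sum(.data$p * .data$cos_phi),
              n = sum(.data$n), .groups = "drop")
}

#' Preferential orientation in a z interval
#'
#' Analyte-density-weighted mean of the cos(phi) distribution over a z
#' interval (typically the partitioning or the adsorption peak), with the
#' sign read as orientation: positive toward the bulk liquid, negative
#' toward the silica surface, |mean| < 0.05 reported as isotropic.
#'
#' @param profile An `orientation_profile`.
#' @param analyte_density Analyte `density_profile` on the same z bins.
#' @param interval Length-2 z interval (nm).
#' @return A `preferred_orientation` object: `mean_cos`, `n`,
#'   `interpretation`.
#' @export
preferred_orientation <- function(profile, analyte_density, interval) {
  m <- orientation_means(profile)
  j <- dplyr::inner_join(
    m |> mutate(z = round(.data$z, 6)),
    tibble(z = round(analyte_density$z, 6), rho = analyte_density$density),
    by = "z") |>
    filter(.data$z >= interval[1], .data$z <= interval[2], .data$rho > 0)
  if (nrow(j) == 0 || sum(j$rho) <= 0) {
    abort("undefined orientation: no analyte density in the interval")
  }
  mean_cos <- sum(j$mean_cos * j$rho) / sum(j$rho)
  interp <- if (abs(mean_cos) < 0.05) "isotropic"
            else if (mean_cos > 0) "bulk-oriented" else "surface-oriented"
  structure(list(mean_cos = mean_cos, n = sum(j$n),
                 interval = interval, interpretation = interp),
            class = "preferred_orientation")
}

#' @export
print.preferred_orientation <- function(x, ...) {
  cat(sprintf("<preferred_orientation> z in [%.2f, %.2f] nm: <cos phi> = %.3f (%s)\n",
              x$interval[1], x$interval[2], x$mean_cos, x$interpretation))
  invisible(x)
}
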