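# Core containers: particle frames of a slit-pore (or bulk) system, region
# bookkeeping, periodic distances, folding onto a single-surface z axis.

.roles <- c("silica", "bonded_phase", "endcap", "residual_OH",
            "water", "organic_solvent", "analyte")

#' Construct a frame ensemble
#'
#' Bundles a particle table covering one or more configurations with the box
#' geometry. Coordinates are in nm throughout; the slab geometry is periodic
#' in x and y only, a bulk box in all three directions.
#'
#' @param particles Tibble with columns `frame` (integer), `time` (ns),
#'   `particle_id`, `site_name`, `role` (one of silica, bonded_phase, endcap,
#'   residual_OH, water, organic_solvent, analyte), `molecule_id`, `x`, `y`,
#'   `z`.
#' @param box Numeric length-3, box edge lengths (Lx, Ly, Lz) in nm.
#' @param surface_planes Numeric length-2, z-coordinates of the two silica
#'   surface planes (required for slab geometry).
#' @param geometry `"slab"` or `"bulk"`.
#' @param folded Whether `z` already holds distance from the nearest surface
#'   plane (see [fold_to_surface()]).
#' @return A `slitpore_frames` object.
#' @export
slitpore_frames <- function(particles, box, surface_planes = NULL,
                            geometry = c("slab", "bulk"), folded = FALSE) {
  geometry <- match.arg(geometry)
  particles <- as_tibble(particles)
  needed <- c("frame", "time", "particle_id", "site_name", "role",
              "molecule_id", "x", "y", "z")
  missing_cols <- setdiff(needed, names(particles))
  if (length(missing_cols) > 0) {
    abort(paste0("particles lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_roles <- setdiff(unique(particles$role), .roles)
  if (length(bad_roles) > 0) {
    abort(paste0("unknown particle role(s): ",
                 paste(bad_roles, collapse = ", ")))
  }
  if (length(box) != 3 || any(box <= 0)) abort("box must be 3 positive lengths")
  if (geometry == "slab") {
    if (is.null(surface_planes) || length(surface_planes) != 2 ||
        surface_planes[1] >= surface_planes[2]) {
      abort("slab geometry needs surface_planes with surf_lo < surf_hi")
    }
  }
  dup <- particles |>
    dplyr::count(.data$frame, .data$particle_id) |>
    filter(n > 1L)
  if (nrow(dup) > 0) abort("particle_id must be unique within a frame")
  structure(
    list(particles = particles, box = as.numeric(box),
         surface_planes = if (is.null(surface_planes)) NULL
                          else as.numeric(surface_planes),
         geometry = geometry, folded = folded),
    class = "slitpore_frames"
  )
}

#' @export
print.slitpore_frames <- function(x, ...) {
  nf <- dplyr::n_distinct(x$particles$frame)
  cat("<slitpore_frames> ", nf, " frame(s), ",
      nrow(x$particles) / max(nf, 1L), " particles/frame, geometry ",
      x$geometry, if (x$folded) " (folded)" else "", "\n", sep = "")
  cat("  box:", paste(signif(x$box, 5), collapse = " x "), "nm\n")
  if (!is.null(x$surface_planes)) {
    cat("  surface planes at z =",
        paste(signif(x$surface_planes, 5), collapse = ", "), "nm\n")
  }
  invisible(x)
}

#' Pore half-width of a slab system
#' @param frames A `slitpore_frames` object with slab geometry.
#' @return Half of the pore width in nm.
#' @export
pore_half_width <- function(frames) {
  stopifnot(inherits(frames, "slitpore_frames"), frames$geometry == "slab")
  diff(frames$surface_planes) / 2
}

# wrap coordinates into [0, L)
.wrap <- function(v, l) v - floor(v / l) * l

#' Minimum-image displacement table
#'
#' Computes distances between two sets of points under the system's periodic
#' boundary conditions: minimum image in x and y for the slab, in x, y and z
#' for a bulk box. For folded slab coordinates the z separation of particles
#' on opposite pore halves is reconstructed from the half labels (their true
#' separation is `pore_width - z1 - z2`).
#'
#' @param p,q Matrices with columns x, y, z (folded or lab frame, consistent
#'   with `folded`/`halves`).
#' @param box Box lengths.
#' @param geometry `"slab"` or `"bulk"`.
#' @param halves_p,halves_q Optional integer vectors (1 = lower surface,
#'   2 = upper surface) for folded slab coordinates.
#' @param pore_width Pore width, required when halves are supplied.
#' @return Matrix of distances, `nrow(p)` x `nrow(q)`.
#' @keywords internal
min_image_dist <- function(p, q, box, geometry = "slab",
                           halves_p = NULL, halves_q = NULL,
                           pore_width = NULL) {
  p <- matrix(as.numeric(p), ncol = 3)
  q <- matrix(as.numeric(q), ncol = 3)
  dx <- outer(p[, 1], q[, 1], "-")
  dy <- outer(p[, 2], q[, 2], "-")
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  dz <- outer(p[, 3], q[, 3], "-")
  if (geometry == "bulk") {
    dz <- dz - box[3] * round(dz / box[3])
  } else if (!is.null(halves_p)) {
    if (is.null(pore_width)) abort("pore_width needed with half labels")
    cross <- outer(halves_p, halves_q, "!=")
    zsum <- outer(p[, 3], q[, 3], "+")
    dz[cross] <- (pore_width - zsum)[cross]
  }
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Fold a slab frame onto the single-surface z axis
#'
#' Replaces every particle's z by its distance to the nearest of the two
#' silica surface planes, mapping both pore halves onto one axis
#' z in [0, half-width]. Both halves are pooled in all downstream profiles,
#' doubling statistics; a `half` column (1 = lower, 2 = upper surface)
#' records the origin of each particle so that cross-half distances and the
#' orientation sign convention stay exact. Folding is idempotent and leaves
#' x, y untouched.
#'
#' Particles beyond both planes by more than `tol` (inside the silica slab,
#' which sits outside the pore) trigger a geometry warning and are clamped
#' to z = 0.
#'
#' @param frames A slab `slitpore_frames` object.
#' @param tol Clamp tolerance in nm (default one bin width, 0.05).
#' @return A folded `slitpore_frames` object.
#' @export
fold_to_surface <- function(frames, tol = 0.05) {
  stopifnot(inherits(frames, "slitpore_frames"))
  if (frames$geometry != "slab") abort("fold_to_surface needs slab geometry")
  if (frames$folded) return(frames)
  lo <- frames$surface_planes[1]
  hi <- frames$surface_planes[2]
  p <- frames$particles
  d_lo <- p$z - lo
  d_hi <- hi - p$z
  zf <- pmin(d_lo, d_hi)
  if (any(zf < -tol)) {
    warn(paste0(sum(zf < -tol),
                " particle(s) beyond both surface planes; clamped to z = 0"))
  }
  p$half <- ifelse(d_lo <= d_hi, 1L, 2L)
  p$z <- pmax(zf, 0)
  out <- frames
  out$particles <- p
  out$folded <- TRUE
  out
}

#' Region bookkeeping for the solvated stationary phase
#'
#' Boundaries on the distance-from-surface axis: the bonded-phase /
#' interfacial border `z_bp_end` (1.05 nm), the start of the bulk liquid
#' region `z_bulk_start` (2.55 nm), the stationary-phase limit `z_sp`
#' (set from the contact profile, see [stationary_phase_limit()]) and the
#' histogram bin width (0.05 nm).
#'
#' @param z_bp_end,z_bulk_start,z_sp,bin_width Region parameters in nm.
#' @return A `region_spec` object.
#' @export
region_spec <- function(z_bp_end = 1.05, z_bulk_start = 2.55,
                        z_sp = NA_real_, bin_width = 0.05) {
  if (!(z_bp_end > 0 && z_bulk_start > z_bp_end)) {
    abort("need 0 < z_bp_end < z_bulk_start")
  }
  if (bin_width <= 0) abort("bin_width must be > 0")
  structure(list(z_bp_end = z_bp_end, z_bulk_start = z_bulk_start,
                 z_sp = z_sp, bin_width = bin_width),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat("<region_spec> bonded phase <=", x$z_bp_end,
      "nm | bulk >", x$z_bulk_start, "nm | z_sp =",
      ifelse(is.na(x$z_sp), "unset", signif(x$z_sp, 4)),
      "| bin", x$bin_width, "nm\n")
  invisible(x)
}

# per-molecule centers of mass for a role/compound selection; works on
# folded or lab frames. Masses from the united-atom site table.
.site_masses <- c(
  CH3 = 15.035, CH2 = 14.027, CH = 13.019, C = 12.011, C_ar = 12.011,
  O = 15.999, OW = 15.999, O_Me = 15.999, HO = 1.008, H = 1.008,
  HW1 = 1.008, HW2 = 1.008, H_Me = 1.008, N_ACN = 14.007, C_ACN = 12.011,
  CH3_Me = 15.035, CH3_ACN = 15.035, SI = 28.086, OS = 15.999,
  BEAD = 100.0, SITE = 1.0
)

.mass_of <- function(site_name) {
  m <- .site_masses[site_name]
  m[is.na(m)] <- 12.011
  unname(m)
}

# Center of mass per (frame, molecule) for particles `sel` (a filtered
# particle tibble). xy are averaged with minimum-image unwrapping relative
# to the first particle of each molecule so molecules straddling the x/y
# boundary get a sensible com. Vectorised via rowsum over a group key.
.molecule_com <- function(sel, box, z_periodic = FALSE) {
  key <- factor(paste(sel$frame, sel$molecule_id, sep = "\r"),
                levels = unique(paste(sel$frame, sel$molecule_id,
                                      sep = "\r")))
  m <- .mass_of(sel$site_name)
  first <- !duplicated(key)
  ref <- match(key, key[first])
  x0 <- sel$x[first][ref]
  y0 <- sel$y[first][ref]
  dx <- sel$x - x0
  dy <- sel$y - y0
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  sm <- rowsum(m, key)
  comx <- .wrap(sel$x[first] + rowsum(m * dx, key) / sm, box[1])
  comy <- .wrap(sel$y[first] + rowsum(m * dy, key) / sm, box[2])
  comz <- if (z_periodic) {
    dz <- sel$z - sel$z[first][ref]
    dz <- dz - box[3] * round(dz / box[3])
    .wrap(sel$z[first] + rowsum(m * dz, key) / sm, box[3])
  } else {
    rowsum(m * sel$z, key) / sm
  }
  tibble(
    frame = sel$frame[first],
    time = sel$time[first],
    molecule_id = sel$molecule_id[first],
    x = as.numeric(comx), y = as.numeric(comy), z = as.numeric(comz),
    half = if ("half" %in% names(sel)) sel$half[first] else NA_integer_)
}
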