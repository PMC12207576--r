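# Hand-built fixtures and independent brute-force oracles shared across the
# suite. The oracles deliberately use naive all-pairs / explicit-image loops
# so they stay independent of the package's distance routines.

`%||%` <- function(a, b) if (is.null(a)) b else a

default_box <- c(4, 4, 10.93)
default_planes <- c(0.465, 10.465)

# frames from a compact spec: df columns site_name, role, molecule_id, x, y,
# z (+ optional frame, time); particle ids assigned in row order per frame
make_frames <- function(df, box = default_box, planes = default_planes,
                        geometry = "slab") {
  df <- tibble::as_tibble(df)
  if (!"frame" %in% names(df)) df$frame <- 1L
  if (!"time" %in% names(df)) df$time <- (df$frame - 1) * 0.1
  df <- df |>
    dplyr::group_by(frame) |>
    dplyr::mutate(particle_id = dplyr::row_number()) |>
    dplyr::ungroup()
  slitpore_frames(df, box = box,
                  surface_planes = if (geometry == "slab") planes else NULL,
                  geometry = geometry)
}

# one-bead analyte molecules at given folded-z positions on the lower surface
point_analytes <- function(z, x = NULL, y = NULL, frame = 1L,
                           box = default_box, planes = default_planes) {
  n <- length(z)
  tibble::tibble(
    site_name = "O", role = "analyte", molecule_id = seq_len(n),
    x = x %||% runif(n) * box[1], y = y %||% runif(n) * box[2],
    z = planes[1] + z, frame = frame)
}

point_topology <- function(n, compound = "probe", donors = FALSE) {
  topology(
    molecule_id = seq_len(n), compound = compound, role = "analyte",
    particle_ids = as.list(seq_len(n)),
    donor_ids = if (donors) as.list(seq_len(n))
                else replicate(n, integer(0), simplify = FALSE),
    acceptor_ids = if (donors) replicate(n, integer(0), simplify = FALSE)
                   else as.list(seq_len(n)))
}

# explicit-image minimum distance: loops over the 9 xy images (slab) or the
# 27 xyz images (bulk)
brute_dist <- function(p, q, box, geometry = "slab") {
  shifts <- if (geometry == "slab") {
    expand.grid(ix = -1:1, iy = -1:1, iz = 0)
  } else {
    expand.grid(ix = -1:1, iy = -1:1, iz = -1:1)
  }
  best <- Inf
  for (k in seq_len(nrow(shifts))) {
    d <- sqrt(sum((p - q + c(shifts$ix[k] * box[1], shifts$iy[k] * box[2],
                             shifts$iz[k] * box[3]))^2))
    best <- min(best, d)
  }
  best
}

# brute-force bonded-phase contact count in LAB coordinates
brute_contacts <- function(frames, molecule_id, frame, r_bp) {
  p <- frames$particles[frames$particles$frame == frame, ]
  an <- p[p$molecule_id == molecule_id & p$role == "analyte", ]
  m <- vapply(an$site_name, function(s) {
    switch(s, CH3 = 15.035, CH2 = 14.027, O = 15.999, HO = 1.008, 12.011)
  }, numeric(1))
  com <- c(sum(m * an$x), sum(m * an$y), sum(m * an$z)) / sum(m)
  beads <- p[p$role == "bonded_phase", ]
  n <- 0L
  for (i in seq_len(nrow(beads))) {
    d <- brute_dist(com, c(beads$x[i], beads$y[i], beads$z[i]), frames$box,
                    frames$geometry)
    if (d <= r_bp) n <- n + 1L
  }
  n
}

# brute-force hydrogen-bond count over all (site, solvent atom) pairs
brute_hbond_count <- function(frames, top, criteria) {
  total <- 0L
  sp_of <- c(OW = "W", HW1 = "W", HW2 = "W", O_Me = "MeOH", H_Me = "MeOH",
             CH3_Me = "MeOH", N_ACN = "ACN", C_ACN = "ACN",
             CH3_ACN = "ACN")
  for (fr in unique(frames$particles$frame)) {
    p <- frames$particles[frames$particles$frame == fr, ]
    an_top <- top[top$role == "analyte", ]
    solv <- p[p$role %in% c("water", "organic_solvent"), ]
    for (i in seq_len(nrow(an_top))) {
      sites <- list()
      for (id in an_top$donor_ids[[i]]) {
        q <- p[p$particle_id == id, ]
        sites[[length(sites) + 1]] <- list(class = "donor",
                                           xyz = c(q$x, q$y, q$z))
      }
      for (id in an_top$acceptor_ids[[i]]) {
        q <- p[p$particle_id == id, ]
        sites[[length(sites) + 1]] <- list(class = "acceptor",
                                           xyz = c(q$x, q$y, q$z))
      }
      for (ring in an_top$ring_ids[[i]]) {
        q <- p[p$particle_id %in% ring, ]
        sites[[length(sites) + 1]] <- list(
          class = "pi", xyz = c(mean(q$x), mean(q$y), mean(q$z)))
      }
      for (s in sites) {
        # one bond at most per (site, solvent molecule)
        for (mol in unique(solv$molecule_id)) {
          atoms <- solv[solv$molecule_id == mol, ]
          bonded <- FALSE
          for (j in seq_len(nrow(atoms))) {
            sp <- sp_of[[atoms$site_name[j]]]
            atype <- if (atoms$site_name[j] %in% c("HW1", "HW2", "H_Me")) "H"
                     else if (atoms$site_name[j] %in%
                              c("OW", "O_Me", "N_ACN")) "key" else "none"
            if (atype == "none") next
            crit <- criteria[criteria$site_class == s$class &
                               criteria$species == sp &
                               criteria$partner_atom == atype, ]
            if (nrow(crit) == 0) next
            d <- brute_dist(s$xyz, c(atoms$x[j], atoms$y[j], atoms$z[j]),
                            frames$box, frames$geometry)
            if (d <= crit$r_hb[1]) bonded <- TRUE
          }
          if (bonded) total <- total + 1L
        }
      }
    }
  }
  total
}

# contact profile object from hand values (bins at 0.05 nm centers)
make_contact_profile <- function(z, c_bp, n = NULL) {
  out <- tibble::tibble(z = z, c_bp = c_bp, n = n %||% rep(10L, length(z)))
  attr(out, "bin_width") <- if (length(z) > 1) diff(z)[1] else 0.05
  attr(out, "r_bp") <- 0.8
  attr(out, "window") <- 40
  class(out) <- c("contact_profile", class(out))
  out
}

make_density_profile <- function(z, density, area = 16, bin = 0.05) {
  out <- tibble::tibble(z = z, density = density,
                        n = round(density * area * bin * 2))
  attr(out, "bin_width") <- bin
  attr(out, "area") <- area
  attr(out, "n_frames") <- 1L
  attr(out, "n_surfaces") <- 2L
  attr(out, "species") <- "test"
  class(out) <- c("density_profile", class(out))
  out
}

make_hbond_profile <- function(z, hb_total, n_visits = NULL) {
  out <- tibble::tibble(
    z = z, hb_functional = hb_total, hb_pi = 0, hb_total = hb_total,
    n_visits = n_visits %||% rep(10L, length(z)))
  attr(out, "bin_width") <- if (length(z) > 1) diff(z)[1] else 0.05
  class(out) <- c("hbond_profile", class(out))
  out
}

make_decomposition <- function(boundary_z, z_sp, surface_z_max = 0.55) {
  structure(list(boundary_z = boundary_z, surface_z_max = surface_z_max,
                 z_sp = z_sp,
                 fractions = c(surface = 0, partitioning = 0.5,
                               adsorption = 0.5),
                 adsorption_fraction = 0.5,
                 partitioning_fraction_two_way = 0.5),
            class = "peak_decomposition")
}
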