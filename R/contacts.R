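# Bonded-phase contact statistics: contact counting within r_BP, contact
# profiles over observation windows, the stationary-phase limit z_SP, and
# the density-weighted stationary-phase averages.

# bonded-phase site positions of one folded frames object
.bp_sites <- function(frames, include_endcap = FALSE) {
  roles <- if (include_endcap) c("bonded_phase", "endcap") else "bonded_phase"
  frames$particles |> filter(.data$role %in% roles)
}

# per-(frame, molecule) bonded-phase contact counts for all analyte
# molecules: the workhorse behind count_contacts() and contact_profile()
.contact_table <- function(frames, r_bp, include_endcap = FALSE) {
  stopifnot(inherits(frames, "slitpore_frames"))
  frames <- fold_to_surface(frames)
  pw <- 2 * pore_half_width(frames)
  an <- frames$particles |> filter(.data$role == "analyte")
  if (nrow(an) == 0) abort("no analyte molecules in frames")
  coms <- .molecule_com(an, frames$box)
  beads_all <- .bp_sites(frames, include_endcap)
  purrr::map_dfr(split(coms, coms$frame), function(cm) {
    fb <- beads_all |> filter(.data$frame == cm$frame[1])
    if (nrow(fb) == 0) {
      return(mutate(cm, contacts = 0L))
    }
    d <- min_image_dist(as.matrix(cm[, c("x", "y", "z")]),
                        as.matrix(fb[, c("x", "y", "z")]),
                        frames$box, geometry = "slab",
                        halves_p = cm$half, halves_q = fb$half,
                        pore_width = pw)
    mutate(cm, contacts = as.integer(rowSums(d <= r_bp)))
  })
}

#' Count bonded-phase contacts of one analyte molecule
#'
#' Number of bonded-phase united-atom sites within `r <= r_bp` (boundary
#' inclusive) of the analyte's center of mass, with minimum-image distances
#' in x,y. Endcap and residual-OH sites are excluded unless
#' `include_endcap = TRUE`.
#'
#' @param frames A slab `slitpore_frames` object.
#' @param molecule_id Analyte molecule id.
#' @param frame Frame index.
#' @param r_bp Contact radius (nm).
#' @param include_endcap Count endcap sites as bonded phase?
#' @return Integer contact count (zero is a valid count).
#' @export
count_contacts <- function(frames, molecule_id, frame = 1L, r_bp,
                           include_endcap = FALSE) {
  frames <- fold_to_surface(frames)
  sub <- frames
  sub$particles <- frames$particles |> filter(.data$frame == !!frame)
  if (nrow(sub$particles) == 0) abort(paste0("no frame ", frame))
  tab <- .contact_table(sub, r_bp, include_endcap)
  row <- tab |> filter(.data$molecule_id == !!molecule_id)
  if (nrow(row) == 0) abort(paste0("no analyte molecule ", molecule_id))
  row$contacts
}

#' Bonded-phase contact profile C_BP(z)
#'
#' Mean number of bonded-phase contacts per analyte molecule at distance z
#' from the surface, from 0.05 nm bins of the analyte center-of-mass
#' position. Frames are grouped into non-overlapping observation windows by
#' timestamp (default 40 ns, the window over which "on average one contact"
#' defines the stationary-phase limit); per-bin means are formed within
#' each complete window and then averaged over windows. Partial trailing
#' windows are dropped. Bins never visited by an analyte are missing (NA),
#' not zero.
#'
#' @param frames A slab `slitpore_frames` object.
#' @param r_bp Contact radius (nm).
#' @param window Observation window (ns).
#' @param regions A [region_spec()] (bin width).
#' @param include_endcap Count endcap sites as bonded phase?
#' @return A `contact_profile` tibble: `z`, `c_bp`, `n` (visits).
#' @export
contact_profile <- function(frames, r_bp, window = 40,
                            regions = region_spec(),
                            include_endcap = FALSE) {
  frames <- fold_to_surface(frames)
  times <- sort(unique(frames$particles$time))
  dt <- if (length(times) > 1) min(diff(times)) else 0
  span <- diff(range(times)) + dt
  if (span < window) {
    abort(paste0("frames span ", signif(span, 4), " ns < one observation ",
                 "window (", window, " ns); use a smaller window"))
  }
  tab <- .contact_table(frames, r_bp, include_endcap)
  bin <- regions$bin_width
  hw <- pore_half_width(frames)
  centers <- .bin_centers(hw, bin)
  tab <- tab |>
    mutate(win = floor((.data$time - min(times)) / window),
           bin_i = pmin(floor(.data$z / bin) + 1L, length(centers))) |>
    filter(.data$win < floor(span / window))
  per_win <- tab |>
    group_by(.data$win, .data$bin_i) |>
    summarise(c_bp = mean(.data$contacts), n = n(), .groups = "drop")
  prof <- per_win |>
    group_by(.data$bin_i) |>
    summarise(c_bp = mean(.data$c_bp), n = sum(.data$n), .groups = "drop")
  out <- tibble(z = centers,
                c_bp = NA_real_,
                n = 0L)
  out$c_bp[prof$bin_i] <- prof$c_bp
  out$n[prof$bin_i] <- prof$n
  attr(out, "bin_width") <- bin
  attr(out, "r_bp") <- r_bp
  attr(out, "window") <- window
  class(out) <- c("contact_profile", class(out))
  out
}

#' Stationary-phase limit z_SP
#'
#' The distance from the silica surface beyond which an analyte molecule
#' has, on average, less than one bonded-phase contact per observation
#' window. Scanning outward, z_SP is the linear interpolation of the
#' C_BP = 1 crossing between the outermost bin with C_BP >= 1 and the next
#' non-missing bin (all non-missing bins beyond it satisfy C_BP < 1);
#' plateaus at exactly 1 resolve outward.
#'
#' @param profile A `contact_profile`.
#' @return z_SP in nm.
#' @export
stationary_phase_limit <- function(profile) {
  stopifnot(inherits(profile, "contact_profile"))
  ok <- !is.na(profile$c_bp)
  z <- profile$z[ok]
  c_bp <- profile$c_bp[ok]
  if (length(c_bp) == 0) abort("contact profile has no visited bins")
  if (all(c_bp < 1)) {
    abort("no stationary phase: C_BP < 1 everywhere")
  }
  if (all(c_bp >= 1)) {
    abort("truncated profile: C_BP >= 1 everywhere (pore too small)")
  }
  i <- max(which(c_bp >= 1))
  if (i == length(c_bp)) {
    abort("truncated profile: outermost visited bin still has C_BP >= 1")
  }
  if (any(c_bp[(i + 1):length(c_bp)] >= 1)) {
    # cannot happen: i is the last index with c_bp >= 1
    abort("internal error in crossing search")
  }
  z[i] + (z[i + 1] - z[i]) * (c_bp[i] - 1) / (c_bp[i] - c_bp[i + 1])
}

#' Stationary-phase averages of contacts and analyte position
#'
#' Density-weighted averages over z <= z_SP:
#' `mean_contacts = sum(C_BP(z) rho(z)) / sum(rho(z))` and likewise
#' `mean_position` with z in place of C_BP. A bin with analyte density but
#' a missing contact value is an error (the two profiles must come from the
#' same sampling).
#'
#' @param contact_profile A `contact_profile`.
#' @param analyte_density A `density_profile` of the analyte on the same
#'   bins.
#' @param z_sp Stationary-phase limit (nm).
#' @return A `stationary_phase_summary` object.
#' @export
stationary_phase_summary <- function(contact_profile, analyte_density,
                                     z_sp) {
  stopifnot(inherits(contact_profile, "contact_profile"),
            inherits(analyte_density, "density_profile"))
  j <- dplyr::inner_join(
    tibble(z = round(contact_profile$z, 6), c_bp = contact_profile$c_bp),
    tibble(z = round(analyte_density$z, 6), rho = analyte_density$density),
    by = "z")
  if (nrow(j) == 0) abort("profiles have no common bins")
  j <- j |> filter(.data$z <= z_sp)
  if (sum(j$rho) <= 0) {
    abort("undefined average: zero analyte density at z <= z_sp")
  }
  if (any(is.na(j$c_bp) & j$rho > 0)) {
    abort("missing contact bins with nonzero analyte density")
  }
  w <- j$rho / sum(j$rho)
  mean_c <- sum(w * j$c_bp, na.rm = TRUE)
  structure(list(
    z_sp = z_sp,
    mean_contacts = mean_c,
    mean_position = sum(w * j$z),
    sd_contacts = sqrt(sum(w * (j$c_bp - mean_c)^2, na.rm = TRUE))
  ), class = "stationary_phase_summary")
}

#' @export
print.stationary_phase_summary <- function(x, ...) {
  cat("<stationary_phase_summary>\n")
  cat(sprintf("  z_SP = %.3f nm | <C_BP>_SP = %.3f (sd %.3f) | <z>_SP = %.3f nm\n",
              x$z_sp, x$mean_contacts, x$sd_contacts, x$mean_position))
  invisible(x)
}

#' @export
tidy.stationary_phase_summary <- function(x, ...) {
  tibble(statistic = c("z_sp", "mean_contacts", "sd_contacts",
                       "mean_position"),
         value = c(x$z_sp, x$mean_contacts, x$sd_contacts, x$mean_position))
}

#' @export
glance.stationary_phase_summary <- function(x, ...) {
  tibble(z_sp = x$z_sp, mean_contacts = x$mean_contacts,
         sd_contacts = x$sd_contacts, mean_position = x$mean_position)
}

#' Analyte-to-bonded-phase radial distribution function
#'
#' g(r) between analyte centers of mass and bonded-phase united-atom sites,
#' normalised by the mean bonded-phase site density within the bonded-phase
#' region (z <= z_bp_end). In this strongly inhomogeneous slab only the
#' location of the first minimum is meaningful; it supplies r_BP via
#' [derive_rbp()].
#'
#' @param frames A slab `slitpore_frames` object.
#' @param r_max,dr RDF range and bin width (nm).
#' @param regions A [region_spec()] (bonded-phase extent for the reference
#'   density).
#' @param include_endcap Count endcap sites as bonded phase?
#' @return An `rdf` tibble with columns `r`, `g`.
#' @export
analyte_bp_rdf <- function(frames, r_max = 1.5, dr = 0.01,
                           regions = region_spec(), include_endcap = FALSE) {
  frames <- fold_to_surface(frames)
  pw <- 2 * pore_half_width(frames)
  an <- frames$particles |> filter(.data$role == "analyte")
  if (nrow(an) == 0) abort("no analyte molecules in frames")
  coms <- .molecule_com(an, frames$box)
  beads_all <- .bp_sites(frames, include_endcap)
  if (nrow(beads_all) == 0) abort("no bonded-phase sites in frames")
  edges <- seq(0, r_max, by = dr)
  counts <- numeric(length(edges) - 1)
  n_com <- 0L
  for (fr in unique(coms$frame)) {
    cm <- coms |> filter(.data$frame == fr)
    fb <- beads_all |> filter(.data$frame == fr)
    d <- min_image_dist(as.matrix(cm[, c("x", "y", "z")]),
                        as.matrix(fb[, c("x", "y", "z")]),
                        frames$box, geometry = "slab",
                        halves_p = cm$half, halves_q = fb$half,
                        pore_width = pw)
    counts <- counts + tabulate(pmin(floor(d / dr) + 1L,
                                     length(edges) - 1L)[d < r_max],
                                nbins = length(edges) - 1L)
    n_com <- n_com + nrow(cm)
  }
  n_frames <- dplyr::n_distinct(frames$particles$frame)
  rho_ref <- nrow(beads_all) / n_frames /
    (frames$box[1] * frames$box[2] * regions$z_bp_end * 2)
  r_mid <- edges[-length(edges)] + dr / 2
  g <- counts / (n_com * 4 * pi * r_mid^2 * dr * rho_ref)
  out <- tibble(r = r_mid, g = g)
  class(out) <- c("rdf", class(out))
  out
}

#' Derive the contact radius r_BP from RDFs
#'
#' Averages the supplied RDFs pointwise, smooths with a 3-bin moving
#' average, and returns the position of the first local minimum after the
#' global maximum, rounded to 0.01 nm. For the six ensemble compounds the
#' trajectory-derived radii are shipped in [rbp_reference()]; this routine
#' serves synthetic or novel systems.
#'
#' @param rdfs An `rdf` tibble or a list of them on a common r grid.
#' @return r_BP in nm.
#' @export
derive_rbp <- function(rdfs) {
  if (inherits(rdfs, "rdf")) rdfs <- list(rdfs)
  r <- rdfs[[1]]$r
  for (x in rdfs) {
    if (length(x$r) != length(r) || any(abs(x$r - r) > 1e-9)) {
      abort("RDFs must share one r grid")
    }
  }
  g <- rowMeans(do.call(cbind, lapply(rdfs, `[[`, "g")))
  s <- as.numeric(stats::filter(g, rep(1 / 3, 3), sides = 2))
  s[is.na(s)] <- g[is.na(s)]
  m <- which.max(s)
  for (i in (m + 1):(length(s) - 1)) {
    if (s[i] <= s[i - 1] && s[i] < s[i + 1]) {
      return(round(r[i], 2))
    }
  }
  abort("no local minimum after the first maximum (monotone RDF?)")
}
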