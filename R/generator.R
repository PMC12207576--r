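# Synthetic slit-pore ensembles with fully known ground truth. Frames are
# i.i.d. samples, not dynamics: every estimator in the package is a time
# average over configurations, so independent sampling suffices; timestamps
# t = i * frame_dt keep the observation-window bookkeeping meaningful.

# ---- low-level samplers ----------------------------------------------------

.unit <- function(v) v / sqrt(sum(v^2))

# orthonormal basis (e1, e2) perpendicular to unit axis a
.perp_basis <- function(a) {
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- .unit(ref - sum(ref * a) * a)
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  cbind(e1, e2)
}

# one direction uniform in the spherical cone of half-angle `half` around axis
.runif_cone <- function(axis, half = pi) {
  axis <- .unit(axis)
  cth <- runif(1, cos(half), 1)
  sth <- sqrt(1 - cth^2)
  phi <- runif(1, 0, 2 * pi)
  b <- .perp_basis(axis)
  cth * axis + sth * (cos(phi) * b[, 1] + sin(phi) * b[, 2])
}

# rotate unit vector `from` (+z by convention) onto `to` with a uniform roll
.orient_frame <- function(axis) {
  axis <- .unit(axis)
  b <- .perp_basis(axis)
  roll <- runif(1, 0, 2 * pi)
  e1 <- cos(roll) * b[, 1] + sin(roll) * b[, 2]
  e2 <- -sin(roll) * b[, 1] + cos(roll) * b[, 2]
  cbind(e1, e2, axis) # columns: local x, y, z in lab coordinates
}

# truncated-Gaussian mixture sampler on [lower, upper]; returns z and the
# component label of each draw
.rtrunc_mix <- function(n, weights, means, sds, lower, upper) {
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  plo <- stats::pnorm(lower, means[comp], sds[comp])
  phi <- stats::pnorm(upper, means[comp], sds[comp])
  z <- stats::qnorm(runif(n, plo, phi), means[comp], sds[comp])
  list(z = pmin(pmax(z, lower), upper), component = comp)
}

# mean of the truncated-linear orientation density f(c) ~ max(0, 1 + b c)
.coslin_mean <- function(b) {
  if (abs(b) <= 1) return(b / 3)
  s <- sign(b); b <- abs(b)
  zc <- 1 + b / 2 + 1 / (2 * b)
  s * (0.5 + b / 3 - 1 / (6 * b^2)) / zc
}

.coslin_b <- function(m) {
  if (abs(m) < 1e-12) return(0)
  if (abs(m) > 0.6) abort("orientation mean |cos phi| must be <= 0.6")
  if (abs(m) <= 1 / 3) return(3 * m)
  s <- sign(m)
  s * uniroot(function(b) .coslin_mean(b) - abs(m), c(1, 1e4))$root
}

# inverse-CDF sampler for f(c) ~ max(0, 1 + b c) on [-1, 1]
.rcos_linear <- function(n, m) {
  if (n == 0) return(numeric(0))
  b <- vapply(m, .coslin_b, numeric(1))
  u <- runif(n)
  lo <- ifelse(b > 1, -1 / b, -1)
  hi <- ifelse(b < -1, 1 / abs(b), 1)
  z_tot <- (hi + b * hi^2 / 2) - (lo + b * lo^2 / 2)
  out <- numeric(n)
  lin <- abs(b) < 1e-9
  out[lin] <- -1 + 2 * u[lin]
  i <- !lin
  a_coef <- lo[i] + b[i] * lo[i]^2 / 2 + u[i] * z_tot[i]
  out[i] <- (-1 + sqrt(pmax(1 + 2 * b[i] * a_coef, 0))) / b[i]
  pmin(pmax(out, -1), 1)
}

# ---- analyte templates -----------------------------------------------------

# local coordinates (nm): molecular axis along +z; ring(s) in the x-z plane.
# Bond geometry is schematic but the site separations are what the
# hydrogen-bond criteria see, so they are chosen large enough that partner
# placement can always avoid unintended bonds.
.hexagon <- function(cx = 0, r = 0.139, phase = 0) {
  th <- phase + seq(0, 300, by = 60) * pi / 180
  cbind(cx + r * cos(th), 0, r * sin(th))
}

.analyte_template <- function(compound, n_sites = 1L) {
  ring1 <- .hexagon()
  tpl <- switch(
    compound,
    benzene = list(
      particles = tibble(site_name = rep("C_ar", 6), element = "C",
                         lx = ring1[, 1], ly = ring1[, 2], lz = ring1[, 3]),
      ring_sets = list(1:6), donor_idx = integer(0),
      acceptor_idx = integer(0), vector_head_idx = NA_integer_),
    naphthalene = {
      r1 <- .hexagon(cx = 0.1204, phase = pi / 6)
      r2 <- .hexagon(cx = -0.1204, phase = pi / 6)
      shared <- which(abs(r1[, 1]) < 1e-9)
      keep2 <- setdiff(seq_len(6), which(abs(r2[, 1]) < 1e-9))
      xyz <- rbind(r1, r2[keep2, ])
      ring2_idx <- c(shared, 6 + seq_along(keep2))
      list(
        particles = tibble(site_name = rep("C_ar", nrow(xyz)), element = "C",
                           lx = xyz[, 1], ly = xyz[, 2], lz = xyz[, 3]),
        ring_sets = list(1:6, ring2_idx), donor_idx = integer(0),
        acceptor_idx = integer(0), vector_head_idx = NA_integer_)
    },
    ethylbenzene = list(
      particles = tibble(
        site_name = c(rep("C_ar", 6), "CH2", "CH3"),
        element = c(rep("C", 8)),
        lx = c(ring1[, 1], 0, 0), ly = 0,
        lz = c(ring1[, 3], 0.25, 0.40)),
      ring_sets = list(1:6), donor_idx = integer(0),
      acceptor_idx = integer(0), vector_head_idx = 8L),
    phenol = list(
      particles = tibble(
        site_name = c(rep("C_ar", 6), "O", "HO"),
        element = c(rep("C", 6), "O", "H"),
        lx = c(ring1[, 1], 0, 0), ly = 0,
        lz = c(ring1[, 3], 0.36, 0.46)),
      ring_sets = list(1:6), donor_idx = 8L, acceptor_idx = 7L,
      vector_head_idx = 7L),
    benzyl_alcohol = list(
      particles = tibble(
        site_name = c(rep("C_ar", 6), "CH2", "O", "HO"),
        element = c(rep("C", 7), "O", "H"),
        lx = c(ring1[, 1], 0, 0, 0), ly = 0,
        lz = c(ring1[, 3], 0.25, 0.42, 0.52)),
      ring_sets = list(1:6), donor_idx = 9L, acceptor_idx = 8L,
      vector_head_idx = 8L),
    acetophenone = list(
      particles = tibble(
        site_name = c(rep("C_ar", 6), "C", "O", "CH3"),
        element = c(rep("C", 7), "O", "C"),
        lx = c(ring1[, 1], 0, 0, 0.13), ly = 0,
        lz = c(ring1[, 3], 0.25, 0.40, 0.31)),
      ring_sets = list(1:6), donor_idx = integer(0), acceptor_idx = 8L,
      vector_head_idx = 8L),
    probe = list(
      # abstract calibration solute: acceptor beads spaced 0.9 nm apart so
      # partner shells can never overlap a second site
      particles = tibble(
        site_name = rep("O", n_sites), element = "O",
        lx = 0, ly = 0, lz = 0.9 * (seq_len(n_sites) - 1)),
      ring_sets = list(), donor_idx = integer(0),
      acceptor_idx = seq_len(n_sites), vector_head_idx = NA_integer_),
    abort(paste0("unknown compound template: ", compound))
  )
  # shift so the molecule's mass-weighted com sits at the local origin
  m <- .mass_of(tpl$particles$site_name)
  com <- c(sum(m * tpl$particles$lx), sum(m * tpl$particles$ly),
           sum(m * tpl$particles$lz)) / sum(m)
  tpl$particles$lx <- tpl$particles$lx - com[1]
  tpl$particles$ly <- tpl$particles$ly - com[2]
  tpl$particles$lz <- tpl$particles$lz - com[3]
  tpl$local_mat <- cbind(tpl$particles$lx, tpl$particles$ly,
                         tpl$particles$lz)
  tpl$has_vector <- !is.na(tpl$vector_head_idx)
  tpl
}

# ---- configuration ---------------------------------------------------------

#' Synthetic slit-pore generator configuration
#'
#' The defaults emulate the study geometry: a 12.14 x 13.20 x 10.93 nm box
#' forming a 10 nm slit pore, 10 analyte molecules, bonded-phase density
#' concentrated below 1.05 nm from the surface, water density declining from
#' its bulk plateau into the bonded phase, an organic-solvent density
#' maximum ("ditch") in the interfacial region, and an analyte density that
#' is a mixture of a silica-surface peak, a partitioning peak and an
#' adsorption peak. `scale_xy` shrinks the box cross-section (particle
#' counts scale with area, z-structure unchanged) for cheap sampling.
#'
#' @param compound Analyte template: one of the six ensemble compounds or
#'   `"probe"` (abstract single/multi-site calibration solute).
#' @param os_type Organic solvent, `"MeOH"` or `"ACN"`.
#' @param box Box lengths (nm). @param pore_width Pore width (nm).
#' @param scale_xy Multiplier applied to the x,y box lengths.
#' @param n_frames,frame_dt Number of frames and their time spacing (ns).
#' @param n_analyte Analyte molecules per frame.
#' @param n_probe_sites Acceptor sites of the probe template.
#' @param bp_sites_per_nm2 Bonded-phase united-atom sites per nm^2 of
#'   surface (both surfaces populated equally).
#' @param bonded_profile List: `weights`, `means`, `sds`, `zmax` of the
#'   truncated-Gaussian mixture for bonded-phase bead positions.
#' @param water_profile List: `bulk` (plateau density, molecules nm^-3),
#'   `z_mid`, `width` of the sigmoid rise toward bulk.
#' @param os_profile List: `bulk`, `z_mid`, `width`, `ditch_amp`,
#'   `ditch_mean`, `ditch_sd`.
#' @param analyte_mixture List: `weights` (surface, partitioning,
#'   adsorption; sum to 1), `means`, `sds` (nm).
#' @param hb_engage_prob Function of folded z: probability that each
#'   donor/acceptor/pi site of an analyte is engaged by a partner.
#' @param w_weight Function of folded z: probability that an engaged
#'   partner is a water molecule (otherwise the organic solvent).
#' @param orientation_mean Function of folded z: mean of the
#'   truncated-linear cos(phi) density (|mean| <= 0.6); positive values
#'   orient the molecular vector toward the bulk liquid.
#' @param n_water,n_os Solvent molecule counts; `NULL` derives them from the
#'   profile integrals over the pore volume.
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#' @return A `slitpore_config` object.
#' @export
slitpore_config <- function(
    compound = "phenol",
    os_type = c("MeOH", "ACN"),
    box = c(12.14, 13.20, 10.93),
    pore_width = 10,
    scale_xy = 1,
    n_frames = 10L,
    frame_dt = 0.1,
    n_analyte = 10L,
    n_probe_sites = 1L,
    bp_sites_per_nm2 = 33.7,
    bonded_profile = list(weights = c(0.6, 0.4), means = c(0.45, 0.85),
                          sds = c(0.25, 0.30), zmax = 1.6),
    water_profile = list(bulk = 9.2, z_mid = 1.0, width = 0.25),
    os_profile = list(bulk = 6.8, z_mid = 0.8, width = 0.25,
                      ditch_amp = 4.0, ditch_mean = 1.3, ditch_sd = 0.25),
    analyte_mixture = list(weights = c(surface = 0.03, partitioning = 0.07,
                                       adsorption = 0.90),
                           means = c(0.50, 0.85, 1.60),
                           sds = c(0.05, 0.15, 0.25)),
    hb_engage_prob = function(z) 0.8 * stats::plogis((z - 1.0) / 0.3),
    w_weight = function(z) rep(0.7, length(z)),
    orientation_mean = function(z) 0.4 * tanh((z - 0.9) / 0.3),
    n_water = NULL,
    n_os = NULL,
    seed = 1L) {
  os_type <- match.arg(os_type)
  box <- c(box[1] * scale_xy, box[2] * scale_xy, box[3])
  if (pore_width >= box[3]) abort("pore_width must be smaller than Lz")
  hw <- pore_width / 2
  w <- analyte_mixture$weights
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    abort("analyte mixture weights must be nonnegative and sum to 1")
  }
  if (any(analyte_mixture$means < 0 | analyte_mixture$means > hw)) {
    abort("analyte mixture component means must lie in [0, pore/2]")
  }
  zg <- seq(0, hw, by = 0.01)
  wp <- function(z) water_profile$bulk *
    stats::plogis((z - water_profile$z_mid) / water_profile$width)
  op <- function(z) os_profile$bulk *
    stats::plogis((z - os_profile$z_mid) / os_profile$width) +
    os_profile$ditch_amp *
    exp(-(z - os_profile$ditch_mean)^2 / (2 * os_profile$ditch_sd^2))
  if (any(wp(zg) < 0) || any(op(zg) < 0)) {
    abort("solvent profiles must be nonnegative")
  }
  area <- box[1] * box[2]
  n_bonded <- as.integer(round(2 * area * bp_sites_per_nm2 / 18) * 18)
  cfg <- structure(list(
    compound = compound, os_type = os_type, box = box,
    pore_width = pore_width, n_frames = as.integer(n_frames),
    frame_dt = frame_dt, n_analyte = as.integer(n_analyte),
    n_probe_sites = as.integer(n_probe_sites),
    n_bonded = n_bonded,
    bonded_profile = bonded_profile,
    water_profile = water_profile, os_profile = os_profile,
    water_fn = wp, os_fn = op,
    analyte_mixture = analyte_mixture,
    hb_engage_prob = hb_engage_prob, w_weight = w_weight,
    orientation_mean = orientation_mean,
    n_water = if (is.null(n_water)) {
      as.integer(round(2 * area * sum(wp(zg)) * 0.01))
    } else as.integer(n_water),
    n_os = if (is.null(n_os)) {
      as.integer(round(2 * area * sum(op(zg)) * 0.01))
    } else as.integer(n_os),
    seed = as.integer(seed)
  ), class = "slitpore_config")
  cfg
}

#' Named generator presets
#'
#' Ready-made configurations at a reduced box cross-section so that a full
#' pipeline run stays interactive. `"phenol-meoh50"` emulates a polar
#' analyte at 50 vol % MeOH (strong adsorption peak, occasional surface
#' peak); `"benzene-meoh50"` an apolar analyte (more partitioning density,
#' pi hydrogen bonds only); `"probe-flat"` the abstract calibration solute
#' with a z-independent engagement probability.
#'
#' @param name Preset name.
#' @param seed,n_frames Passed through to [slitpore_config()].
#' @return A `slitpore_config` object.
#' @export
slitpore_preset <- function(name = c("phenol-meoh50", "benzene-meoh50",
                                     "probe-flat"),
                            seed = 1L, n_frames = 40L) {
  name <- match.arg(name)
  switch(
    name,
    "phenol-meoh50" = slitpore_config(
      compound = "phenol", os_type = "MeOH", scale_xy = 0.35,
      n_frames = n_frames, seed = seed),
    "benzene-meoh50" = slitpore_config(
      compound = "benzene", os_type = "MeOH", scale_xy = 0.35,
      n_frames = n_frames, seed = seed,
      analyte_mixture = list(weights = c(surface = 0.0, partitioning = 0.35,
                                         adsorption = 0.65),
                             means = c(0.50, 0.70, 1.55),
                             sds = c(0.05, 0.18, 0.28))),
    "probe-flat" = slitpore_config(
      compound = "probe", os_type = "MeOH", scale_xy = 0.35,
      n_frames = n_frames, seed = seed,
      hb_engage_prob = function(z) rep(0.6, length(z)),
      orientation_mean = function(z) rep(0, length(z)))
  )
}

#' @export
print.slitpore_config <- function(x, ...) {
  cat("<slitpore_config> ", x$compound, " in W-", x$os_type, "\n", sep = "")
  cat("  box", paste(signif(x$box, 4), collapse = " x "), "nm, pore",
      x$pore_width, "nm,", x$n_frames, "frame(s) @", x$frame_dt, "ns\n")
  cat("  counts/frame:", x$n_analyte, "analyte,", x$n_bonded, "bonded-phase,",
      x$n_water, "W,", x$n_os, x$os_type, "\n")
  invisible(x)
}

# ---- partner construction with unintended-bond avoidance -------------------

# detection-relevant first atom per (site class, species)
.placed_atom <- function(class, species) {
  if (class == "donor") {
    switch(species, W = "OW", MeOH = "O_Me", ACN = "N_ACN")
  } else {
    switch(species, W = "HW1", MeOH = "H_Me",
           abort("ACN cannot donate to an acceptor/pi site"))
  }
}

# build a full partner molecule with its detection atom at `pos`, extending
# outward along `v`; returns matrix of positions + site names
.build_partner <- function(species, class, pos, v) {
  if (species == "W") {
    if (class == "donor") {
      o <- pos
      h1 <- o + 0.096 * .runif_cone(v, pi / 4)
      h2 <- o + 0.096 * .runif_cone(v, pi / 3)
      list(names = c("OW", "HW1", "HW2"), xyz = rbind(o, h1, h2))
    } else {
      h1 <- pos
      o <- h1 + 0.096 * .runif_cone(v, pi / 6)
      h2 <- o + 0.096 * .runif_cone(v, pi / 3)
      list(names = c("OW", "HW1", "HW2"), xyz = rbind(o, h1, h2))
    }
  } else if (species == "MeOH") {
    if (class == "donor") {
      o <- pos
      h <- o + 0.096 * .runif_cone(v, pi / 4)
      c3 <- o + 0.14 * .runif_cone(v, pi / 3)
      list(names = c("O_Me", "H_Me", "CH3_Me"), xyz = rbind(o, h, c3))
    } else {
      h <- pos
      o <- h + 0.096 * .runif_cone(v, pi / 6)
      c3 <- o + 0.14 * .runif_cone(v, pi / 3)
      list(names = c("O_Me", "H_Me", "CH3_Me"), xyz = rbind(o, h, c3))
    }
  } else {
    nn <- pos
    cc <- nn + 0.116 * .runif_cone(v, pi / 9)
    c3 <- cc + 0.146 * .unit(cc - nn)
    list(names = c("N_ACN", "C_ACN", "CH3_ACN"), xyz = rbind(nn, cc, c3))
  }
}

# Per-site cutoff lookup for one partner species: for every site in
# site_tbl, the cutoff its class assigns to H-type partner atoms and to
# key-type partner atoms (Inf where no bond is possible). This mirrors the
# detector's criteria exactly so the generator can re-check placements.
.site_cutoffs <- function(site_tbl, species, criteria) {
  crit <- criteria[criteria$species == species, ]
  r_h <- rep(-Inf, nrow(site_tbl))
  r_key <- rep(-Inf, nrow(site_tbl))
  for (j in seq_len(nrow(crit))) {
    hit <- site_tbl$site_class == crit$site_class[j]
    if (crit$partner_atom[j] == "H") r_h[hit] <- crit$r_hb[j]
    else r_key[hit] <- crit$r_hb[j]
  }
  list(r_h = r_h, r_key = r_key)
}

# would `cand` (partner molecule) bond any site other than the intended one
# (row `own`), or the intended site more than once?
.partner_clashes <- function(cand, site_xyz, cutoffs, own_row, box,
                             geometry) {
  is_h <- cand$names %in% c("HW1", "HW2", "H_Me")
  is_key <- cand$names %in% c("OW", "O_Me", "N_ACN")
  d <- min_image_dist(cand$xyz, site_xyz, box, geometry = geometry)
  bonded <- matrix(FALSE, nrow(d), ncol(d))
  if (any(is_h)) {
    bonded[is_h, ] <- sweep(d[is_h, , drop = FALSE], 2, cutoffs$r_h, "<=")
  }
  if (any(is_key)) {
    bonded[is_key, ] <- sweep(d[is_key, , drop = FALSE], 2, cutoffs$r_key,
                              "<=")
  }
  n_per_site <- colSums(bonded)
  # detection counts one bond per (site, molecule), so extra atoms of this
  # molecule reaching the intended site are harmless; bonds to any other
  # site are not
  if (n_per_site[own_row] < 1L) return(TRUE)
  any(n_per_site[-own_row] > 0L)
}

# place one engaged partner for site `own_row`; retries until no unintended
# criterion is met (rare failures are tallied by the caller, not fatal)
.place_partner <- function(site_tbl, site_xyz, cutoffs, own_row, species,
                           axis_dir, criteria, box, geometry = "slab",
                           max_try = 60L) {
  cls <- site_tbl$site_class[own_row]
  s <- site_xyz[own_row, ]
  crit <- criteria[criteria$site_class == cls & criteria$species == species, ]
  if (nrow(crit) == 0) abort(paste0("no criteria for class ", cls))
  r_hb <- crit$r_hb[1]
  cand <- NULL
  for (k in seq_len(max_try)) {
    v <- .runif_cone(axis_dir, pi / 7)
    u <- runif(1, 0, r_hb)
    cand <- .build_partner(species, cls, s + u * v, v)
    if (!.partner_clashes(cand, site_xyz, cutoffs, own_row, box, geometry)) {
      return(list(cand = cand, clean = TRUE))
    }
  }
  list(cand = cand, clean = FALSE)
}
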