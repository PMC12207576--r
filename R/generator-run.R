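# Frame assembly for the synthetic generator: topology layout, per-frame
# sampling, ground-truth bookkeeping.

# fast min-separation test for small site sets (periodic x,y; optionally z)
.min_sep_ok <- function(new_xyz, placed, box, z_periodic, cutoff) {
  c2 <- cutoff^2
  for (r in seq_len(nrow(new_xyz))) {
    dx <- placed[, 1] - new_xyz[r, 1]
    dx <- dx - box[1] * round(dx / box[1])
    dy <- placed[, 2] - new_xyz[r, 2]
    dy <- dy - box[2] * round(dy / box[2])
    dz <- placed[, 3] - new_xyz[r, 3]
    if (z_periodic) dz <- dz - box[3] * round(dz / box[3])
    if (any(dx * dx + dy * dy + dz * dz < c2)) return(FALSE)
  }
  TRUE
}

.runif_sphere_m <- function(n) {
  v <- matrix(rnorm(3 * n), n)
  v / sqrt(rowSums(v^2))
}

# inverse-CDF table for a nonnegative density on [0, hw]
.profile_sampler <- function(fn, hw) {
  z <- seq(0, hw, length.out = 2001)
  dens <- fn(z)
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  list(z = z, cdf = cdf)
}
.sample_profile <- function(n, tab) {
  if (n == 0) return(numeric(0))
  stats::approx(tab$cdf, tab$z, runif(n), ties = "ordered", rule = 2)$y
}

# particle/molecule id layout: beads, analytes, water, organic solvent
.system_layout <- function(cfg, tmpl) {
  np_an <- nrow(tmpl$particles)
  n_bead <- cfg$n_bonded
  bead_pids <- seq_len(n_bead)
  an_first <- n_bead + (seq_len(cfg$n_analyte) - 1L) * np_an + 1L
  an_pids <- lapply(an_first, function(s) s + 0:(np_an - 1L))
  w_start <- n_bead + cfg$n_analyte * np_an
  w_pids <- lapply(seq_len(cfg$n_water), function(k) w_start + (k - 1L) * 3L + 1:3)
  o_start <- w_start + cfg$n_water * 3L
  o_pids <- lapply(seq_len(cfg$n_os), function(k) o_start + (k - 1L) * 3L + 1:3)
  list(
    bead_pids = bead_pids,
    bead_mids = seq_len(n_bead),
    an_pids = an_pids,
    an_mids = n_bead + seq_len(cfg$n_analyte),
    w_pids = w_pids,
    w_mids = n_bead + cfg$n_analyte + seq_len(cfg$n_water),
    o_pids = o_pids,
    o_mids = n_bead + cfg$n_analyte + cfg$n_water + seq_len(cfg$n_os)
  )
}

.os_site_names <- function(os_type) {
  if (os_type == "MeOH") c("O_Me", "H_Me", "CH3_Me")
  else c("N_ACN", "C_ACN", "CH3_ACN")
}

.system_topology <- function(cfg, tmpl, lay) {
  n_bead <- cfg$n_bonded
  os_names <- .os_site_names(cfg$os_type)
  an_rows <- lapply(seq_len(cfg$n_analyte), function(i) {
    pid <- lay$an_pids[[i]]
    list(
      molecule_id = lay$an_mids[i], compound = cfg$compound,
      role = "analyte", particle_ids = pid,
      ring_ids = lapply(tmpl$ring_sets, function(r) pid[r]),
      donor_ids = pid[tmpl$donor_idx], acceptor_ids = pid[tmpl$acceptor_idx],
      vector_tail_id = if (tmpl$has_vector) 0L else NA_integer_,
      vector_head_id = if (tmpl$has_vector) pid[tmpl$vector_head_idx]
                       else NA_integer_
    )
  })
  topology(
    molecule_id = c(lay$bead_mids, lay$an_mids, lay$w_mids, lay$o_mids),
    compound = c(rep("C18", n_bead), rep(cfg$compound, cfg$n_analyte),
                 rep("W", cfg$n_water), rep(cfg$os_type, cfg$n_os)),
    role = c(rep("bonded_phase", n_bead), rep("analyte", cfg$n_analyte),
             rep("water", cfg$n_water),
             rep("organic_solvent", cfg$n_os)),
    particle_ids = c(as.list(lay$bead_pids), lay$an_pids, lay$w_pids,
                     lay$o_pids),
    ring_ids = c(replicate(n_bead, list(), simplify = FALSE),
                 lapply(an_rows, `[[`, "ring_ids"),
                 replicate(cfg$n_water + cfg$n_os, list(), simplify = FALSE)),
    donor_ids = c(replicate(n_bead, integer(0), simplify = FALSE),
                  lapply(an_rows, `[[`, "donor_ids"),
                  replicate(cfg$n_water + cfg$n_os, integer(0),
                            simplify = FALSE)),
    acceptor_ids = c(replicate(n_bead, integer(0), simplify = FALSE),
                     lapply(an_rows, `[[`, "acceptor_ids"),
                     replicate(cfg$n_water + cfg$n_os, integer(0),
                               simplify = FALSE)),
    vector_tail_id = c(rep(NA_integer_, n_bead),
                       vapply(an_rows, `[[`, integer(1), "vector_tail_id"),
                       rep(NA_integer_, cfg$n_water + cfg$n_os)),
    vector_head_id = c(rep(NA_integer_, n_bead),
                       vapply(an_rows, `[[`, integer(1), "vector_head_id"),
                       rep(NA_integer_, cfg$n_water + cfg$n_os))
  )
}

# hydrogen-bond site list of one placed analyte: donor/acceptor sites get
# outward approach cones (rotated +-35 deg apart when both exist), pi sites
# approach along the ring normal
.analyte_sites <- function(tmpl, pl, axis, i, pids) {
  both <- length(tmpl$donor_idx) > 0 && length(tmpl$acceptor_idx) > 0
  th <- 35 * pi / 180
  e1 <- pl$rot[, 1]
  mk <- function(idx, class, rotsign) {
    if (length(idx) == 0) return(NULL)
    adir <- if (both) .unit(cos(th) * axis + rotsign * sin(th) * e1)
            else axis
    lapply(idx, function(j) list(
      analyte = i, class = class, label = as.character(pids[j]),
      xyz = pl$pos[j, ], axis = adir))
  }
  s <- c(mk(tmpl$donor_idx, "donor", 1),
         mk(tmpl$acceptor_idx, "acceptor", -1))
  if (length(tmpl$ring_sets) > 0) {
    s <- c(s, lapply(seq_along(tmpl$ring_sets), function(r) list(
      analyte = i, class = "pi", label = paste0("pi", r),
      xyz = pl$ring_coms[[r]],
      axis = sample(c(-1, 1), 1) * pl$rot[, 2])))
  }
  s
}

# build one analyte's lab-frame particle matrix plus its site table
.place_analyte <- function(tmpl, com, axis) {
  rot <- .orient_frame(axis) # columns e1, e2, axis
  pos <- tmpl$local_mat %*% t(rot)
  pos[, 1] <- pos[, 1] + com[1]
  pos[, 2] <- pos[, 2] + com[2]
  pos[, 3] <- pos[, 3] + com[3]
  ring_coms <- lapply(tmpl$ring_sets,
                      function(r) colMeans(pos[r, , drop = FALSE]))
  list(pos = pos, rot = rot, ring_coms = ring_coms)
}

.solvent_block <- function(key_xyz, dirs1, dirs2, species, os_type) {
  if (species == "W") {
    nm <- c("OW", "HW1", "HW2")
    a2 <- key_xyz + 0.096 * dirs1
    a3 <- key_xyz + 0.096 * dirs2
  } else if (os_type == "MeOH") {
    nm <- c("O_Me", "H_Me", "CH3_Me")
    a2 <- key_xyz + 0.096 * dirs1
    a3 <- key_xyz + 0.140 * dirs2
  } else {
    nm <- c("N_ACN", "C_ACN", "CH3_ACN")
    a2 <- key_xyz + 0.116 * dirs1
    a3 <- key_xyz + 0.262 * dirs1
  }
  list(names = nm, a1 = key_xyz, a2 = a2, a3 = a3)
}

#' Generate a synthetic slit-pore frame ensemble
#'
#' Draws `n_frames` independent configurations from the configured density
#' model: bonded-phase beads and solvent molecules from their z-profiles
#' (uniform in x,y), analyte molecules as rigid templates with center-of-mass
#' z from the three-component mixture and orientation cos(phi) from the
#' truncated-linear bias, and -- with probability `hb_engage_prob(z)` per
#' donor/acceptor/pi site -- a hydrogen-bond partner placed inside the
#' site's distance criterion. Partner placements are re-sampled until only
#' the intended bond holds, and background solvent keeps a 0.6 nm buffer
#' from all solute sites, so the ground truth (every intended bond, and
#' nothing else) is exact. Both pore halves are populated symmetrically.
#'
#' @param config A [slitpore_config()].
#' @param criteria Hydrogen-bond criteria used for partner placement
#'   (default [hbond_criteria()]; use the same table for detection).
#' @return A list with elements `frames` (lab-coordinate
#'   [slitpore_frames()]), `topology` and `truth` (ground-truth draws,
#'   engagements and the configured expectation functions).
#' @export
generate_slitpore <- function(config, criteria = hbond_criteria()) {
  stopifnot(inherits(config, "slitpore_config"))
  tmpl <- .analyte_template(config$compound, config$n_probe_sites)
  lay <- .system_layout(config, tmpl)
  top <- .system_topology(config, tmpl, lay)
  box <- config$box
  hw <- config$pore_width / 2
  lo <- (box[3] - config$pore_width) / 2
  hi <- lo + config$pore_width

  withr::with_seed(config$seed, {
    wtab <- .profile_sampler(config$water_fn, hw)
    otab <- .profile_sampler(config$os_fn, hw)
    frames_l <- vector("list", config$n_frames)
    draws_l <- vector("list", config$n_frames)
    eng_l <- vector("list", config$n_frames)
    unclean <- 0L
    for (fi in seq_len(config$n_frames)) {
      out <- .gen_slab_frame(config, tmpl, lay, criteria, fi, wtab, otab,
                             lo, hi, hw)
      frames_l[[fi]] <- out$particles
      draws_l[[fi]] <- out$draws
      eng_l[[fi]] <- out$engagements
      unclean <- unclean + out$unclean
    }
  })
  if (unclean > 0) {
    warn(paste0(unclean, " engaged partner(s) could not fully avoid ",
                "unintended bonds after 60 tries"))
  }
  frames <- slitpore_frames(bind_rows(frames_l), box = box,
                            surface_planes = c(lo, hi), geometry = "slab")
  truth <- structure(list(
    draws = bind_rows(draws_l),
    engagements = bind_rows(eng_l),
    mixture = config$analyte_mixture,
    adsorption_fraction = unname(config$analyte_mixture$weights[3]),
    hb_engage_prob = config$hb_engage_prob,
    w_weight = config$w_weight,
    orientation_mean = config$orientation_mean,
    n_sites = length(tmpl$donor_idx) + length(tmpl$acceptor_idx) +
      length(tmpl$ring_sets),
    unclean = unclean
  ), class = "slitpore_ground_truth")
  list(frames = frames, topology = top, truth = truth, config = config)
}

.gen_slab_frame <- function(cfg, tmpl, lay, criteria, fi, wtab, otab,
                            lo, hi, hw) {
  box <- cfg$box
  t_ns <- (fi - 1) * cfg$frame_dt
  os <- cfg$os_type

  # bonded-phase beads
  bead_tbl <- NULL
  if (cfg$n_bonded > 0) {
    bp <- cfg$bonded_profile
    bz <- .rtrunc_mix(cfg$n_bonded, bp$weights, bp$means, bp$sds, 0, bp$zmax)
    bhalf <- sample(1:2, cfg$n_bonded, replace = TRUE)
    bead_tbl <- tibble(
      particle_id = lay$bead_pids, site_name = "CH2", role = "bonded_phase",
      molecule_id = lay$bead_mids,
      x = runif(cfg$n_bonded) * box[1], y = runif(cfg$n_bonded) * box[2],
      z = ifelse(bhalf == 1L, lo + bz$z, hi - bz$z))
  }

  # analytes
  mix <- cfg$analyte_mixture
  n_an <- cfg$n_analyte
  dr <- .rtrunc_mix(n_an, mix$weights, mix$means, mix$sds, 0, hw)
  ahalf <- sample(1:2, n_an, replace = TRUE)
  cosphi <- if (tmpl$has_vector) {
    .rcos_linear(n_an, cfg$orientation_mean(dr$z))
  } else rep(NA_real_, n_an)

  np <- nrow(tmpl$local_mat)
  pos_all <- matrix(NA_real_, n_an * np, 3)
  site_rows <- list()
  placed_xyz <- NULL
  # solvent-free configurations carry no hydrogen-bond partners, so site
  # bookkeeping and placement separation are unnecessary
  track_sites <- (cfg$n_water + cfg$n_os) > 0
  for (i in seq_len(n_an)) {
    nsign <- if (ahalf[i] == 1L) 1 else -1
    if (tmpl$has_vector) {
      cth <- cosphi[i]
      sth <- sqrt(max(1 - cth^2, 0))
      psi <- runif(1, 0, 2 * pi)
      axis <- c(sth * cos(psi), sth * sin(psi), nsign * cth)
    } else {
      axis <- .runif_sphere_m(1)[1, ]
    }
    comz <- if (ahalf[i] == 1L) lo + dr$z[i] else hi - dr$z[i]
    # x,y uniform, but redrawn if any hydrogen-bond site would come within
    # 1 nm of a previously placed analyte's sites (the z draw is kept, so
    # the configured density mixture is untouched); keeps engaged-partner
    # shells free of neighbouring solutes
    s <- list()
    for (try in 1:30) {
      com <- c(runif(1) * box[1], runif(1) * box[2], comz)
      pl <- .place_analyte(tmpl, com, axis)
      if (!track_sites) break
      s <- .analyte_sites(tmpl, pl, axis, i, lay$an_pids[[i]])
      if (is.null(placed_xyz) || length(s) == 0) break
      if (.min_sep_ok(do.call(rbind, lapply(s, `[[`, "xyz")),
                      placed_xyz, box, FALSE, 1.0)) break
    }
    if (length(s) > 0) {
      placed_xyz <- rbind(placed_xyz,
                          do.call(rbind, lapply(s, `[[`, "xyz")))
    }
    pos_all[(i - 1L) * np + seq_len(np), ] <- pl$pos
    site_rows <- c(site_rows, s)
  }
  an_tbl <- tibble(
    particle_id = unlist(lay$an_pids),
    site_name = rep(tmpl$particles$site_name, n_an),
    role = "analyte",
    molecule_id = rep(lay$an_mids, each = np),
    x = pos_all[, 1], y = pos_all[, 2], z = pos_all[, 3])

  # engagement per site
  n_sites <- length(site_rows)
  eng_tbl <- NULL
  partners <- list() # per engaged site: solvent block + species
  if (n_sites > 0) {
    site_tbl <- tibble(
      analyte = vapply(site_rows, `[[`, numeric(1), "analyte"),
      site_class = vapply(site_rows, `[[`, character(1), "class"),
      label = vapply(site_rows, `[[`, character(1), "label"))
    site_xyz <- do.call(rbind, lapply(site_rows, `[[`, "xyz"))
    zi <- dr$z[site_tbl$analyte]
    engaged <- runif(n_sites) < cfg$hb_engage_prob(zi)
    species <- ifelse(runif(n_sites) < cfg$w_weight(zi), "W", os)
    # classes the organic solvent cannot serve fall back to water
    can_os <- vapply(seq_len(n_sites), function(s) {
      any(criteria$site_class == site_tbl$site_class[s] &
            criteria$species == os)
    }, logical(1))
    species[!can_os] <- "W"
    species[!engaged] <- NA_character_
    cut_by_sp <- list(W = .site_cutoffs(site_tbl, "W", criteria))
    if (any(species == os, na.rm = TRUE)) {
      cut_by_sp[[os]] <- .site_cutoffs(site_tbl, os, criteria)
    }
    clean <- rep(NA, n_sites)
    for (s in which(engaged)) {
      pp <- .place_partner(site_tbl, site_xyz, cut_by_sp[[species[s]]], s,
                           species[s], site_rows[[s]]$axis, criteria, box)
      partners[[length(partners) + 1L]] <-
        list(block = pp$cand, species = species[s])
      clean[s] <- pp$clean
    }
    eng_tbl <- tibble(
      frame = fi, molecule_id = lay$an_mids[site_tbl$analyte],
      site_class = site_tbl$site_class, site_label = site_tbl$label,
      z = zi, engaged = engaged, species = species, clean = clean)
  } else {
    site_xyz <- matrix(numeric(0), ncol = 3)
  }

  # solvent: engaged partners consume the pools first, the rest of the pool
  # is background placed outside a 0.6 nm buffer around all solute sites
  sp_vec <- vapply(partners, `[[`, character(1), "species")
  w_used <- sum(sp_vec == "W")
  o_used <- sum(sp_vec != "W")
  if (w_used > cfg$n_water || o_used > cfg$n_os) {
    abort("solvent pool exhausted: raise n_water/n_os or lower engagement")
  }
  solv_rows <- list()
  wi <- 0L; oi <- 0L
  for (p in partners) {
    if (p$species == "W") {
      wi <- wi + 1L; pid <- lay$w_pids[[wi]]; mid <- lay$w_mids[wi]
      role <- "water"
    } else {
      oi <- oi + 1L; pid <- lay$o_pids[[oi]]; mid <- lay$o_mids[oi]
      role <- "organic_solvent"
    }
    solv_rows[[length(solv_rows) + 1L]] <- tibble(
      particle_id = pid, site_name = p$block$names, role = role,
      molecule_id = mid,
      x = p$block$xyz[, 1], y = p$block$xyz[, 2], z = p$block$xyz[, 3])
  }
  bg <- .background_solvent(cfg, lay, wtab, otab, wi, oi, site_xyz, lo, hi,
                            geometry = "slab")
  particles <- bind_rows(c(list(bead_tbl, an_tbl), solv_rows, bg))
  particles$x <- .wrap(particles$x, box[1])
  particles$y <- .wrap(particles$y, box[2])
  particles$frame <- fi
  particles$time <- t_ns
  draws <- tibble(
    frame = fi, molecule_id = lay$an_mids, z = dr$z, half = ahalf,
    component = c("surface", "partitioning", "adsorption")[dr$component],
    cos_phi = cosphi)
  list(particles = particles, draws = draws,
       engagements = eng_tbl,
       unclean = if (is.null(eng_tbl)) 0L else sum(!eng_tbl$clean, na.rm = TRUE))
}

# background solvent molecules for pool indices > (wi, oi)
.background_solvent <- function(cfg, lay, wtab, otab, wi, oi, site_xyz,
                                lo, hi, geometry) {
  box <- cfg$box
  out <- list()
  fill <- function(n_bg, tab, pids, mids, species) {
    if (n_bg <= 0) return(NULL)
    if (geometry == "slab") {
      zf <- .sample_profile(n_bg, tab)
      half <- sample(1:2, n_bg, replace = TRUE)
      key <- cbind(runif(n_bg) * box[1], runif(n_bg) * box[2],
                   ifelse(half == 1L, lo + zf, hi - zf))
    } else {
      key <- cbind(runif(n_bg) * box[1], runif(n_bg) * box[2],
                   runif(n_bg) * box[3])
    }
    if (nrow(site_xyz) > 0) {
      for (round in 1:8) {
        d <- min_image_dist(key, site_xyz, box, geometry = geometry)
        bad <- apply(d <= 0.6, 1, any)
        if (!any(bad)) break
        nb <- sum(bad)
        if (geometry == "slab") {
          zf2 <- .sample_profile(nb, tab)
          h2 <- sample(1:2, nb, replace = TRUE)
          key[bad, ] <- cbind(runif(nb) * box[1], runif(nb) * box[2],
                              ifelse(h2 == 1L, lo + zf2, hi - zf2))
        } else {
          key[bad, ] <- cbind(runif(nb) * box[1], runif(nb) * box[2],
                              runif(nb) * box[3])
        }
      }
    }
    blk <- .solvent_block(key, .runif_sphere_m(n_bg), .runif_sphere_m(n_bg),
                          species, cfg$os_type)
    if (geometry == "slab") {
      # reflect satellite atoms that poke through a surface plane back into
      # the pore so no density sits inside the silica slab
      refl <- function(zv) {
        zv <- ifelse(zv < lo, 2 * lo - zv, zv)
        ifelse(zv > hi, 2 * hi - zv, zv)
      }
      blk$a2[, 3] <- refl(blk$a2[, 3])
      blk$a3[, 3] <- refl(blk$a3[, 3])
    }
    tibble(
      particle_id = c(vapply(pids, `[`, integer(1), 1),
                      vapply(pids, `[`, integer(1), 2),
                      vapply(pids, `[`, integer(1), 3)),
      site_name = rep(blk$names, each = n_bg),
      role = if (species == "W") "water" else "organic_solvent",
      molecule_id = rep(mids, 3),
      x = c(blk$a1[, 1], blk$a2[, 1], blk$a3[, 1]),
      y = c(blk$a1[, 2], blk$a2[, 2], blk$a3[, 2]),
      z = c(blk$a1[, 3], blk$a2[, 3], blk$a3[, 3]))
  }
  n_bg_w <- cfg$n_water - wi
  n_bg_o <- cfg$n_os - oi
  out$w <- fill(n_bg_w, wtab, lay$w_pids[wi + seq_len(max(n_bg_w, 0))],
                lay$w_mids[wi + seq_len(max(n_bg_w, 0))], "W")
  out$o <- fill(n_bg_o, otab, lay$o_pids[oi + seq_len(max(n_bg_o, 0))],
                lay$o_mids[oi + seq_len(max(n_bg_o, 0))], cfg$os_type)
  out
}

#' Generate a neat-water bulk box ensemble
#'
#' Homogeneous (fully periodic) boxes of one analyte compound in neat water,
#' used to estimate the solute's hydrogen-bond requirement HB_solute-W,max.
#' Each donor/acceptor/pi site of each analyte is engaged by a water partner
#' with probability `hb_prob` (a scalar, or a vector named by site class),
#' so the ground-truth expected hydrogen bonds per molecule is the sum of
#' the per-site probabilities.
#'
#' @param n_analyte Analyte molecules per frame (>= 1).
#' @param hb_prob Engagement probability per site, in `[0, 1]`; optionally
#'   named per class, e.g. `c(donor = 1, acceptor = 1, pi = 0.98)`.
#' @param seed Integer seed.
#' @param compound Analyte template (see [slitpore_config()]).
#' @param n_probe_sites Number of acceptor sites of the probe template.
#' @param n_frames Number of independent frames.
#' @param frame_dt Frame time spacing (ns).
#' @param box Box lengths (nm), periodic in x, y and z.
#' @param n_water Water molecules per frame (engaged partners are drawn from
#'   this pool; the rest is background kept outside a 0.6 nm buffer).
#' @param criteria Hydrogen-bond criteria table.
#' @return A list with `frames`, `topology`, `truth`, `config`.
#' @export
generate_bulk_box <- function(n_analyte = 10L, hb_prob = 0.6, seed = 1L,
                              compound = "probe", n_probe_sites = 1L,
                              n_frames = 20L, frame_dt = 0.1,
                              box = c(5, 5, 5), n_water = 120L,
                              criteria = hbond_criteria()) {
  if (n_analyte < 1) abort("n_analyte must be >= 1")
  if (any(hb_prob < 0 | hb_prob > 1)) abort("hb_prob must lie in [0, 1]")
  tmpl <- .analyte_template(compound, n_probe_sites)
  classes <- c(rep("donor", length(tmpl$donor_idx)),
               rep("acceptor", length(tmpl$acceptor_idx)),
               rep("pi", length(tmpl$ring_sets)))
  if (length(classes) == 0) abort("compound template has no hydrogen-bond sites")
  p_site <- if (is.null(names(hb_prob))) {
    rep(hb_prob[1], length(classes))
  } else {
    missing_cls <- setdiff(unique(classes), names(hb_prob))
    if (length(missing_cls) > 0) {
      abort(paste0("hb_prob lacks class(es): ",
                   paste(missing_cls, collapse = ", ")))
    }
    unname(hb_prob[classes])
  }

  cfg <- list(compound = compound, os_type = "MeOH", box = box,
              n_frames = as.integer(n_frames), frame_dt = frame_dt,
              n_analyte = as.integer(n_analyte),
              n_probe_sites = as.integer(n_probe_sites),
              n_bonded = 0L, n_water = as.integer(n_water), n_os = 0L)
  lay <- .system_layout(cfg, tmpl)
  top <- .system_topology(cfg, tmpl, lay)

  withr::with_seed(as.integer(seed), {
    frames_l <- vector("list", n_frames)
    eng_l <- vector("list", n_frames)
    unclean <- 0L
    for (fi in seq_len(n_frames)) {
      np <- nrow(tmpl$local_mat)
      pos_all <- matrix(NA_real_, n_analyte * np, 3)
      site_rows <- list()
      placed_xyz <- NULL
      for (i in seq_len(n_analyte)) {
        axis <- .runif_sphere_m(1)[1, ]
        # dilute-solution placement: redraw the position while any site sits
        # within 1 nm of a previously placed analyte's sites
        for (try in 1:30) {
          com <- runif(3) * box
          pl <- .place_analyte(tmpl, com, axis)
          s <- .analyte_sites(tmpl, pl, axis, i, lay$an_pids[[i]])
          if (is.null(placed_xyz) || length(s) == 0) break
          if (.min_sep_ok(do.call(rbind, lapply(s, `[[`, "xyz")),
                          placed_xyz, box, TRUE, 1.0)) break
        }
        if (length(s) > 0) {
          placed_xyz <- rbind(placed_xyz,
                              do.call(rbind, lapply(s, `[[`, "xyz")))
        }
        pos_all[(i - 1L) * np + seq_len(np), ] <- pl$pos
        site_rows <- c(site_rows, s)
      }
      an_tbl <- tibble(
        particle_id = unlist(lay$an_pids),
        site_name = rep(tmpl$particles$site_name, n_analyte),
        role = "analyte",
        molecule_id = rep(lay$an_mids, each = np),
        x = pos_all[, 1], y = pos_all[, 2], z = pos_all[, 3])
      n_sites <- length(site_rows)
      site_tbl <- tibble(
        analyte = vapply(site_rows, `[[`, numeric(1), "analyte"),
        site_class = vapply(site_rows, `[[`, character(1), "class"),
        label = vapply(site_rows, `[[`, character(1), "label"))
      site_xyz <- do.call(rbind, lapply(site_rows, `[[`, "xyz"))
      p_vec <- rep(p_site, times = n_analyte)
      engaged <- runif(n_sites) < p_vec
      cuts <- .site_cutoffs(site_tbl, "W", criteria)
      partners <- list()
      clean <- rep(NA, n_sites)
      for (s in which(engaged)) {
        pp <- .place_partner(site_tbl, site_xyz, cuts, s, "W",
                             site_rows[[s]]$axis, criteria, box,
                             geometry = "bulk")
        partners[[length(partners) + 1L]] <- pp$cand
        clean[s] <- pp$clean
      }
      if (length(partners) > n_water) {
        abort("solvent pool exhausted: raise n_water")
      }
      solv_rows <- lapply(seq_along(partners), function(k) {
        tibble(particle_id = lay$w_pids[[k]],
               site_name = partners[[k]]$names, role = "water",
               molecule_id = lay$w_mids[k],
               x = partners[[k]]$xyz[, 1], y = partners[[k]]$xyz[, 2],
               z = partners[[k]]$xyz[, 3])
      })
      bg <- .background_solvent(cfg, lay, NULL, NULL, length(partners), 0L,
                                site_xyz, NA, NA, geometry = "bulk")
      particles <- bind_rows(c(list(an_tbl), solv_rows, bg))
      particles$x <- .wrap(particles$x, box[1])
      particles$y <- .wrap(particles$y, box[2])
      particles$z <- .wrap(particles$z, box[3])
      particles$frame <- fi
      particles$time <- (fi - 1) * frame_dt
      frames_l[[fi]] <- particles
      eng_l[[fi]] <- tibble(
        frame = fi, molecule_id = lay$an_mids[site_tbl$analyte],
        site_class = site_tbl$site_class, site_label = site_tbl$label,
        z = NA_real_, engaged = engaged,
        species = ifelse(engaged, "W", NA_character_), clean = clean)
      unclean <- unclean + sum(!clean, na.rm = TRUE)
    }
  })
  if (unclean > 0) {
    warn(paste0(unclean, " engaged partner(s) could not fully avoid ",
                "unintended bonds after 60 tries"))
  }
  frames <- slitpore_frames(bind_rows(frames_l), box = box,
                            geometry = "bulk")
  truth <- structure(list(
    draws = NULL,
    engagements = bind_rows(eng_l),
    expected_hb = sum(p_site),
    expected_hb_by_class = tapply(p_site, classes, sum),
    n_sites = length(classes),
    unclean = unclean
  ), class = "slitpore_ground_truth")
  list(frames = frames, topology = top, truth = truth,
       config = c(cfg, list(hb_prob = hb_prob, seed = as.integer(seed))))
}

#' @export
print.slitpore_ground_truth <- function(x, ...) {
  cat("<slitpore_ground_truth>\n")
  if (!is.null(x$draws)) {
    cat("  analyte draws:", nrow(x$draws), "\n")
  }
  cat("  site engagements:", nrow(x$engagements),
      "(", sum(x$engagements$engaged), "engaged )\n")
  invisible(x)
}
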