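# Hydrogen-bond detection, profiles, summaries, partner densities and the
# neat-water requirement.

lo <- 0.465

# one phenol-like solute (ring + O + HO) plus arbitrary solvent atoms
phenol_frame <- function(solvent, frame = 1L) {
  th <- seq(0, 300, by = 60) * pi / 180
  solute <- tibble::tibble(
    site_name = c(rep("C_ar", 6), "O", "HO"),
    role = "analyte", molecule_id = 1L,
    x = c(2 + 0.139 * cos(th), 2, 2),
    y = rep(2, 8),
    z = lo + c(1.6 + 0.139 * sin(th), 1.96, 2.06),
    frame = frame)
  make_frames(dplyr::bind_rows(solute, dplyr::mutate(solvent, frame = frame)))
}

phenol_top <- function(n_solvent_mols, solvent_role = "water") {
  topology(
    molecule_id = c(1L, 1L + seq_len(n_solvent_mols)),
    compound = c("phenol", rep("W", n_solvent_mols)),
    role = c("analyte", rep(solvent_role, n_solvent_mols)),
    particle_ids = c(list(1:8),
                     lapply(seq_len(n_solvent_mols),
                            function(k) 8L + (k - 1L) * 3L + 1:3)),
    ring_ids = c(list(list(1:6)),
                 replicate(n_solvent_mols, list(), simplify = FALSE)),
    donor_ids = c(list(8L),
                  replicate(n_solvent_mols, integer(0), simplify = FALSE)),
    acceptor_ids = c(list(7L),
                     replicate(n_solvent_mols, integer(0), simplify = FALSE)))
}

# water with its OW at o_xyz and HW1 displaced 0.096 nm along `dir`
water_at <- function(o_xyz, mol = 2L, dir = c(0, -1, 0)) {
  tibble::tibble(
    site_name = c("OW", "HW1", "HW2"), role = "water", molecule_id = mol,
    x = o_xyz[1] + c(0, 0.096 * dir[1], 0.07),
    y = o_xyz[2] + c(0, 0.096 * dir[2], 0.07),
    z = lo + o_xyz[3] + c(0, 0.096 * dir[3], 0))
}

test_that("pi detection is boundary inclusive at exactly 0.30 nm", {
  # ring com sits at (2, 2, 1.6); place one W hydrogen exactly 0.30 above
  solv <- tibble::tibble(
    site_name = c("OW", "HW1", "HW2"), role = "water", molecule_id = 2L,
    x = c(2, 2, 2.07), y = c(2, 2, 2),
    z = lo + c(1.996, 1.90, 2.05))
  frames <- phenol_frame(solv)
  tbl <- detect_hbonds(frames, phenol_top(1))
  pi_rows <- tbl[tbl$kind == "pi", ]
  expect_identical(nrow(pi_rows), 1L)
  expect_equal(pi_rows$distance, 0.30, tolerance = 1e-9)
  expect_identical(nrow(tbl), brute_hbond_count(frames, phenol_top(1),
                                                hbond_criteria()))
})

test_that("sites just outside their cutoff are not bonded", {
  # ACN nitrogen 0.26 nm from the donor hydrogen (cutoff 0.255)
  solv <- tibble::tibble(
    site_name = c("N_ACN", "C_ACN", "CH3_ACN"), role = "organic_solvent",
    molecule_id = 2L,
    x = c(2, 2, 2), y = c(2, 2, 2), z = lo + c(2.32, 2.44, 2.58))
  frames <- phenol_frame(solv)
  tbl <- detect_hbonds(frames, phenol_top(1, "organic_solvent"))
  expect_identical(nrow(tbl[tbl$site_class == "donor", ]), 0L)
  # moving it inside the cutoff creates exactly one donor bond
  solv2 <- dplyr::mutate(solv, z = lo + c(2.31, 2.43, 2.57))
  tbl2 <- detect_hbonds(phenol_frame(solv2),
                        phenol_top(1, "organic_solvent"))
  expect_identical(nrow(tbl2[tbl2$site_class == "donor", ]), 1L)
})

test_that("missing criteria for an annotated class is a config error", {
  solv <- water_at(c(2, 2, 2.3))
  frames <- phenol_frame(solv)
  crit <- hbond_criteria()
  crit <- crit[crit$site_class != "pi", ]
  expect_error(detect_hbonds(frames, phenol_top(1), crit), "'pi'")
})

test_that("lowering any cutoff never increases the bond count", {
  sim <- generate_bulk_box(n_analyte = 12, hb_prob = 0.8, seed = 19,
                           compound = "phenol", n_frames = 10,
                           n_water = 60)
  full <- detect_hbonds(sim$frames, sim$topology)
  for (f in c(0.9, 0.7, 0.5)) {
    crit <- hbond_criteria()
    crit$r_hb <- pmax(crit$r_hb * f, 0.151)
    fewer <- detect_hbonds(sim$frames, sim$topology, crit)
    expect_lte(nrow(fewer), nrow(full))
  }
})

test_that("species-resolved counts conserve the total", {
  cfg <- slitpore_config(compound = "phenol", scale_xy = 0.35, n_frames = 15,
                         n_analyte = 8, bp_sites_per_nm2 = 0,
                         n_water = 40, n_os = 40, seed = 47)
  sim <- generate_slitpore(cfg)
  tbl <- detect_hbonds(sim$frames, sim$topology)
  expect_gt(nrow(tbl), 0)
  expect_identical(sum(table(tbl$partner_species)), nrow(tbl))
  expect_true(all(tbl$partner_species %in% c("W", "MeOH")))
  expect_true(all(tbl$distance <= 0.32 + 1e-12))
})

test_that("random slab fixtures agree with the brute-force detector", {
  set.seed(83)
  for (k in 1:8) {
    n_w <- sample(3:8, 1)
    solv <- purrr::map_dfr(seq_len(n_w), function(i) {
      water_at(c(runif(1) * default_box[1], runif(1) * default_box[2],
                 runif(1, 1.2, 2.2)), mol = 1L + i)
    })
    frames <- phenol_frame(solv)
    top <- phenol_top(n_w)
    tbl <- detect_hbonds(frames, top)
    expect_identical(nrow(tbl),
                     brute_hbond_count(frames, top, hbond_criteria()))
  }
})

test_that("profiles report per-visit means with additive site counts", {
  # two waters whose HW1 atoms reach the acceptor O (2, 2, 1.96) from
  # opposite sides while their other atoms stay clear of the donor H and
  # the ring center of mass
  solv <- dplyr::bind_rows(
    water_at(c(2, 2.29, 1.96), 2L, dir = c(0, -1, 0)),
    water_at(c(2, 1.71, 1.96), 3L, dir = c(0, 1, 0)))
  frames <- phenol_frame(solv)
  top <- phenol_top(2)
  tbl <- detect_hbonds(frames, top)
  vis <- analyte_positions(frames)
  prof <- hbond_profile(tbl, vis, hw = 5)
  hit <- prof[!is.na(prof$hb_total) & prof$hb_total > 0, ]
  expect_identical(nrow(hit), 1L)
  # two acceptor partners on one molecule: per-visit count of 2
  expect_equal(hit$hb_functional, 2)
  expect_identical(nrow(tbl),
                   brute_hbond_count(frames, top, hbond_criteria()))
})

test_that("empty tables give an all-missing profile with a warning", {
  frames <- phenol_frame(water_at(c(2, 2, 4.5)))
  tbl <- detect_hbonds(frames, phenol_top(1))
  expect_identical(nrow(tbl), 0L)
  vis <- analyte_positions(frames)
  expect_warning(prof <- hbond_profile(tbl, vis, hw = 5), "empty")
  expect_true(all(is.na(prof$hb_total) | prof$hb_total == 0))
})

test_that("summary weighting follows the contact-average rule", {
  z <- c(1.575, 1.625)
  hb <- make_hbond_profile(z, c(2, 1))
  rho <- make_density_profile(z, c(1, 1))
  tbl_stub <- tibble::tibble(partner_species = c("W", "W"),
                             analyte_z = c(1.575, 1.625))
  class(tbl_stub) <- c("hbond_table", class(tbl_stub))
  s <- hbond_summary(hb, rho, z_sp = 1.65, hb_bulk = 3, tbl_stub)
  expect_equal(s$hb_sp, 1.5)
  expect_equal(s$recovery, 1.5 / 3)
  expect_equal(s$w_contribution_sp, 1.0)
  # constant profiles are weight-independent
  hbc <- make_hbond_profile(z, c(1.7, 1.7))
  rho2 <- make_density_profile(z, c(5, 1))
  expect_equal(hbond_summary(hbc, rho2, 1.65, 3, tbl_stub)$hb_sp, 1.7)
  expect_error(hbond_summary(hb, rho, 1.65, hb_bulk = 0, tbl_stub),
               "hb_bulk")
})

test_that("slab probe ensemble recovers a z-dependent engagement curve", {
  cfg <- slitpore_config(
    compound = "probe", scale_xy = 1, n_frames = 60, n_analyte = 40,
    bp_sites_per_nm2 = 0, n_water = 60, n_os = 0, seed = 29,
    w_weight = function(z) rep(1, length(z)),
    hb_engage_prob = function(z) 0.8 * stats::plogis((z - 1.2) / 0.3))
  sim <- generate_slitpore(cfg)
  expect_identical(sim$truth$unclean, 0L)
  tbl <- detect_hbonds(sim$frames, sim$topology)
  expect_identical(nrow(tbl), sum(sim$truth$engagements$engaged))
  vis <- analyte_positions(sim$frames)
  prof <- hbond_profile(tbl, vis, hw = 5)
  busy <- prof[!is.na(prof$hb_total) & prof$n_visits >= 100, ]
  expect_gt(nrow(busy), 3)
  for (i in seq_len(nrow(busy))) {
    p <- cfg$hb_engage_prob(busy$z[i])
    se <- sqrt(p * (1 - p) / busy$n_visits[i])
    expect_lt(abs(busy$hb_total[i] - p), 3 * se + 0.03)
  }
})

test_that("partner rows condition on the analyte's peak", {
  dec <- make_decomposition(boundary_z = 1.05, z_sp = 2.5)
  # adsorption-peak analyte at z = 1.6 with engaged partner key atom at 1.96
  frames <- phenol_frame(water_at(c(2, 2.29, 1.96)))
  tbl <- detect_hbonds(frames, phenol_top(1))
  pd <- partner_density(tbl, dec, hw = 5)
  expect_true(all(pd$peak == "adsorption"))
  expect_identical(attr(pd, "excluded_rows"), 0L)
  w_rows <- pd[pd$species == "W", ]
  expect_equal(sum(w_rows$n), nrow(tbl))
  # partner atoms are binned by their own z (1.96), not the analyte's
  expect_true(all(abs(w_rows$z - 1.96) <= 0.025 + 1e-9))

  # the same geometry with a partitioning-peak analyte conditions the rows
  # onto the partitioning profile instead
  dec2 <- make_decomposition(boundary_z = 1.7, z_sp = 2.5)
  pd2 <- partner_density(tbl, dec2, hw = 5)
  expect_true(all(pd2$peak == "partitioning"))

  # analytes beyond z_sp are excluded and tallied
  dec3 <- make_decomposition(boundary_z = 1.05, z_sp = 1.2)
  pd3 <- partner_density(tbl, dec3, hw = 5)
  expect_identical(nrow(pd3), 0L)
  expect_identical(attr(pd3, "excluded_rows"), nrow(tbl))
})

test_that("the water partner share recovers the configured weight", {
  cfg <- slitpore_config(
    compound = "probe", scale_xy = 1, n_frames = 50, n_analyte = 40,
    bp_sites_per_nm2 = 0, n_water = 60, n_os = 60, seed = 37,
    hb_engage_prob = function(z) rep(0.7, length(z)),
    w_weight = function(z) rep(0.7, length(z)))
  sim <- generate_slitpore(cfg)
  tbl <- detect_hbonds(sim$frames, sim$topology)
  n <- nrow(tbl)
  share <- mean(tbl$partner_species == "W")
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(share - 0.7), 3 * se + 0.01)
  # and the integrated partner-density areas see the same split
  dec <- make_decomposition(boundary_z = 1.05, z_sp = 5)
  areas <- integrate_partner_density(partner_density(tbl, dec, hw = 5),
                                     window = c(0, 5))
  tot <- sum(areas$area)
  expect_lt(abs(sum(areas$area[areas$species == "W"]) / tot - share), 0.02)
})

test_that("neat-water requirement splits functional and pi contributions", {
  # a small fraction of placements cannot avoid unintended bonds in the
  # crowded phenol site geometry; the tally enters the tolerance below
  sim <- suppressWarnings(generate_bulk_box(
    n_analyte = 40, n_frames = 120, seed = 53, compound = "phenol",
    hb_prob = c(donor = 1, acceptor = 1, pi = 0.98), n_water = 140,
    box = c(8, 8, 8)))
  hb <- hb_max_neat_water(sim$frames, sim$topology)
  n_mf <- 40 * 120
  se_pi <- sqrt(0.98 * 0.02 / n_mf)
  unc <- sim$truth$unclean / n_mf
  expect_equal(hb$functional, 2.0, tolerance = 0.01 + unc)
  expect_lt(abs(hb$pi - 0.98), 3 * se_pi + unc + 0.005)
  expect_error(hb_max_neat_water(
    make_frames(point_analytes(1.5)), point_topology(1)), "geometry")
})
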