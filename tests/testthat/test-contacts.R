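# Contact counting, contact profiles, the stationary-phase limit and the
# stationary-phase averages.

bead_frame <- function(bead_xyz, analyte_xyz = c(2, 2, 1.0), frame = 1L) {
  lo <- default_planes[1]
  n <- nrow(bead_xyz)
  make_frames(tibble::tibble(
    site_name = c("O", rep("CH2", n)),
    role = c("analyte", rep("bonded_phase", n)),
    molecule_id = c(1L, 1L + seq_len(n)),
    x = c(analyte_xyz[1], bead_xyz[, 1]),
    y = c(analyte_xyz[2], bead_xyz[, 2]),
    z = lo + c(analyte_xyz[3], bead_xyz[, 3]),
    frame = frame))
}

test_that("counting is boundary inclusive at exactly r_bp", {
  beads <- rbind(c(2 + 0.50, 2, 1.0),  # 0.50 nm
                 c(2 + 0.79, 2, 1.0),  # exactly r_bp
                 c(2 + 0.90, 2, 1.0))  # outside
  frames <- bead_frame(beads)
  expect_identical(count_contacts(frames, 1L, 1L, r_bp = 0.79), 2L)
  expect_identical(count_contacts(frames, 1L, 1L, r_bp = 0.79),
                   brute_contacts(frames, 1L, 1L, 0.79))
})

test_that("zero bonded-phase sites give a zero count", {
  frames <- make_frames(point_analytes(1.0))
  expect_identical(count_contacts(frames, 1L, 1L, r_bp = 0.8), 0L)
})

test_that("beads across the x periodic boundary are counted", {
  beads <- rbind(c(default_box[1] - 0.2, 2, 1.0))
  frames <- bead_frame(beads, analyte_xyz = c(0.1, 2, 1.0))
  expect_identical(count_contacts(frames, 1L, 1L, r_bp = 0.35), 1L)
  expect_identical(brute_contacts(frames, 1L, 1L, 0.35), 1L)
})

test_that("random fixtures agree with the brute-force oracle", {
  set.seed(61)
  for (k in 1:20) {
    n_bead <- sample(20:80, 1)
    beads <- cbind(runif(n_bead) * default_box[1],
                   runif(n_bead) * default_box[2],
                   runif(n_bead) * 4.5)
    an <- c(runif(1) * default_box[1], runif(1) * default_box[2],
            runif(1, 0.3, 2.5))
    frames <- bead_frame(beads, analyte_xyz = an)
    r <- runif(1, 0.5, 1.2)
    expect_identical(count_contacts(frames, 1L, 1L, r_bp = r),
                     brute_contacts(frames, 1L, 1L, r))
  }
})

test_that("contact profile averages molecule visits within bins", {
  lo <- default_planes[1]
  # one molecule pinned at z = 0.7 with 12 beads in range, 3 frames
  beads12 <- cbind(2 + 0.3 * cos(seq_len(12)), 2 + 0.3 * sin(seq_len(12)),
                   0.7)
  df <- purrr::map_dfr(1:3, function(fr) tibble::tibble(
    site_name = c("O", rep("CH2", 12)),
    role = c("analyte", rep("bonded_phase", 12)),
    molecule_id = c(1L, 1L + 1:12),
    x = c(2, beads12[, 1]), y = c(2, beads12[, 2]),
    z = lo + c(0.7, beads12[, 3]), frame = fr))
  frames <- make_frames(df)
  prof <- contact_profile(frames, r_bp = 0.79, window = 0.3)
  hit <- prof[!is.na(prof$c_bp), ]
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$c_bp, 12)
  expect_true(0.7 >= hit$z - 0.025 && 0.7 <= hit$z + 0.025)

  # two molecules in the same bin with 10 and 6 contacts average to 8
  mk_ring <- function(cx, cy, n) cbind(cx + 0.3 * cos(seq_len(n)),
                                       cy + 0.3 * sin(seq_len(n)), 1.2)
  b2 <- rbind(mk_ring(1, 1, 10), mk_ring(3, 3, 6))
  df2 <- purrr::map_dfr(1:2, function(fr) tibble::tibble(
    site_name = c("O", "O", rep("CH2", 16)),
    role = c("analyte", "analyte", rep("bonded_phase", 16)),
    molecule_id = c(1L, 2L, 2L + 1:16),
    x = c(1, 3, b2[, 1]), y = c(1, 3, b2[, 2]),
    z = lo + c(1.2, 1.2, b2[, 3]), frame = fr))
  prof2 <- contact_profile(make_frames(df2), r_bp = 0.5, window = 0.1)
  expect_equal(prof2$c_bp[!is.na(prof2$c_bp)], 8)
})

test_that("frames shorter than the observation window error out", {
  frames <- make_frames(point_analytes(1.0))
  expect_error(contact_profile(frames, r_bp = 0.8, window = 40),
               "smaller window")
})

test_that("z_sp interpolates the C_BP = 1 crossing", {
  prof <- make_contact_profile(z = seq(0.3, 0.5, by = 0.05),
                               c_bp = c(12, 6, 2, 0.9, 0.4))
  # hand oracle: crossing between the bins at 0.40 (C=2) and 0.45 (C=0.9)
  expect_equal(stationary_phase_limit(prof),
               0.40 + 0.05 * (2 - 1) / (2 - 0.9))
  # step profile: interpolation between the last >=1 bin and the zero bin
  step <- make_contact_profile(z = seq(0.25, 0.4, by = 0.05),
                               c_bp = c(5, 5, 0, 0))
  expect_equal(stationary_phase_limit(step), 0.30 + 0.05 * (5 - 1) / 5)
  # plateaus at exactly 1 resolve outward
  plat <- make_contact_profile(z = seq(0.25, 0.4, by = 0.05),
                               c_bp = c(2, 1, 1, 0.5))
  expect_equal(stationary_phase_limit(plat), 0.35)
})

test_that("doubling a decreasing profile moves z_sp outward", {
  z <- seq(0.3, 1.5, by = 0.05)
  c_bp <- 8 * exp(-2.5 * (z - 0.3))
  p1 <- make_contact_profile(z, c_bp)
  p2 <- make_contact_profile(z, 2 * c_bp)
  expect_gt(stationary_phase_limit(p2), stationary_phase_limit(p1))
})

test_that("degenerate contact profiles raise the documented errors", {
  expect_error(stationary_phase_limit(
    make_contact_profile(seq(0.3, 0.4, 0.05), c(0.5, 0.4, 0.2))),
    "no stationary phase")
  expect_error(stationary_phase_limit(
    make_contact_profile(seq(0.3, 0.4, 0.05), c(9, 7, 5))),
    "truncated")
})

test_that("stationary-phase averages equal hand arithmetic", {
  z <- c(0.325, 0.375, 0.425)
  cp <- make_contact_profile(z, c(10, 6, 2))
  rho <- make_density_profile(z, c(1, 2, 1))
  s <- stationary_phase_summary(cp, rho, z_sp = 0.45)
  expect_equal(s$mean_contacts, 24 / 4) # (10*1 + 6*2 + 2*1) / 4
  expect_equal(s$mean_position, (0.325 + 2 * 0.375 + 0.425) / 4)

  # all density in one bin pins the mean position to that bin center
  rho1 <- make_density_profile(z, c(0, 5, 0))
  expect_equal(stationary_phase_summary(cp, rho1, 0.45)$mean_position, 0.375)

  # invariant under uniform density rescaling, and bounded by the profile
  rho10 <- make_density_profile(z, 10 * c(1, 2, 1))
  expect_equal(stationary_phase_summary(cp, rho10, 0.45)$mean_contacts,
               s$mean_contacts)
  expect_true(s$mean_contacts >= 2 && s$mean_contacts <= 10)
})

test_that("shifting density toward the bulk lowers the contact average", {
  z <- c(0.325, 0.375, 0.425)
  cp <- make_contact_profile(z, c(10, 6, 2))
  inner <- stationary_phase_summary(cp, make_density_profile(z, c(2, 1, 1)),
                                    0.45)
  outer <- stationary_phase_summary(cp, make_density_profile(z, c(1, 1, 2)),
                                    0.45)
  expect_lt(outer$mean_contacts, inner$mean_contacts)
})

test_that("missing contact bins with analyte density are an error", {
  z <- c(0.325, 0.375, 0.425)
  cp <- make_contact_profile(z, c(10, NA, 2))
  rho <- make_density_profile(z, c(1, 2, 1))
  expect_error(stationary_phase_summary(cp, rho, 0.45), "missing contact")
  expect_error(stationary_phase_summary(cp, make_density_profile(z, rep(0, 3)),
                                        0.45), "zero analyte density")
})

test_that("r_bp derivation finds the constructed RDF minimum", {
  r <- seq(0.05, 1.5, by = 0.01)
  g <- 1 + 2 * exp(-(r - 0.5)^2 / 0.01) - 0.5 * exp(-(r - 0.80)^2 / 0.02)
  # numeric oracle: argmin of the smoothed curve beyond the peak
  s <- stats::filter(g, rep(1 / 3, 3), sides = 2)
  oracle <- round(r[which.min(replace(s, r < 0.6, Inf))], 2)
  rdf <- tibble::tibble(r = r, g = g)
  class(rdf) <- c("rdf", class(rdf))
  expect_equal(derive_rbp(rdf), oracle)
  expect_equal(derive_rbp(list(rdf, rdf)), derive_rbp(rdf)) # averaging identity
  mono <- tibble::tibble(r = r, g = exp(-r))
  class(mono) <- c("rdf", class(mono))
  expect_error(derive_rbp(mono), "no local minimum")
})

test_that("the shipped contact radii carry the reference values", {
  ref <- rbp_reference()
  expect_equal(ref$r_bp[ref$compound == "phenol" & ref$os_type == "MeOH"],
               0.79)
  expect_equal(ref$r_bp[ref$compound == "naphthalene" & ref$os_type == "ACN"],
               0.83)
  expect_true(all(ref$r_bp >= 0.5 & ref$r_bp <= 1.2))
  expect_true(all(ref$provenance == "literature"))
})

test_that("contact profile matches the semi-analytic sphere-count oracle", {
  r_bp <- 0.5
  bpp <- list(weights = 1, means = 0.6, sds = 0.3, zmax = 1.6)
  cfg <- slitpore_config(
    compound = "probe", scale_xy = 0.4, n_frames = 150, n_analyte = 20,
    bp_sites_per_nm2 = 25, n_water = 0, n_os = 0, seed = 3,
    bonded_profile = bpp,
    hb_engage_prob = function(z) rep(0, length(z)),
    analyte_mixture = list(weights = c(0, 1, 0), means = c(0.5, 0.8, 1.6),
                           sds = c(0.05, 0.02, 0.1)))
  sim <- generate_slitpore(cfg)
  prof <- contact_profile(sim$frames, r_bp = r_bp,
                          window = cfg$n_frames * cfg$frame_dt)
  # Monte-Carlo/quadrature oracle: expected beads in the r_bp sphere around
  # an analyte at z0, from the configured bead density of one pore half
  area <- sim$frames$box[1] * sim$frames$box[2]
  pdf_z <- function(z) {
    d <- stats::dnorm(z, bpp$means, bpp$sds) /
      (stats::pnorm(bpp$zmax, bpp$means, bpp$sds) -
         stats::pnorm(0, bpp$means, bpp$sds))
    ifelse(z >= 0 & z <= bpp$zmax, d, 0)
  }
  expected_c <- function(z0) {
    integrand <- function(z) {
      (cfg$n_bonded / 2) * pdf_z(z) / area * pi * (r_bp^2 - (z - z0)^2)
    }
    stats::integrate(integrand, max(0, z0 - r_bp), z0 + r_bp)$value
  }
  hit <- prof[!is.na(prof$c_bp) & prof$n > 300, ]
  for (i in seq_len(nrow(hit))) {
    mu <- expected_c(hit$z[i])
    se <- sqrt(mu / hit$n[i]) # Poisson-like spread of the per-visit count
    expect_lt(abs(hit$c_bp[i] - mu), 3 * se + 0.05 * mu)
  }
})
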