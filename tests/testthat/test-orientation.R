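# Orientation analysis: sign conventions, folding symmetry, weighted means.

lo <- 0.465
hi <- 10.465

# a two-particle molecule with an explicit vector tail -> head
stick <- function(tail_xyz, head_xyz, mol = 1L, frame = 1L) {
  tibble::tibble(
    site_name = c("C", "O"), role = "analyte", molecule_id = mol,
    x = c(tail_xyz[1], head_xyz[1]), y = c(tail_xyz[2], head_xyz[2]),
    z = c(tail_xyz[3], head_xyz[3]), frame = frame)
}

stick_top <- function(n, pid0 = 0L) {
  topology(
    molecule_id = seq_len(n), compound = "stick", role = "analyte",
    particle_ids = lapply(seq_len(n), function(k) (k - 1L) * 2L + 1:2),
    vector_tail_id = (seq_len(n) - 1L) * 2L + 1L,
    vector_head_id = (seq_len(n) - 1L) * 2L + 2L)
}

test_that("sign convention: heads toward the bulk give positive cos phi", {
  # lower half, head straight up (toward bulk): cos = +1
  df <- dplyr::bind_rows(
    stick(c(1, 1, lo + 1.0), c(1, 1, lo + 1.3), 1L),
    # upper half, head straight down in lab = toward bulk: also +1
    stick(c(3, 3, hi - 1.0), c(3, 3, hi - 1.3), 2L),
    # parallel to the surface: cos = 0
    stick(c(2, 2, lo + 1.0), c(2.3, 2, lo + 1.0), 3L))
  frames <- make_frames(df)
  prof <- orientation_profile(frames, stick_top(3))
  top_bin <- prof[prof$cos_phi > 0.9, ]
  expect_equal(sum(top_bin$n), 2L)
  mid_bin <- prof[abs(prof$cos_phi - 0.05) < 1e-9, ]
  expect_equal(sum(mid_bin$n), 1L) # cos = 0 falls in the [0, 0.1) bin
})

test_that("per-slice distributions normalise and mean lies in [-1, 1]", {
  set.seed(7)
  df <- purrr::map_dfr(1:30, function(i) {
    th <- runif(1, 0, pi); ph <- runif(1, 0, 2 * pi)
    v <- 0.3 * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    p0 <- c(runif(1, 1, 3), runif(1, 1, 3), lo + runif(1, 0.5, 2.5))
    stick(p0, p0 + v, i)
  })
  prof <- orientation_profile(make_frames(df), stick_top(30))
  sums <- prof |> dplyr::group_by(z) |> dplyr::summarise(s = sum(p))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  m <- orientation_means(prof)
  expect_true(all(m$mean_cos >= -1 & m$mean_cos <= 1))
})

test_that("weighted mixture mean matches the binned hand oracle", {
  # 15 molecules at cos = +0.85 and 5 at cos = -0.75 (bin centers), all in
  # one z bin: weighted mean = 0.75*0.85 - 0.25*0.75 = 0.45
  mk <- function(cos_v, i) {
    s <- sqrt(1 - cos_v^2)
    # pick the tail so the mass-weighted com sits at z = 1.6 regardless of
    # the orientation (one z bin for the whole mixture)
    w_head <- 15.999 / (12.011 + 15.999)
    p0 <- c(1 + 0.2 * i, 1, lo + 1.62 - w_head * 0.3 * cos_v)
    stick(p0, p0 + 0.3 * c(s, 0, cos_v), i)
  }
  df <- dplyr::bind_rows(
    purrr::map_dfr(1:15, ~mk(0.85, .x)),
    purrr::map_dfr(16:20, ~mk(-0.75, .x)))
  frames <- make_frames(df)
  prof <- orientation_profile(frames, stick_top(20))
  dens <- make_density_profile(seq(0.025, 4.975, 0.05),
                               rep(1, 100)) # uniform weights
  po <- preferred_orientation(prof, dens, c(1.5, 1.7))
  expect_equal(po$mean_cos, 0.75 * 0.85 - 0.25 * 0.75, tolerance = 1e-9)
  expect_identical(po$interpretation, "bulk-oriented")
})

test_that("all-surface-pointing vectors are classified surface-oriented", {
  df <- purrr::map_dfr(1:6, function(i) {
    p0 <- c(i * 0.5, 1, lo + 1.2)
    stick(p0, p0 - c(0, 0, 0.3), i)
  })
  prof <- orientation_profile(make_frames(df), stick_top(6))
  dens <- make_density_profile(seq(0.025, 4.975, 0.05), rep(1, 100))
  po <- preferred_orientation(prof, dens, c(1.0, 1.4))
  expect_lt(po$mean_cos, -0.9)
  expect_identical(po$interpretation, "surface-oriented")
})

test_that("negating every molecular vector negates the weighted mean", {
  set.seed(9)
  vecs <- purrr::map(1:25, function(i) {
    th <- acos(runif(1, -1, 1)); ph <- runif(1, 0, 2 * pi)
    0.3 * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  })
  p0s <- purrr::map(1:25, ~c(runif(1, 1, 3), runif(1, 1, 3),
                             lo + runif(1, 1.3, 1.7)))
  # negation = point reflection through the molecule's center of mass, so
  # every com (and hence every z-bin assignment) is unchanged
  mkframes <- function(sign) {
    make_frames(purrr::map_dfr(1:25, function(i) {
      tail <- p0s[[i]]; head <- p0s[[i]] + vecs[[i]]
      com <- (12.011 * tail + 15.999 * head) / (12.011 + 15.999)
      if (sign > 0) stick(tail, head, i)
      else stick(2 * com - tail, 2 * com - head, i)
    }))
  }
  dens <- make_density_profile(seq(0.025, 4.975, 0.05), rep(1, 100))
  po_plus <- preferred_orientation(
    orientation_profile(mkframes(1), stick_top(25)), dens, c(0, 3))
  po_minus <- preferred_orientation(
    orientation_profile(mkframes(-1), stick_top(25)), dens, c(0, 3))
  expect_equal(po_minus$mean_cos, -po_plus$mean_cos)
})

test_that("upper and lower pore halves give identical folded profiles", {
  set.seed(15)
  df_lo <- purrr::map_dfr(1:20, function(i) {
    th <- acos(runif(1, -1, 1)); ph <- runif(1, 0, 2 * pi)
    v <- 0.3 * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    p0 <- c(runif(1, 1, 3), runif(1, 1, 3), lo + runif(1, 0.5, 2.5))
    stick(p0, p0 + v, i)
  })
  # mirror every molecule through the pore midplane: folded observables
  # must be bit-identical
  mid <- (lo + hi) / 2
  df_hi <- df_lo |> dplyr::mutate(z = 2 * mid - z)
  p_lo <- orientation_profile(make_frames(df_lo), stick_top(20))
  p_hi <- orientation_profile(make_frames(df_hi), stick_top(20))
  expect_equal(as.data.frame(p_lo), as.data.frame(p_hi))
})

test_that("generator orientation bias is recovered exactly via the binned oracle", {
  cfg <- slitpore_config(
    compound = "phenol", scale_xy = 0.4, n_frames = 250, n_analyte = 40,
    bp_sites_per_nm2 = 0, n_water = 0, n_os = 0, seed = 27,
    hb_engage_prob = function(z) rep(0, length(z)),
    orientation_mean = function(z) rep(0.4, length(z)))
  sim <- generate_slitpore(cfg)
  fr <- fold_to_surface(sim$frames)
  prof <- orientation_profile(fr, sim$topology)
  dens <- density_profile(fr, sim$topology)
  po <- preferred_orientation(prof, dens, c(0, 5))
  # the analyte-density weighting makes the global weighted mean identical
  # to the binned mean of the recorded ground-truth draws
  cc <- seq(-0.95, 0.95, by = 0.1)
  oracle <- mean(cc[pmin(floor((sim$truth$draws$cos_phi + 1) / 0.1) + 1, 20)])
  expect_equal(po$mean_cos, oracle)
  n <- nrow(sim$truth$draws)
  se <- stats::sd(sim$truth$draws$cos_phi) / sqrt(n)
  expect_lt(abs(po$mean_cos - 0.4), 3 * se + 0.01)
})

test_that("an isotropic ensemble reads as isotropic", {
  cfg <- slitpore_config(
    compound = "phenol", scale_xy = 0.4, n_frames = 250, n_analyte = 40,
    bp_sites_per_nm2 = 0, n_water = 0, n_os = 0, seed = 33,
    hb_engage_prob = function(z) rep(0, length(z)),
    orientation_mean = function(z) rep(0, length(z)))
  sim <- generate_slitpore(cfg)
  fr <- fold_to_surface(sim$frames)
  po <- preferred_orientation(orientation_profile(fr, sim$topology),
                              density_profile(fr, sim$topology), c(0, 5))
  expect_lt(abs(po$mean_cos), 3 * 0.58 / sqrt(10000))
  expect_identical(po$interpretation, "isotropic")
})

test_that("degenerate vectors and empty intervals raise errors", {
  df <- stick(c(1, 1, lo + 1), c(1, 1, lo + 1)) # zero length
  expect_error(orientation_profile(make_frames(df), stick_top(1)),
               "zero-length")
  df2 <- stick(c(1, 1, lo + 1), c(1, 1, lo + 1.3))
  prof <- orientation_profile(make_frames(df2), stick_top(1))
  dens <- make_density_profile(seq(0.025, 4.975, 0.05),
                               c(rep(1, 30), rep(0, 70)))
  expect_error(preferred_orientation(prof, dens, c(4, 5)), "undefined")
})
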