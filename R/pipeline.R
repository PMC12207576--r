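# End-to-end orchestration: generate (or accept) frames, run profiles,
# contacts, hydrogen bonds and orientation, and collect a run report.

#' Run the full interfacial analysis pipeline
#'
#' Generates a synthetic ensemble from `config` (or uses pre-generated
#' `sim` input), then runs, in order: analyte density profile, contact
#' profile and stationary-phase limit, stationary-phase averages, peak
#' decomposition, hydrogen-bond detection/profile/summary, partner
#' densities, preferential orientations (when the compound has a molecular
#' vector), and molecular-graph descriptors (when the compound is one of
#' the analyte ensemble). Deterministic given the config seed.
#'
#' @param config A [slitpore_config()] or preset name (see
#'   [slitpore_preset()]).
#' @param sim Optional pre-generated list from [generate_slitpore()]
#'   (overrides `config`).
#' @param r_bp Contact radius; default looks the compound up in
#'   [rbp_reference()] and falls back to deriving it from the RDF.
#' @param criteria Hydrogen-bond criteria.
#' @param regions A [region_spec()].
#' @param window Contact observation window (ns); default the full frame
#'   span, so short synthetic ensembles form one window.
#' @param hb_bulk Bulk-liquid hydrogen bonds per molecule for the recovery
#'   fraction; default estimates it from the bulk region (z > z_bulk_start)
#'   of the run's own hydrogen-bond profile, NA when the bulk holds no
#'   analyte visits.
#' @param out_dir Optional directory for TSV/JSON artifacts and a manifest.
#' @return A `slitpore_report` object.
#' @export
run_pipeline <- function(config = slitpore_preset("phenol-meoh50"),
                         sim = NULL, r_bp = NULL,
                         criteria = hbond_criteria(),
                         regions = region_spec(), window = NULL,
                         hb_bulk = NULL, out_dir = NULL) {
  if (is.character(config)) config <- slitpore_preset(config)
  if (is.null(sim)) {
    # template lookup fails fast on unknown compounds, before any sampling
    .analyte_template(config$compound, config$n_probe_sites)
    sim <- generate_slitpore(config, criteria)
  } else {
    config <- sim$config
  }
  frames <- fold_to_surface(sim$frames)
  top <- sim$topology
  window <- window %||% (config$n_frames * config$frame_dt)

  dens <- density_profile(frames, top, role = "analyte",
                          compound = config$compound, regions = regions)
  if (is.null(r_bp)) {
    ref <- rbp_reference()
    hit <- ref |> filter(.data$compound == config$compound,
                         .data$os_type == config$os_type)
    r_bp <- if (nrow(hit) == 1) hit$r_bp else derive_rbp(analyte_bp_rdf(
      frames, regions = regions))
  }
  cprof <- contact_profile(frames, r_bp, window = window, regions = regions)
  z_sp <- stationary_phase_limit(cprof)
  sp <- stationary_phase_summary(cprof, dens, z_sp)
  regions$z_sp <- z_sp
  decomp <- decompose_peaks(dens, regions)

  htbl <- detect_hbonds(frames, top, criteria)
  vis <- analyte_positions(frames)
  hprof <- hbond_profile(htbl, vis, regions,
                         hw = pore_half_width(frames))
  if (is.null(hb_bulk)) {
    jb <- dplyr::inner_join(
      tibble(z = round(hprof$z, 6), hb = hprof$hb_total),
      tibble(z = round(dens$z, 6), rho = dens$density), by = "z") |>
      filter(.data$z > regions$z_bulk_start, .data$rho > 0, !is.na(.data$hb))
    hb_bulk <- if (nrow(jb) > 0) sum(jb$hb * jb$rho) / sum(jb$rho)
               else NA_real_
    if (!is.na(hb_bulk) && hb_bulk <= 0) hb_bulk <- NA_real_
  }
  hsum <- hbond_summary(hprof, dens, z_sp, hb_bulk, htbl, regions)
  pdens <- partner_density(htbl, decomp, regions,
                           hw = pore_half_width(frames))

  tmpl <- .analyte_template(config$compound, config$n_probe_sites)
  orient <- NULL
  if (tmpl$has_vector) {
    oprof <- orientation_profile(frames, top, regions)
    orient <- list(
      profile = oprof,
      partitioning = preferred_orientation(
        oprof, dens, c(0, decomp$boundary_z)),
      adsorption = preferred_orientation(
        oprof, dens, c(decomp$boundary_z, z_sp)))
  }
  graphs <- compound_graphs()
  desc <- if (config$compound %in% names(graphs)) {
    g <- graphs[[config$compound]]
    tibble(compound = config$compound, v_vdw = vdw_volume(g),
           n_chx = count_chx(g))
  } else NULL

  report <- structure(list(
    compound = config$compound, os_type = config$os_type,
    r_bp = r_bp, z_sp = z_sp,
    density = dens, contact_profile = cprof,
    sp_summary = sp, decomposition = decomp,
    hbond_profile = hprof, hbond_summary = hsum,
    partner_density = pdens, orientation = orient,
    descriptors = desc,
    provenance = list(seed = config$seed,
                      config_hash = rlang::hash(config),
                      package_version =
                        as.character(utils::packageVersion("chromapore")))
  ), class = "slitpore_report")
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_profile(report$density, file.path(out_dir, "analyte_density.tsv"))
  utils::write.table(
    as.data.frame(report$contact_profile),
    file.path(out_dir, "contact_profile.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    as.data.frame(report$partner_density),
    file.path(out_dir, "partner_density.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(glance(report), file.path(out_dir, "summary.yaml"))
  yaml::write_yaml(report$provenance, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.slitpore_report <- function(x, ...) {
  cat("<slitpore_report> ", x$compound, " in W-", x$os_type, "\n", sep = "")
  cat(sprintf("  r_BP = %.2f nm | z_SP = %.3f nm\n", x$r_bp, x$z_sp))
  print(x$sp_summary)
  print(x$decomposition)
  print(x$hbond_summary)
  if (!is.null(x$orientation)) {
    print(x$orientation$partitioning)
    print(x$orientation$adsorption)
  }
  invisible(x)
}

#' @export
tidy.slitpore_report <- function(x, ...) {
  rows <- list(
    tibble(statistic = c("r_bp", "z_sp"), value = c(x$r_bp, x$z_sp)),
    tidy(x$sp_summary),
    tidy(x$decomposition) |>
      mutate(statistic = paste0("fraction_", .data$peak),
             value = .data$fraction) |>
      select("statistic", "value"),
    tidy(x$hbond_summary))
  if (!is.null(x$orientation)) {
    rows <- c(rows, list(tibble(
      statistic = c("cos_phi_partitioning", "cos_phi_adsorption"),
      value = c(x$orientation$partitioning$mean_cos,
                x$orientation$adsorption$mean_cos))))
  }
  bind_rows(rows)
}

#' @export
glance.slitpore_report <- function(x, ...) {
  out <- tibble(
    compound = x$compound, os_type = x$os_type, r_bp = x$r_bp,
    z_sp = x$z_sp,
    mean_contacts = x$sp_summary$mean_contacts,
    mean_position = x$sp_summary$mean_position,
    adsorption_fraction = x$decomposition$adsorption_fraction,
    hb_sp = x$hbond_summary$hb_sp,
    hb_recovery = x$hbond_summary$recovery,
    w_contribution_sp = x$hbond_summary$w_contribution_sp)
  if (!is.null(x$orientation)) {
    out$cos_phi_adsorption <- x$orientation$adsorption$mean_cos
  }
  out
}

#' Read a pipeline run configuration from YAML
#'
#' Keys mirror the arguments of [slitpore_config()] (scalar fields only;
#' profile shapes and probability functions keep their defaults). Unknown
#' compounds raise a config error before any computation.
#'
#' @param path YAML file path.
#' @return A `slitpore_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such config file: ", path))
  y <- yaml::read_yaml(path)
  allowed <- c("compound", "os_type", "box", "pore_width", "scale_xy",
               "n_frames", "frame_dt", "n_analyte", "n_probe_sites",
               "bp_sites_per_nm2", "n_water", "n_os", "seed")
  bad <- setdiff(names(y), allowed)
  if (length(bad) > 0) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  cfg <- do.call(slitpore_config, y)
  .analyte_template(cfg$compound, cfg$n_probe_sites)
  cfg
}
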