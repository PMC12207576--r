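# Interchange formats: extended XYZ frames and the topology TSV. Both are
# plain text so fixtures stay human-readable and diffable.

#' Assemble a topology table
#'
#' Per-molecule records naming the member particles and the annotation sites
#' used by the hydrogen-bond and orientation analyses.
#'
#' @param molecule_id Integer vector.
#' @param compound,role Character vectors.
#' @param particle_ids List of integer vectors (members of each molecule).
#' @param ring_ids List of lists of integer vectors: the aromatic rings of
#'   each molecule (each ring >= 5 particles); empty list when none.
#' @param donor_ids,acceptor_ids Lists of integer vectors: hydrogen-bond
#'   donor (polar H) and acceptor (O/N) particles.
#' @param vector_tail_id,vector_head_id Endpoints of the solute-specific
#'   molecular vector (NA when the compound has none).
#' @return A `topology` tibble.
#' @export
topology <- function(molecule_id, compound, role, particle_ids,
                     ring_ids = NULL, donor_ids = NULL, acceptor_ids = NULL,
                     vector_tail_id = NA_integer_,
                     vector_head_id = NA_integer_) {
  n <- length(molecule_id)
  empty <- replicate(n, integer(0), simplify = FALSE)
  top <- tibble(
    molecule_id = as.integer(molecule_id),
    compound = compound,
    role = role,
    particle_ids = particle_ids,
    ring_ids = ring_ids %||% replicate(n, list(), simplify = FALSE),
    donor_ids = donor_ids %||% empty,
    acceptor_ids = acceptor_ids %||% empty,
    vector_tail_id = as.integer(rep_len(vector_tail_id, n)),
    vector_head_id = as.integer(rep_len(vector_head_id, n))
  )
  validate_topology(top)
  class(top) <- c("topology", class(top))
  top
}

#' @rdname topology
#' @param top A topology tibble to validate.
#' @export
validate_topology <- function(top) {
  all_ids <- unlist(top$particle_ids)
  if (anyDuplicated(all_ids) > 0) abort("particle_ids overlap across molecules")
  for (i in seq_len(nrow(top))) {
    own <- top$particle_ids[[i]]
    rings <- top$ring_ids[[i]]
    for (ring in rings) {
      if (length(ring) < 5) abort("aromatic ring sets need >= 5 members")
      if (!all(ring %in% own)) abort("ring ids outside molecule")
    }
    for (ids in list(top$donor_ids[[i]], top$acceptor_ids[[i]])) {
      if (!all(ids %in% own)) abort("site ids outside molecule")
    }
    vt <- top$vector_tail_id[i]; vh <- top$vector_head_id[i]
    if (!is.na(vt) || !is.na(vh)) {
      if (is.na(vt) || is.na(vh) || vt == vh ||
          !all(c(vt, vh) %in% c(own, 0L))) {
        # tail id 0 denotes the ring center of mass rather than a particle
        abort("vector endpoints must be two distinct ids of the molecule")
      }
    }
  }
  invisible(top)
}

.collapse_ids <- function(x) paste(x, collapse = ";")
.collapse_rings <- function(rings) {
  if (length(rings) == 0) return("")
  paste(vapply(rings, .collapse_ids, character(1)), collapse = "|")
}
.parse_ids <- function(s) {
  if (is.na(s) || s == "") integer(0) else as.integer(strsplit(s, ";")[[1]])
}
.parse_rings <- function(s) {
  if (is.na(s) || s == "") return(list())
  lapply(strsplit(s, "|", fixed = TRUE)[[1]], .parse_ids)
}

#' Write / read a topology TSV
#'
#' Columns: molecule_id, compound, role, particle_ids (semicolon list),
#' aromatic_ring_ids (rings separated by `|`), donor_ids, acceptor_ids,
#' vector_tail_id, vector_head_id. A vector tail id of 0 denotes the
#' molecule's aromatic ring center of mass.
#'
#' @param top A topology tibble.
#' @param path File path.
#' @return `write_topology` returns `path` invisibly; `read_topology` a
#'   topology tibble.
#' @export
write_topology <- function(top, path) {
  flat <- tibble(
    molecule_id = top$molecule_id,
    compound = top$compound,
    role = top$role,
    particle_ids = vapply(top$particle_ids, .collapse_ids, character(1)),
    aromatic_ring_ids = vapply(top$ring_ids, .collapse_rings, character(1)),
    donor_ids = vapply(top$donor_ids, .collapse_ids, character(1)),
    acceptor_ids = vapply(top$acceptor_ids, .collapse_ids, character(1)),
    vector_tail_id = top$vector_tail_id,
    vector_head_id = top$vector_head_id
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) abort(paste0("no such topology file: ", path))
  flat <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  topology(
    molecule_id = flat$molecule_id,
    compound = flat$compound,
    role = flat$role,
    particle_ids = lapply(as.character(flat$particle_ids), .parse_ids),
    ring_ids = lapply(as.character(flat$aromatic_ring_ids), .parse_rings),
    donor_ids = lapply(as.character(flat$donor_ids), .parse_ids),
    acceptor_ids = lapply(as.character(flat$acceptor_ids), .parse_ids),
    vector_tail_id = flat$vector_tail_id,
    vector_head_id = flat$vector_head_id
  )
}

#' Write frames as extended XYZ
#'
#' One block per frame: particle count, then a key=value header
#' (`time_ns`, `Lx`, `Ly`, `Lz` and for slab geometry `surf_lo`, `surf_hi`),
#' then one line per particle: `site_name x y z role molecule_id`
#' (coordinates in nm, written to 1e-6 nm). Particles are written in
#' `particle_id` order so ids are implicit in the row order.
#'
#' @param frames A `slitpore_frames` object (lab coordinates, not folded).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  stopifnot(inherits(frames, "slitpore_frames"))
  if (frames$folded) abort("write_frames expects lab-frame (unfolded) frames")
  con <- file(path, open = "wt")
  on.exit(close(con))
  box <- frames$box
  for (fr in sort(unique(frames$particles$frame))) {
    p <- frames$particles |> filter(.data$frame == fr) |>
      arrange(.data$particle_id)
    hdr <- sprintf("time_ns=%.6f Lx=%.6f Ly=%.6f Lz=%.6f",
                   p$time[1], box[1], box[2], box[3])
    if (frames$geometry == "slab") {
      hdr <- sprintf("%s surf_lo=%.6f surf_hi=%.6f", hdr,
                     frames$surface_planes[1], frames$surface_planes[2])
    }
    writeLines(as.character(nrow(p)), con)
    writeLines(hdr, con)
    writeLines(sprintf("%s %.6f %.6f %.6f %s %d",
                       p$site_name, p$x, p$y, p$z, p$role, p$molecule_id),
               con)
  }
  invisible(path)
}

#' Read extended-XYZ frames
#'
#' Parses the format written by [write_frames()], wraps all coordinates into
#' the box and checks each frame's particle count against the topology.
#'
#' @param path File path.
#' @param top Topology tibble (particle count per frame must match the total
#'   number of particle ids).
#' @return A `slitpore_frames` object in lab coordinates.
#' @export
read_frames <- function(path, top) {
  if (!file.exists(path)) abort(paste0("no such frame file: ", path))
  lines <- readLines(path)
  expected_n <- length(unlist(top$particle_ids))
  i <- 1L
  fr <- 0L
  blocks <- list()
  box <- NULL; planes <- NULL; geometry <- "bulk"
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i])) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) {
      abort(sprintf("malformed frame header at line %d: expected count", i))
    }
    if (i + 1L > length(lines)) {
      abort(sprintf("truncated frame header at line %d", i))
    }
    fr <- fr + 1L
    if (n != expected_n) {
      abort(sprintf(
        "topology error in frame %d: %d particles in file, %d in topology",
        fr, n, expected_n))
    }
    kv <- strsplit(strsplit(lines[i + 1L], "\\s+")[[1]], "=")
    bad <- vapply(kv, length, integer(1)) != 2L
    if (any(bad)) {
      abort(sprintf("malformed frame header at line %d", i + 1L))
    }
    vals <- setNames(as.numeric(vapply(kv, `[`, character(1), 2)),
                     vapply(kv, `[`, character(1), 1))
    box <- unname(vals[c("Lx", "Ly", "Lz")])
    if (all(c("surf_lo", "surf_hi") %in% names(vals))) {
      planes <- unname(vals[c("surf_lo", "surf_hi")])
      geometry <- "slab"
    }
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(body, "\\s+")
    if (any(vapply(parts, length, integer(1)) != 6L)) {
      abort(sprintf("malformed particle line in frame %d", fr))
    }
    m <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
    blocks[[fr]] <- tibble(
      frame = fr,
      time = unname(vals[["time_ns"]]),
      particle_id = seq_len(n),
      site_name = m[, 1],
      role = m[, 5],
      molecule_id = as.integer(m[, 6]),
      x = .wrap(as.numeric(m[, 2]), box[1]),
      y = .wrap(as.numeric(m[, 3]), box[2]),
      z = .wrap(as.numeric(m[, 4]), box[3])
    )
    i <- i + 2L + n
  }
  if (fr == 0L) abort("no frames found in file")
  slitpore_frames(bind_rows(blocks), box = box, surface_planes = planes,
                  geometry = geometry)
}
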