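# Solute descriptors from molecular graphs, plus retention/selectivity
# arithmetic and the literature reference tables for the six-analyte ensemble.

# Group-contribution atomic volumes (A^3) used by the bond/ring-corrected
# van der Waals volume formula. Missing elements raise an error rather than
# defaulting.
.vdw_contrib <- c(
  H = 7.24, C = 20.58, N = 15.60, O = 14.71, F = 13.31, Cl = 22.45,
  Br = 26.52, I = 32.19, P = 24.87, S = 24.43, Se = 28.73, Si = 38.79,
  B = 40.48
)

#' Build a molecular graph from atom and bond tables
#'
#' A minimal heavy-atom graph with implicit hydrogens, sufficient for the
#' group-contribution van der Waals volume and the hydrophobic CH_x group
#' count. Ring counts are derived from the cyclomatic number; the aromatic
#' ring count comes from the cyclomatic number of the aromatic subgraph, so
#' fused systems (naphthalene) resolve to two rings.
#'
#' @param atoms Data frame with columns `atom_id`, `element`, `aromatic`
#'   (0/1 or logical), `n_h` (implicit hydrogen count).
#' @param bonds Data frame with columns `atom1`, `atom2` referencing
#'   `atom_id`s. One row per heavy-atom bond; bonds to implicit hydrogens
#'   are accounted for via `n_h`.
#' @param compound Optional compound name stored on the result.
#' @return An object of class `molecular_graph`.
#' @export
#' @examples
#' benzene <- compound_graphs()[["benzene"]]
#' vdw_volume(benzene)
#' count_chx(benzene)
molecular_graph <- function(atoms, bonds, compound = NA_character_) {
  atoms <- as_tibble(atoms)
  bonds <- as_tibble(bonds)
  stopifnot(all(c("atom_id", "element", "aromatic", "n_h") %in% names(atoms)))
  stopifnot(all(c("atom1", "atom2") %in% names(bonds)))
  if (anyDuplicated(atoms$atom_id) > 0) {
    abort("duplicate atom_id in atoms table")
  }
  unknown <- setdiff(c(bonds$atom1, bonds$atom2), atoms$atom_id)
  if (length(unknown) > 0) {
    abort(paste0("bonds reference unknown atoms: ",
                 paste(unknown, collapse = ", ")))
  }
  atoms$aromatic <- as.logical(atoms$aromatic)
  atoms$n_h <- as.integer(atoms$n_h)
  if (any(atoms$n_h < 0)) abort("n_h must be >= 0")

  if (.n_components(atoms$atom_id, bonds) != 1L) {
    abort("molecular graph must be connected")
  }

  # cyclomatic numbers: whole heavy graph and aromatic subgraph
  n_heavy <- nrow(atoms)
  r_total <- nrow(bonds) - n_heavy + 1L
  ar_ids <- atoms$atom_id[atoms$aromatic]
  ar_bonds <- bonds[bonds$atom1 %in% ar_ids & bonds$atom2 %in% ar_ids, ]
  if (length(ar_ids) > 0) {
    r_a <- nrow(ar_bonds) - length(ar_ids) + .n_components(ar_ids, ar_bonds)
  } else {
    r_a <- 0L
  }
  r_nr <- r_total - r_a
  if (r_a < 0 || r_nr < 0) abort("inconsistent ring census")

  structure(
    list(
      compound = compound,
      atoms = atoms,
      bonds = bonds,
      n_atoms = n_heavy + sum(atoms$n_h),
      n_bonds = nrow(bonds) + sum(atoms$n_h),
      r_aromatic = as.integer(r_a),
      r_nonaromatic = as.integer(r_nr)
    ),
    class = "molecular_graph"
  )
}

# connected components by BFS over an edge list
.n_components <- function(ids, bonds) {
  if (length(ids) == 0) return(0L)
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  adj <- split(c(bonds$atom2, bonds$atom1), c(bonds$atom1, bonds$atom2))
  k <- 0L
  for (root in ids) {
    if (!is.na(comp[[root]])) next
    k <- k + 1L
    queue <- root
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      if (!is.na(comp[[v]])) next
      comp[[v]] <- k
      nb <- adj[[v]]
      queue <- c(queue, nb[nb %in% ids & is.na(comp[nb])])
    }
  }
  k
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph>", x$compound, "\n")
  cat("  heavy atoms:", nrow(x$atoms), " implicit H:", sum(x$atoms$n_h), "\n")
  cat("  bonds (incl. H):", x$n_bonds,
      " aromatic rings:", x$r_aromatic,
      " nonaromatic rings:", x$r_nonaromatic, "\n")
  invisible(x)
}

#' Group-contribution van der Waals volume
#'
#' Sums atomic volume contributions over all atoms (implicit hydrogens
#' included) and applies the bond and ring corrections
#' \deqn{V = \sum_i V_i - 5.92\,N_B - 14.7\,R_A - 3.8\,R_{NR}}
#' where \eqn{N_B} is the total bond count (bonds to hydrogen included),
#' \eqn{R_A} the number of aromatic rings and \eqn{R_{NR}} the number of
#' nonaromatic rings. The result is rounded to 0.01 A^3.
#'
#' @param graph A [molecular_graph()].
#' @return van der Waals volume in A^3.
#' @export
vdw_volume <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  el <- graph$atoms$element
  missing_el <- setdiff(unique(el), names(.vdw_contrib))
  if (length(missing_el) > 0) {
    abort(paste0("no volume contribution for element(s): ",
                 paste(missing_el, collapse = ", ")))
  }
  v_atoms <- sum(.vdw_contrib[el]) + sum(graph$atoms$n_h) * .vdw_contrib[["H"]]
  v <- v_atoms - 5.92 * graph$n_bonds - 14.7 * graph$r_aromatic -
    3.8 * graph$r_nonaromatic
  round(v, 2)
}

#' Count hydrophobic CH_x groups
#'
#' Counts the hydrophobic hydrocarbon structural elements CH_x with
#' x = 0, 1, 2, 3 of a solute. Every carbon atom is one CH_x group (x = 0
#' covers carbons without hydrogens, e.g. ring-fusion or carbonyl carbons);
#' heteroatoms contribute nothing.
#'
#' @param graph A [molecular_graph()].
#' @return Integer count of CH_x groups.
#' @export
count_chx <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  sum(graph$atoms$element == "C")
}

#' Molecular graphs of the analyte ensemble
#'
#' Reads the shipped atom/bond tables for the six analytes (benzene,
#' ethylbenzene, naphthalene, acetophenone, benzyl alcohol, phenol) and
#' returns one [molecular_graph()] per compound.
#'
#' @param atoms_path,bonds_path Paths to TSV tables; defaults to the
#'   fixtures shipped with the package.
#' @return Named list of `molecular_graph` objects.
#' @export
compound_graphs <- function(
    atoms_path = system.file("extdata", "compound_atoms.tsv",
                             package = "chromapore"),
    bonds_path = system.file("extdata", "compound_bonds.tsv",
                             package = "chromapore")) {
  atoms <- utils::read.delim(atoms_path, sep = "\t", stringsAsFactors = FALSE)
  bonds <- utils::read.delim(bonds_path, sep = "\t", stringsAsFactors = FALSE)
  compounds <- unique(atoms$compound)
  graphs <- lapply(compounds, function(cp) {
    molecular_graph(atoms[atoms$compound == cp, -1],
                    bonds[bonds$compound == cp, -1],
                    compound = cp)
  })
  setNames(graphs, compounds)
}

#' Descriptor table for the analyte ensemble
#'
#' Computes the graph-derived descriptors (van der Waals volume, CH_x count)
#' for every shipped compound and joins the literature solute properties
#' (partition coefficients, hydrogen-bond requirement in neat water).
#'
#' @return A tibble with one row per compound.
#' @export
solute_descriptors <- function() {
  graphs <- compound_graphs()
  computed <- purrr::map_dfr(graphs, function(g) {
    tibble(compound = g$compound,
           v_vdw = vdw_volume(g),
           n_chx = count_chx(g))
  })
  left_join(computed, solute_reference(), by = "compound")
}

#' Literature solute properties (reference data)
#'
#' Shipped reference values for the analyte ensemble: octanol-water and
#' hexadecane-water partition coefficients and the hydrogen-bond requirement
#' measure HB_solute-W,max (mean solute-water hydrogen bonds per molecule in
#' neat water; for the hydroxyl compounds split into values with
#' hydrogen-bond donor vs acceptor solvents). These are literature inputs
#' carried as reference data, not quantities recomputed by this package.
#'
#' @return A tibble with provenance column `"literature"`.
#' @export
solute_reference <- function() {
  tibble(
    compound = c("naphthalene", "ethylbenzene", "benzene", "acetophenone",
                 "benzyl_alcohol", "phenol"),
    log_kow = c(3.30, 3.15, 2.13, 1.58, 1.10, 1.46),
    log_khw = c(3.41, 3.20, 2.15, 1.14, -0.43, -1.08),
    hb_max_donor = c(1.79, 1.14, 1.14, 2.18, 2.37, 1.98),
    hb_max_acceptor = c(NA, NA, NA, NA, 1.01, 1.00),
    provenance = "literature"
  )
}

#' Bonded-phase contact radii (reference data)
#'
#' Shipped per-compound, per-organic-solvent contact radii r_BP (nm) for the
#' analyte ensemble, as derived in the original trajectory study from radial
#' distribution functions between analyte centers of mass and bonded-phase
#' united-atom groups. Carried as literature reference data; use
#' [derive_rbp()] to derive radii for synthetic or novel systems.
#'
#' @return A tibble with columns `compound`, `os_type`, `r_bp`, `provenance`.
#' @export
rbp_reference <- function() {
  tibble(
    compound = rep(c("naphthalene", "ethylbenzene", "acetophenone",
                     "benzyl_alcohol", "phenol", "benzene"), 2),
    os_type = rep(c("MeOH", "ACN"), each = 6),
    r_bp = c(0.84, 0.84, 0.81, 0.80, 0.79, 0.79,
             0.83, 0.83, 0.81, 0.79, 0.78, 0.79),
    provenance = "literature"
  )
}

#' Retention factor from elution and dead time
#'
#' `k = (t_r - t_0) / t_0 = t_r / t_0 - 1`. A retention time below the dead
#' time yields a negative k, which is returned with a warning (flagged, not
#' an error, so diagnostic runs can proceed).
#'
#' @param t_r Elution time of the analyte (any time unit).
#' @param t_0 Dead time of the column (same unit, > 0).
#' @return Retention factor(s) `k`.
#' @export
retention_factor <- function(t_r, t_0) {
  if (any(t_0 <= 0)) abort("dead time t_0 must be > 0")
  k <- t_r / t_0 - 1
  if (any(k < 0)) {
    warn("t_r < t_0 gives negative retention factor(s); flagged, not removed")
  }
  k
}

#' Retention factor from compartment occupation
#'
#' The number-distribution form of the retention factor: the ratio of
#' analyte molecules residing in the stationary-phase compartment to those
#' in the mobile-phase compartment at any given time (equivalently the
#' ratio of average residence times).
#'
#' @param n_sp,n_mp Counts (or residence times) in the stationary and
#'   mobile-phase compartments; `n_mp` must be > 0.
#' @return Retention factor(s) `k`.
#' @export
retention_from_counts <- function(n_sp, n_mp) {
  if (any(n_mp <= 0)) abort("mobile-phase count/time must be > 0")
  if (any(n_sp < 0)) abort("stationary-phase count/time must be >= 0")
  n_sp / n_mp
}

#' Selectivity factor
#'
#' `alpha = k2 / k1` with `k2 >= k1`, so `alpha >= 1` by convention;
#' symmetric in its arguments.
#'
#' @param k1,k2 Retention factors (> 0).
#' @return Selectivity factor alpha >= 1.
#' @export
selectivity <- function(k1, k2) {
  if (any(k1 <= 0) || any(k2 <= 0)) {
    abort("selectivity requires positive retention factors")
  }
  pmax(k1, k2) / pmin(k1, k2)
}
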