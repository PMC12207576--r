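---
title: "Methods: interfacial analysis of solvated RPLC slit pores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interfacial analysis of solvated RPLC slit pores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromapore)
```

## The system and its coordinate conventions

A reversed-phase liquid chromatography (RPLC) slit-pore model consists of a
silica slab carrying a bonded phase (C18 chains as united-atom beads, plus
endcapping and residual silanol groups), a water/organic-solvent (W/OS)
mixture filling a pore of width ~10 nm, and a small number of analyte
molecules. The geometry is periodic in x and y only; the two silica surface
planes bound the pore in z.

All analyses work on the *folded* axis: each particle's z is replaced by
its distance to the nearest surface plane, mapping both pore halves onto
one axis z ∈ [0, pore/2]. Both halves are pooled, which doubles the
statistics; a `half` label is kept so that (i) distances between particles
on opposite halves are reconstructed exactly (their true separation is
`pore_width − z₁ − z₂`) and (ii) the orientation sign convention flips the
surface normal consistently for the upper half. Folding is idempotent and
leaves x, y untouched. How a two-surface model should be combined into the
single-surface profiles of the literature is not standardised; fold-and-pool
is this package's choice and is flagged here deliberately.

Regions on the folded axis (defaults in `region_spec()`): the bonded-phase
region z ≤ 1.05 nm, the bulk liquid region z > 2.55 nm, histogram bin width
0.05 nm. The stationary-phase limit `z_SP` is *derived*, not configured
(below).

## Estimators

**Density profiles.** Counts of the selected positions (molecule center of
mass, aromatic-ring center of mass, or a named site) per bin, divided by
`Lx·Ly·Δz·n_surfaces·n_frames`. Mass conservation (profile integral equals
the mean molecule count per frame) is enforced as a test invariant. Centers
of mass are mass-weighted with minimum-image unwrapping in the periodic
directions, so molecules straddling a boundary are handled exactly.

**Bonded-phase contacts.** `C_BP(z)` is the mean number of bonded-phase
united-atom sites with `r ≤ r_BP` (boundary inclusive) of the analyte
center of mass, binned by that center's z. Endcap and residual-OH sites are
excluded by default (`include_endcap` switches this, since "bonded-phase
groups" is ambiguous about endcapping). Frames are grouped into
non-overlapping observation windows by timestamp (default 40 ns); per-bin
means are formed per complete window and averaged across windows, partial
trailing windows dropped. `z_SP` is the linear interpolation of the
`C_BP = 1` crossing between the outermost bin with `C_BP ≥ 1` and the next
visited bin; plateaus at exactly 1 resolve outward (the conservative,
larger stationary phase). Profiles entirely below 1 ("no stationary phase")
or entirely above 1 ("truncated; pore too small") are explicit errors.
`⟨C_BP⟩_SP` and `⟨z_analyte⟩_SP` are analyte-density-weighted averages over
z ≤ z_SP; a bin with analyte density but no contact estimate is an error
rather than a silent zero, because both profiles must come from the same
sampling.

**Contact radii.** For the six-compound analyte ensemble the
trajectory-derived radii (0.78–0.84 nm depending on compound and OS type)
ship as a literature reference table. For synthetic or novel systems
`derive_rbp()` averages analyte–bonded-phase radial distribution functions,
smooths with a 3-bin moving average and returns the first local minimum
after the global maximum, rounded to 0.01 nm. RDF normalisation in a
strongly inhomogeneous slab is not well defined; we normalise by the mean
bonded-phase site density within the bonded-phase region and use only the
minimum *location* downstream.

**Peak decomposition.** The boundary between the partitioning and the
adsorption peak is the minimum of the 3-bin-smoothed analyte profile inside
`[z_bp_end − 0.15, z_bp_end + 0.25]` nm; if no interior minimum exists the
region border (1.05 nm) is used. Fractions are density masses at z ≤ z_SP
in three windows: silica-surface peak (z ≤ 0.55 nm, from the location of
surface-adsorption peaks at ~0.5 nm), partitioning, adsorption. For the
two-way split the surface peak is merged into the partitioning fraction, so
the adsorption contribution is defined against the *total* stationary-phase
density. The alternative (excluding the surface peak from the denominator)
changes the fraction by at most the surface-peak mass; both numbers are
recoverable from the three-way fractions.

**Hydrogen bonds.** Pure distance criteria, no angular term — a deliberate
deviation from common geometric definitions, matching the convention the
profiles are built for. Criteria are keyed by (solute site class, solvent
species): solute donor hydrogens are measured to the solvent key atom (O of
W/MeOH, N of ACN), solute acceptor atoms and aromatic-ring centers of mass
(π systems) to solvent hydrogens. The π cutoffs (0.30 nm to W, 0.32 nm to
MeOH hydrogens) are established values. The functional-group defaults
(0.245/0.245/0.255 nm) are plausible placeholders only: system-specific
per-pair cutoffs should replace them via `hbond_criteria()`, and no claim
is made that the defaults reproduce any published per-pair table. One bond
is counted per (solute site, partner molecule); a site may bind several
molecules, so per-molecule bond numbers exceed 1. `⟨HB⟩_SP` uses the same
density weighting as `⟨C_BP⟩_SP`; the recovery fraction divides by a
bulk-liquid value that is an *input* (estimated from the run's own bulk
region when not supplied). Partner density profiles bin the partner key
atom by *its own* z and condition on the peak holding the *analyte's*
center of mass; analytes beyond z_SP are excluded and tallied. The default
integration window for adsorption-peak partners is 1.5–2.25 nm, where most
of those partners reside.

**Orientation.** `cos φ` between the solute-specific molecular vector
(topology tail → head; tail id 0 denotes the first aromatic ring's center
of mass) and the surface normal pointing into the pore; positive values
mean the head (functional group or side chain) points toward the bulk
liquid. The estimator is the histogram the convention prescribes — 0.05 nm
z bins × 0.1-wide cos φ bins, normalised per z slice — so means are formed
from bin centers and carry a discretisation of at most half a bin (0.05).
Preferential orientations per peak are density-weighted means over the
peak's z interval, labelled isotropic when |mean| < 0.05. Default vector
choices for the ensemble: ring com → terminal CH3 (ethylbenzene), ring com
→ O (phenol, benzyl alcohol, acetophenone); benzene and naphthalene have no
side chain, show no preferential orientation, and carry no vector.

**Descriptors.** The group-contribution van der Waals volume
`V = Σ V_atom − 5.92 N_B − 14.7 R_A − 3.8 R_NR` uses atomic contributions
(C 20.58, H 7.24, O 14.71, N 15.60 Å³, …), the total bond count including
bonds to hydrogen, and the aromatic/nonaromatic ring census from the
cyclomatic numbers of the graph and of its aromatic subgraph (fused
naphthalene resolves to two rings). The contributions are validated in the
test suite by reproducing all six ensemble volumes to ±0.02 Å³ before any
other use. `N(CH_x)` counts every carbon atom as one hydrophobic CH_x group
(x = 0 included, covering ring-fusion and carbonyl carbons): this is the
minimal rule consistent with all six published counts, and the only
genuinely open calibration in the module — a rule excluding carbonyl
carbons would break the acetophenone count.

## The synthetic generator and its ground-truth contract

`generate_slitpore()` draws independent frames from a fully parameterised
density model; `generate_bulk_box()` does the same for homogeneous
neat-water boxes. Frames are i.i.d. samples, not dynamics: every estimator
here is a time average over configurations, so independent sampling
suffices, and the 40 ns observation window is emulated through `frame_dt`
timestamps. Defaults copy the study conditions: a 12.14 × 13.20 × 10.93 nm
box forming a 10 nm pore, 10 analyte molecules, bonded-phase bead density
33.7 sites/nm² of surface concentrated below ~1.05 nm, water rising
sigmoidally to a 9.2 nm⁻³ plateau, an OS "ditch" maximum in the interfacial
region on a 6.8 nm⁻³ plateau, and an analyte mixture of surface (0.5 nm),
partitioning (0.85 nm) and adsorption (1.6 nm) truncated-Gaussian
components with phenol-like weights (0.03/0.07/0.90). `scale_xy` shrinks
the cross-section for cheap sampling; particle counts scale with area and
the z structure is untouched.

The generator's contract is that its bookkeeping is exact:

* every analyte's center-of-mass z, mixture component and cos φ draw is
  recorded;
* each donor/acceptor/π site is engaged with probability
  `hb_engage_prob(z)`, the partner species chosen by `w_weight(z)` (W vs
  OS; classes the OS cannot serve fall back to W), and the partner's
  detection atom placed uniformly within the site's cutoff;
* placements are re-sampled (up to 60 tries, geometric re-check against the
  same criteria table) until the *intended* bond is the only one the
  partner forms, so detected bonds equal intended bonds exactly — residual
  failures are tallied in `truth$unclean` and warned about;
* background solvent keeps a 0.6 nm buffer around all solute sites, and
  analytes are placed with a 1 nm minimum site separation (x,y redrawn
  only, so the configured z mixture is exact) — a dilute-solution
  assumption;
* per-frame particle counts are exactly the configured counts, and a fixed
  seed gives bit-identical output.

Orientation draws come from a truncated-linear density
`f(c) ∝ max(0, 1 + b c)` whose slope is solved from the target mean
(|mean| ≤ 0.6); the mean can be any function of z.

What the generator does **not** emulate: energetics and forces, solvent
orientational structure beyond engaged partners, intramolecular
flexibility (analytes are rigid templates), time correlation between
frames, and surface chemistry (silica atoms are represented only through
the surface planes). Passing recovery tests therefore demonstrates
estimator correctness, not force-field realism; trajectory-derived numbers
from production simulations (contact averages, adsorption contributions,
r_BP, HB_solute–W,max of real compounds) are *reference data* here, shipped
with `provenance = "literature"`, and are never claimed to be reproduced
from synthetic ensembles.

## Numerical choices and degenerate inputs

* Bins start at z = 0 at the surface plane; values are reported at bin
  centers. Positions exactly on a bin edge belong to the upper bin.
* Boundary-inclusive comparisons (`r ≤ cutoff`) everywhere, matching the
  stated criteria; the oracle-equivalence tests include fixtures with
  particles placed exactly on the cutoff sphere.
* Ties at `C_BP = 1` resolve outward (larger z_SP).
* Empty selections, all-zero stationary-phase densities, missing bins where
  density exists, zero-length molecular vectors, bulk frames passed to slab
  analyses (and vice versa) are errors, not silent zeros.
* Round trips through the extended-XYZ format preserve coordinates to
  1e-6 nm (the written precision).

## Problem sizes used by the tests

The suite validates against brute-force oracles on ~100 randomized fixtures
of up to ~10³ particles, and recovers generator parameters from ensembles
of 5·10⁴ analyte samples (mixture fractions, orientation bias) and 10⁴
molecule-frames (engagement probabilities), all within 3 standard errors of
the recorded ground truth. These sizes were chosen so the whole suite runs
interactively on a laptop while keeping the 3-SE bands a few per mil to a
few per cent wide.

## Known limitations

* The hydrogen-bond criterion is distance-only by construction; angular
  definitions will disagree near the cutoffs.
* The functional-group cutoff defaults are unvalidated placeholders (see
  above).
* `N(CH_x)`'s all-carbon rule is calibrated on six compounds; heteroatom-rich
  solutes outside that chemistry may need a different rule.
* Orientation means inherit the 0.1 cos-φ bin discretisation.
* The generator's dilute-solution placement slightly perturbs analyte pair
  correlations (never the z marginal); it is not suitable for studying
  analyte aggregation.
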