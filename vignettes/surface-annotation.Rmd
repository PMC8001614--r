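---
title: "Annotating protein solvent-accessible surfaces with protsurf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating protein solvent-accessible surfaces with protsurf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protsurf)
```

## The problem

Large α-solenoid proteins such as huntingtin expose enormous solvent-accessible
surfaces whose local physicochemical character — polar versus hydrophobic,
interaction-prone versus inert, metal-coordinating versus not — determines how
they engage partner proteins and membranes. Modern cryo-EM models of such
proteins are large but incomplete (unmodeled loops leave backbone gaps), and
residue-level predictions of protein–protein interaction sites or metal-ion
binding sites arrive as flat tables from external predictors. `protsurf`
provides the geometric layer between the two: it defines the surface, maps
smoothed hydropathy onto it, and turns flat site predictions into spatial
objects (patches, coordination neighborhoods, overlaps, domain tallies) that
can be compared, counted and visualized.

## The model and its assumptions

**Surface definition.** Per-atom accessible area is computed with the
Shrake–Rupley method: test points are spread quasi-uniformly over each heavy
atom's solvent-extended sphere (van der Waals radius + probe radius, default
probe 1.4 Å for water) and the accessible area is the fraction of points not
inside any other atom's extended sphere times the sphere area. Residue SASA is
the sum over the residue's atoms. Relative solvent accessibility (RSA) is
residue SASA divided by that residue type's maximal accessible area in a
reference extended state — the Rost & Sander (1994) empirical table by
default, with the Tien et al. (2013) theoretical table selectable. The protein
surface is the set of residues with RSA ≥ 0.20 (inclusive at the threshold).
Occlusion defaults to the full deposited complex — a co-resolved binding
partner buries its interface, and the analyzed surface is the complex's — with
a chain-only mode for sensitivity checks.

Two numerical choices matter here. The test points are a deterministic
Fibonacci (golden-angle) lattice, so areas are reproducible without a seed;
at the default 960 points per atom an isolated sphere's area is exact and
small systems agree with closed-form results to well under 2%. Hydrogens are
ignored (absent from cryo-EM depositions), waters are excluded on load, and
alternate locations resolve to the highest-occupancy record (ties: first by
label).

**Hydropathy mapping.** Each surface residue carries its Kyte–Doolittle
hydropathy index (−4.5 for Arg up to +4.5 for Ile). Because single-residue
values are noisy at surface scale, each value is smoothed by the unweighted
arithmetic mean over all surface residues (itself included) whose Cα lies
within 6 Å of its own Cα. Cα–Cα membership was chosen over all-atom
membership for determinism and consistency with the patch definition below;
the mean is unweighted because no kernel is implied by simple averaging.
Smoothing contracts the range: smoothed extremes always lie within the raw
extremes, and summaries report both (an isolated arginine attains −4.5 either
way).

**Interaction patches.** Predicted interaction-site residues are clustered
into patches: connected components of the graph with an edge between two site
residues whenever their Cα–Cα distance is strictly below 6 Å. Strict `<` is
deliberate at the patch cutoff, while the ion neighborhood radius below is
inclusive `≤` — the two rules mirror the distinct conventions "lower than"
versus "within". Singleton components are patches.

**Ion neighborhoods.** A residue coordinates a predicted ion center if any of
its heavy atoms lies within 3.5 Å of the center. All heavy atoms are used
because 3.5 Å is a coordination-shell distance unreachable from most Cα
positions; a Cα-only mode exists for comparison. Overlap between the
interaction-site set and the ion neighborhood is reported as counts, shared
keys and Jaccard index, and both sets can be tallied against user-supplied
domain intervals (e.g. N-HEAT / BRIDGE / C-HEAT). Domain boundaries are never
hard-coded: the published boundary definitions live in the structural
literature, so they are a configuration input, with a first-match rule and a
warning on overlapping intervals.

**Gap accounting.** For a declared full region in author numbering, a gap is
any maximal run of absent author numbers, interior or terminal. The invariant
`n_solved + Σ gap lengths = region length` is asserted property-style in the
test suite. Author numbering (with insertion codes) is the residue identity
used by every module.

## The synthetic-data generator

All tests run offline against `build_helix_bundle()`, which emits ideal
α-helices (rise 1.5 Å/residue, 100°/residue twist, Cα at 2.3 Å from the
axis) on parallel axes, one chain per helix, with an ideal-geometry backbone
(N, Cα, C, O) and a single Cβ-like pseudo-atom standing in for each side
chain (absent for Gly). Peptide N and C atoms are tilted toward the helix
axis and the carbonyl O points along the rise, which keeps every non-bonded
pair beyond a 1 Å overlap bound (checked at generation time; consecutive Cα
distances come out at 3.83 Å).

`plant_sites()` marks runs of consecutive residues as interaction sites such
that runs are mutually farther than the patch cutoff — the true patch count
is known by construction and verified geometrically before the instance is
returned. `plant_ions()` places one ion per target residue at an exact offset
from a chosen atom (the pseudo side chain if present), with the chosen atom
guaranteed nearest in the whole model and non-target residues kept at a
clearance distance, so the true neighborhood at any radius between the offset
and the clearance is exactly the target set. All generator output is
bit-for-bit reproducible under a fixed seed, and the generators restore the
caller's RNG state.

What the generator does *not* emulate: real side-chain rotamers and packing
density (residues are 4–5 atoms, so absolute SASA and RSA run high relative
to real proteins — one reason RSA > 1 is permitted and logged), loop regions,
β-structure, and crystallographic artifacts. Passing the planted-truth suite
therefore demonstrates the correctness of the geometry, clustering and
accounting machinery, not agreement with any particular deposited structure;
statistics on real entries additionally depend on the deposited coordinates
and on the upstream predictors that produce the site tracks.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `probe_radius` | 1.4 | Å | solvent probe for SASA |
| `n_points` | 960 | — | test points per atom (≥ 32) |
| `rsa_threshold` | 0.20 | fraction | surface membership (≥) |
| `kd_radius` | 6.0 | Å | hydropathy smoothing neighborhood |
| `patch_cutoff` | 6.0 | Å | patch contact graph edge (<) |
| `ion_radius` | 3.5 | Å | ion coordination neighborhood (≤) |
| `occluder_scope` | `complex` | — | who occludes whom in SASA |
| `max_asa_table` | `RostSander1994` | — | RSA normalization constants |
| `polarity_scheme` | `textbook` | — | His counted as charged |

The polarity partition (charged = Asp, Glu, Lys, Arg, His; polar-uncharged =
Ser, Thr, Asn, Gln, Tyr, Cys; non-polar = the rest) is the common textbook
scheme; published polarity percentages rarely state their convention, so a
`his_neutral` variant is provided and both are exercised in the tests.

## A worked run

```{r pipeline}
td <- tempfile(); dir.create(td)
b <- build_helix_bundle(3, 40, spacing = 12, seed = 7)
ps <- plant_sites(b$model, k_patches = 5, patch_size = 3, seed = 3)
pin <- plant_ions(b$model, c("A:5:", "B:20:", "C:33:"), offset = 3.0, seed = 4)

write_annotated_pdb(b$model, numeric(), file.path(td, "bundle.pdb"))
write.table(as.data.frame(ps$sites)[, c("chain", "resno", "icode", "resid", "score")],
            file.path(td, "sites.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(x = pin$ions$points[, 1], y = pin$ions$points[, 2],
                       z = pin$ions$points[, 3], label = pin$ions$labels),
            file.path(td, "ions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

report <- run_pipeline(list(
  structure = file.path(td, "bundle.pdb"), chain = "A", full_region = c(1, 40),
  site_track = file.path(td, "sites.tsv"), ion_track = file.path(td, "ions.tsv"),
  n_points = 240, output_dir = file.path(td, "out")
), quiet = TRUE)

c(n_patches = report$patches$n_patches,
  n_ion_neighbors = report$ions$n_neighbor_residues,
  n_overlap = report$overlap$n_intersection)
```

The planted truth (5 patches, 3 ion targets, no overlap) is recovered
exactly. On a real entry the same call takes a PDB/mmCIF path, the deposited
full region, and predictor output tables; every stage writes a TSV/JSON file
plus B-factor-annotated PDBs for viewer-based coloring (smoothed hydropathy
clamped to ±4.5 on the blue–white–red convention; interaction = 1, ion
neighbor = 2, both = 3).

## Problem sizes and design choices

The test suite and the acceptance script use bundles of 150–240 residues
(3–4 helices of 40–60 residues) and 120–960 sphere points; these sizes make
the planted constructions non-trivial (dozens of patches across chains)
while keeping the whole offline suite fast. The acceptance script's study
conditions are fixed at a three-helix bundle of 180 residues with uniform
residue composition, 8 planted patches of 4 residues and 6 planted ions (2
inside patches), with all randomness derived from the single `--seed`
argument.

Where the design was genuinely open we chose as follows: surface area is
reported both as the sum over surface residues and as the whole-chain total
(published totals do not always say which); interval coverage statistics are
reported as computed from the interval arithmetic, even when a source
document's stated count differs by one; and the declared-region length, not
the deposited residue count, is the coverage denominator.

## Known limitations

- SASA agreement with DSSP-derived numbers is approximate by nature: DSSP's
  surface integration differs from Shrake–Rupley, so counts on real entries
  should be compared with percent-level tolerance, never bit-exactness.
- The package consumes site predictions; it does not re-implement any
  interface or ion-site predictor, and prediction quality is outside its
  scope.
- No secondary-structure assignment, superposition, or rendering; annotated
  PDBs delegate visualization to external viewers.
- Multi-model (NMR) ensembles are truncated to the first model.
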