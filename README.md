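# protsurf

Solvent-accessible surface annotation and spatial site analysis for protein
structures.

`protsurf` is for structural bioinformaticians who have (i) a deposited
protein structure — typically a large, partially modeled cryo-EM complex —
and (ii) residue-level predictions from external tools (protein–protein
interaction sites, metal-ion centers), and who want the geometric analyses
that connect the two:

- **Surface definition** — per-residue solvent-accessible surface area
  (SASA) by the Shrake–Rupley method (probe 1.4 Å, deterministic
  Fibonacci-lattice test points), normalized to relative solvent
  accessibility (RSA = SASA / max-ASA of the residue type, Rost & Sander
  1994 table by default), surface = residues with RSA ≥ 0.20.
- **Hydropathy mapping** — Kyte–Doolittle values of surface residues,
  spatially smoothed by the unweighted mean over all surface residues whose
  Cα lies within 6 Å.
- **Composition** — residue-type counts and polar / charged / non-polar
  fractions of any residue set.
- **Interaction patches** — connected components of the site-residue contact
  graph with edges at Cα–Cα distance < 6 Å.
- **Ion neighborhoods** — residues with any heavy atom within 3.5 Å of a
  predicted ion center, plus overlap (counts, Jaccard) between site classes
  and domain-interval tallies.
- **Gap accounting** — backbone gaps and coverage of a declared region in
  author numbering, for incompletely modeled cryo-EM chains.
- **Synthetic generator** — ideal α-helix bundles with planted interaction
  patches and ions whose ground truth is known exactly, so the whole
  pipeline is testable offline.

## Worked example

```r
library(protsurf)

td <- tempfile(); dir.create(td)
b   <- build_helix_bundle(3, 40, spacing = 12, seed = 7)   # 120-residue bundle
ps  <- plant_sites(b$model, k_patches = 5, patch_size = 3, seed = 3)
pin <- plant_ions(b$model, c("A:5:", "B:20:", "C:33:"), offset = 3.0, seed = 4)

write_annotated_pdb(b$model, numeric(), file.path(td, "bundle.pdb"))
write.table(as.data.frame(ps$sites)[, c("chain","resno","icode","resid","score")],
            file.path(td, "sites.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(x = pin$ions$points[,1], y = pin$ions$points[,2],
                       z = pin$ions$points[,3], label = pin$ions$labels),
            file.path(td, "ions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

report <- run_pipeline(list(
  structure  = file.path(td, "bundle.pdb"), chain = "A", full_region = c(1, 40),
  site_track = file.path(td, "sites.tsv"),  ion_track = file.path(td, "ions.tsv"),
  n_points = 240, output_dir = file.path(td, "out")))
```

The run logs each stage and prints, among others:

```
[protsurf] surface: 40 of 40 residues at RSA >= 0.20, area 3045.8 A^2
[protsurf] 15 site residues -> 5 patches (cutoff 6.0 A)
[protsurf] 3 ions -> 3 neighbor residues (radius 3.5 A)
[protsurf] overlap: 0 residues shared (Jaccard 0.000)
```

meaning: every residue of the small synthetic chain A is exposed with a
summed surface of ≈3046 Å²; the 15 planted site residues cluster into
exactly the 5 planted patches; the 3 planted ions each coordinate exactly
their target residue; and the two site classes share no residues — all equal
to the generator's ground truth. `report.json`, per-stage TSVs and two
B-factor-annotated PDBs (smoothed hydropathy; site classes coded 1/2/3) are
written to the output directory. On a real entry, pass the PDB/mmCIF path,
the deposited region (e.g. `full_region = c(97, 3139)`), and the predictor
output tables instead.

A thin command-line wrapper with `analyze`, `validate` and `synth`
subcommands is installed at `inst/cli/protsurf.R`.

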