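Package: protsurf
Title: Solvent-Accessible Surface Annotation and Spatial Site Analysis for Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the solvent-accessible surface of protein
    structures and to analyze externally predicted residue annotations on it.
    Computes per-residue solvent-accessible surface area with the
    Shrake-Rupley method, normalizes it to relative solvent accessibility
    (RSA) and defines the protein surface by an RSA threshold; maps
    Kyte-Doolittle hydropathy onto the surface with spatial smoothing over a
    fixed-radius neighborhood; tabulates surface residue composition and
    polarity fractions; clusters predicted protein-protein interaction-site
    residues into spatial patches via a C-alpha contact graph; extracts
    residues coordinating predicted metal-ion centers; and reports overlap
    and domain assignment between site classes. Includes backbone-gap and
    coverage accounting for cryo-EM models, a synthetic helix-bundle
    generator with planted ground truth for offline testing, and a
    single-command pipeline producing a machine-readable report bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
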