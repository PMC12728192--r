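Package: gatescope
Title: Lateral-Gate Conformational Analysis for Beta-Barrel Membrane
    Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Structure-analysis toolkit for the lateral gate of
    beta-barrel membrane protein assembly machines (Sam50/BamA-type
    16-stranded barrels). Reads and writes atomic models in PDB and mmCIF
    format, performs Kabsch rigid superposition with C-alpha RMSD
    reporting, computes the gate-loop openness statistic that places a
    conformation on the closed-to-stalled opening scale, detects hydrogen
    bonds geometrically (strict donor-H-acceptor mode and a heavy-atom
    mode for models without hydrogens), maps leaflet-to-leaflet membrane
    thickness on a lateral grid with a local-patch thinning statistic,
    and ranks candidate ligand poses by real-space map correlation,
    nonbonded interaction energy, and interface hydrogen-bond counts.
    A synthetic-data module generates idealized openable beta-barrels,
    bilayer headgroup clouds, seam hydrogen-bond trajectories, and
    ligand pose sets so every analysis is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
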