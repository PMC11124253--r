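Package: dockselect
Title: Post-Docking Selectivity Analysis for Paired Virtual Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning paired AutoDock-Vina-style virtual-screening
    outputs against two related targets (such as acetylcholinesterase and
    butyrylcholinesterase) into selectivity calls. Parses multi-model ligand
    PDBQT output and rigid-receptor PDBQT files, computes per-ligand
    binding-mode statistics (first-mode energy, mean, standard deviation,
    standard error, mean RMSD bounds), pairs ligands across screens to form
    the signed and absolute binding-energy difference (the selectivity
    statistic), classifies ligands as selective for either target or
    nonselective, summarizes screens with occurrence histograms, compares
    distributions with a tie-corrected Mann-Whitney U test, maps
    residue-proximity densities of ligand H, O and N atoms under per-element
    distance cutoffs, applies rotatable-bond and Lipinski-subset ligand
    filters, and generates seeded synthetic paired screens and geometric
    fixtures with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
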