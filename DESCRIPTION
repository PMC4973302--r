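Package: tunneldock
Title: Rigid-Body Ensemble Docking and Orientation Analysis for
    Tunnel-Cavity Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds large ensembles of rigid ligand poses inside
    tunnel-shaped protein cavities by least-squares (Kabsch)
    superposition of conformer libraries onto docked templates, in both
    the direct and the end-to-end inverted atom correspondence. Poses
    are scored by steric-clash counts (heavy-atom contacts closer than
    a cutoff) and potential-hydrogen-bond counts (hydroxyl oxygen to
    protein donor/acceptor within a distance window), classified by
    portal penetration and terminal-ring orientation, and analysed for
    orientation preference by top-decile frequency counts with a
    chi-squared goodness-of-fit test. Includes grid-based cavity
    detection (volume, tunnel length, enclosed-solvent counting),
    alternate-conformation (altloc) protein models with deletion and
    truncate-to-alanine perturbations for robustness reruns, and a
    fully synthetic generator of tunnel proteins and rigid two-ring
    diol ligand libraries with known ground truth, modelled on the
    carotenoid-binding START-domain problem.
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
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
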