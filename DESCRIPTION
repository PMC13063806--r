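Package: lipidraft
Title: Lipid Bilayer Trajectory and Langmuir Isotherm Analysis for
    Raft-Ligand Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for characterising how small amphiphilic
    ligands (e.g. polyphenols) interact with liquid-ordered (Lo) and
    liquid-disordered (Ld) model membranes.  Computes membrane structure
    metrics (area per lipid, bilayer thickness, area compressibility
    modulus from box-area fluctuations), lateral diffusion coefficients by
    mean-square-displacement fitting, geometric hydrogen-bond detection,
    heavy-atom contact series and cumulative strong-binding times,
    Shrake-Rupley solvent-accessible surface area partitioned between
    lipid headgroups and tails, mass-density profiles with a five-region
    depth classification, and Langmuir surface-pressure-area isotherm
    features (limiting area, collapse point, compressibility modulus,
    condensation/expansion mixing slopes).  Includes a synthetic-data
    generator producing planar bilayer trajectories, two-state binding
    traces, planted hydrogen-bond geometries and parametric isotherms
    with known ground truth, plus replicate-level statistics (one-way
    ANOVA, Pearson correlation, fold-change tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
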