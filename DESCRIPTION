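Package: fragsite
Title: Fragment-Screening Analytics for Binding-Site Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for biophysical fragment-based screening
    campaigns against a protein target. Defines ligand-binding sites from
    protein-ligand coordinates by heavy-atom proximity ranking, compares
    binding-site sequence conservation against global ortholog conservation
    from a multiple sequence alignment, calls fragment binders from
    ligand-observed CPMG NMR attenuation ratios with competition-based site
    assignment, simulates and fits one-set-of-sites isothermal titration
    calorimetry isotherms, derives binding free energy and ligand
    efficiency, fits four-parameter logistic dose-response curves, performs
    backbone Kabsch superposition with RMSD, and generates seeded synthetic
    inputs (ortholog families, screening decks, toy structures) so the full
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    seqinr,
    stats,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
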