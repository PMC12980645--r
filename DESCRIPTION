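Package: coilstaple
Title: Staple-Site Evaluation for Crosslinked Coiled-Coil Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for evaluating peptide staple (macrocyclization) sites on
    the disulfide-tethered alpha-helical coiled-coil heterodimer A/B and
    related scaffolds.  Implements heptad-register bookkeeping and
    cross-chain anchor-pair classification, two-state thermal denaturation
    fitting with Gibbs-Helmholtz stability differences, anchor-spacing
    (Cbeta-Cbeta) and per-atom fluctuation (RMSF) statistics on folded- and
    unfolded-temperature conformational ensembles, linear stabilization
    models linking unfolded-state constraint to folding free energy, a
    folded-state compatibility classifier with ranked site recommendations,
    and seeded synthetic generators (melt curves, idealized coiled-coil
    ensembles, tethered random-coil unfolded ensembles) with known ground
    truth.  Ships a reference data table of observed and simulated melting
    and anchor-spacing measurements for stapled A/B variants together with a
    reproduction report for the derived quantities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
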