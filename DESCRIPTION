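Package: asymdimer
Title: Asymmetric Homodimer Analysis from NMR Exchange Spectroscopy and
    Interface Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to establish whether a protein homodimer is symmetric or
    asymmetric from solution NMR and structural evidence. Detects two-state
    peak doubling in 2D (1H,15N) peak lists, computes compound chemical-shift
    asymmetry profiles, fits a global two-site exchange rate to EXSY
    auto/cross-peak intensity series with bootstrap confidence intervals,
    classifies dimer topology from state-labelled intermolecular NOE
    contacts, and analyses beta-sheet dimer interfaces (backbone hydrogen
    bonds, strand register, C2 swap-RMSD symmetry, Shrake-Rupley surface
    burial, interface overlap). A synthetic-data module generates every
    input at desk scale: exchange-relaxation intensity series, doubled peak
    lists, and idealized two-chain beta-strand dimers in antiparallel,
    symmetric-parallel and register-shifted parallel geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
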