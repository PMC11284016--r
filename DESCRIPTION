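Package: fvhumanize
Title: Antibody Humanization by CDR Grafting and Framework Shuffling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico antibody humanization toolkit for variable-domain (Fv)
    engineering. Numbers heavy and kappa chains under IMGT or Kabat layouts and
    segments them into framework and complementarity-determining regions;
    selects the most homologous human germline framework per region and grafts
    murine CDRs onto it; applies and proposes structure-guided back mutations
    via a four-class residue interaction analysis (hydrogen bonds, hydrophobic
    contacts, salt bridges, pi-pi stacking at fixed distance thresholds) and
    Shrake-Rupley solvent accessibility; assembles and decomposes combinatorial
    framework-shuffled libraries; scores repertoire-based humanness (9-mer
    content, top-k identity) and counts predicted MHC class II strong binders.
    Ships seeded synthetic-data generators so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
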