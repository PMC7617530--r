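Package: oncostruct
Title: Protein Structural Context of Cancer Missense Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyse cancer-associated missense mutations in their protein
    structural context. Reads experimental (PDB/mmCIF) and predicted protein
    structures, maps protein sequences onto chains, classifies residues by
    relative solvent accessibility and secondary structure, rank-normalises
    per-protein stability perturbations (the ddG_rank metric), quantifies
    three-dimensional clustering of mutated residues (the EDC metric), and
    performs gene-level enrichment statistics to prioritise candidate tumour
    suppressors and oncogenes. Includes seed-deterministic synthetic-data
    generators (chains, stability landscapes, mutation cohorts with truth
    labels) so the full pipeline can be exercised and validated without
    external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
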