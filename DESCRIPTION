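Package: dombind
Title: Domain-Based Aggregation of Protein-Ligand Co-Complex Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates protein-ligand co-complex structures by protein domain
    family to estimate per-domain-position ligand-binding frequencies. Parses
    PDB/mmCIF co-complexes, maps profile-HMM match states onto structure
    residues, classifies ligands (DNA/RNA base and backbone, peptide, ion,
    metabolite-like and drug-like small molecules via Tanimoto similarity),
    scores each match state by the Henikoff-weighted fraction of instances
    with a heavy side-chain atom within a distance cutoff of the ligand, and
    attaches bootstrap standard errors. Provides interface-consistency and
    cross-validated precision-recall evaluation, transfer of confident
    binding frequencies onto query protein sequences, and Poisson-binomial
    tests for overlap between inferred binding sites and site sets of
    interest. Includes a synthetic-data generator with planted binding
    geometry for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    ChemmineOB,
    Biostrings,
    optparse
Config/testthat/edition: 3
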