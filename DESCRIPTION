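Package: neuroconcord
Title: Cross-Species Concordance Scoring of Disease Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a human late-onset Alzheimer's disease expression
    signature from multiple case/control microarray datasets (background
    filtering, quantile normalization, batch standardization, robust
    covariate adjustment, SAM-style permutation selection with
    cross-dataset commonality, and subtraction of age-associated genes),
    characterizes the signature by repressor-weighted pathway activity and
    protein-protein interaction network topology (degree profiles,
    set-to-set shortest-path distances, size-adjusted permutation nulls),
    scans promoters for transcription-factor binding sites with position
    weight matrices and clusters genes by Jaccard similarity of binding
    profiles, and scores animal-model expression profiles for concordance
    with the human signature via one-sided permutation tests with
    strong/weak classification. A synthetic-data generator with known
    ground truth emulates the multi-cohort study design so every stage is
    testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    limma,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
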