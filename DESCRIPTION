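Package: codonlens
Title: Codon-Level Dataset Curation and Embedding-Space Neighborhood Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing nucleotide- and protein-level sequence
    representations on protein tasks at the codon level: coding-sequence (CDS)
    validation against protein translations, degeneracy-aware dataset
    construction for deep mutational scans (Complete and Unique training sets,
    single-codon mutation libraries, fitness normalization), synonymous-codon
    sampling strategies (within-sequence permutation and uniform resampling),
    codon-usage and GC-content features with nearest-centroid species
    classification, embedding augmentation, and a k-nearest-neighbor protocol
    for probing local embedding-space structure (mutated-position distances,
    mutant-amino-acid neighborhood accuracy, and the exact random-arrangement
    baseline). Includes seeded synthetic-data generators that plant ground
    truth at every stage: species-biased CDS corpora, single-codon mutation
    scans with fitness labels, and embedding matrices with controllable
    neighborhood structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
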