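#!/usr/bin/env Rscript
# Simulate the two synthetic datasets used throughout the analysis and write
# them out as standard bundles (FASTA + TSV metadata):
#   (a) a 5-species CDS corpus with species-specific codon usage, distinct
#       label profiles, and a GC effect on the label;
#   (b) a complete single-codon mutation scan of a 100-codon reference gene
#       with planted normalized-fitness labels.

library(codonlens)

seed <- 20260928
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

message("Simulating 5-species corpus (200 sequences/species, 300 codons) ...")
models <- default_species_models(5, alpha = 0.5, seed = seed)
corpus <- gen_species_corpus(models, n_per_species = 200,
                             protein_length = 300, seed = seed + 1)
write_fasta(corpus, "results/data/species_corpus.fasta")
write_table(corpus[, c("id", "species", "label")],
            "results/data/species_corpus.tsv")
message("  ", nrow(corpus), " sequences; label range ",
        paste(round(range(corpus$label), 1), collapse = " - "), " degC")

message("Simulating mutation scan (100 codons, all 63 substitutions/position) ...")
scan <- gen_mutation_scan(100, fitness_model = "position_effect",
                          seed = seed + 2)
write_fasta(scan$reference, "results/data/scan_reference.fasta")
write_fasta(scan$variants, "results/data/scan_variants.fasta")
write_table(scan$variants[, c("id", "label", "mutation", "position",
                              "ref_codon", "alt_codon")],
            "results/data/scan_variants.tsv")
message("  ", nrow(scan$variants), " variants, ",
        length(scan$degeneracy_groups), " distinct proteins; ",
        round(100 * mean(scan$variants$label < 1)),
        "% of variants below wildtype fitness")

prof <- codon_usage(corpus)
write_table(cbind(id = as.data.frame(prof)$codon, as.data.frame(prof)[-1]),
            "results/data/corpus_codon_usage.tsv")
message("Wrote corpus codon-usage table (64 rows).")
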