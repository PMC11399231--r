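#!/usr/bin/env Rscript
# Degeneracy-aware training sets for the mutation scan: hold out a random
# test set, then build the two training-set variants —
#   Complete: all variants except those degenerate with any test protein;
#   Unique:   one CDS per distinct protein (raw labels retained).
# Also demonstrates the fitness readout: count-weighted log-concentration
# fitness, normalized by wildtype.

library(codonlens)

seed <- 20260928
dir.create("results", showWarnings = FALSE)

scan <- gen_mutation_scan(100, seed = seed + 2)
v <- scan$variants

set.seed(seed + 5)
test_idx <- sample(nrow(v), 630)  # 10% held out
train <- v[-test_idx, ]; class(train) <- class(v)
test <- v[test_idx, ]; class(test) <- class(v)
test <- dedupe_test_degenerates(test, seed = seed + 6)$kept

complete <- build_complete_set(train, test)
unique_set <- build_unique_set(v, seed = seed + 7)

message("Scan: ", nrow(v), " variants, ",
        length(scan$degeneracy_groups), " distinct proteins")
message("Test set after degenerate-pair removal: ", nrow(test))
message("Complete training set: ", nrow(complete), " of ", nrow(train),
        " (", nrow(train) - nrow(complete), " degenerate with test removed)")
message("Unique training set: ", nrow(unique_set),
        " (one CDS per distinct protein)")

tab <- data.frame(
  id = c("all_variants", "test", "complete_train", "unique_train"),
  n = c(nrow(v), nrow(test), nrow(complete), nrow(unique_set)),
  frac_below_wt = c(mean(v$label < 1), mean(test$label < 1),
                    mean(complete$label < 1), mean(unique_set$label < 1))
)
write_table(tab, "results/curation_set_sizes.tsv")

# fitness readout on a toy selection gradient: allele counts across plates
# at increasing drug concentration, wildtype surviving everywhere
plates <- c(1, 10, 100, 1000)
counts <- rbind(wt = c(10, 10, 10, 10),
                tolerant = c(0, 5, 10, 20),
                sensitive = c(20, 5, 0, 0))
f <- apply(counts, 1, fitness_weighted_average, concentrations = plates)
w <- normalize_fitness(f, f["wt"])
message("Toy fitness readout (normalized by wildtype):")
for (a in names(w)) message(sprintf("  %-10s f = %.3f  w = %.3f%s", a, f[a],
                                    w[a], ifelse(w[a] > 1, "  (> WT)", "")))
write_table(data.frame(id = names(w), fitness = unname(f),
                       normalized = unname(w)),
            "results/curation_fitness_demo.tsv")
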