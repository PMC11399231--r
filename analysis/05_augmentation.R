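#!/usr/bin/env Rscript
# Do global sequence features close the gap for a representation that lacks
# them? Labels in the species corpus are species mean + GC slope + noise.
# We give a single-layer ridge head deliberately uninformative (random)
# embeddings and measure held-out R^2 as one-hot species and z-scored
# GC-content blocks are appended: the R^2 ladder none < species < species+GC
# quantifies how much of the signal each global feature carries.

library(codonlens)

seed <- 20260928
dir.create("results", showWarnings = FALSE)

n_seeds <- 5
r2 <- matrix(NA_real_, n_seeds, 3,
             dimnames = list(NULL, c("none", "species", "species_gc")))
for (s in seq_len(n_seeds)) {
  models <- default_species_models(5, alpha = 0.5, seed = seed + 10 * s)
  corpus <- gen_species_corpus(models, 120, 150, seed = seed + 10 * s + 1)
  n <- nrow(corpus)
  set.seed(seed + 10 * s + 2)
  idx <- sample(n, n %/% 2)
  train <- corpus[idx, ]; class(train) <- class(corpus)
  test <- corpus[-idx, ]; class(test) <- class(corpus)
  E_tr <- embedding_set(train$id, matrix(rnorm(nrow(train) * 8), ncol = 8),
                        data.frame(label = train$label))
  E_te <- embedding_set(test$id, matrix(rnorm(nrow(test) * 8), ncol = 8),
                        data.frame(label = test$label))
  gc_tr <- gc_feature(train)
  gc_te <- gc_feature(test, stats = attr(gc_tr, "stats"))
  sp_tr <- one_hot_species(train)
  sp_te <- one_hot_species(test, levels = attr(sp_tr, "levels"))
  blocks <- list(none = list(), species = list(sp_tr),
                 species_gc = list(sp_tr, gc_tr))
  blocks_te <- list(none = list(), species = list(sp_te),
                    species_gc = list(sp_te, gc_te))
  for (v in names(blocks)) {
    head <- fit_linear_head(augment(E_tr, blocks[[v]]), ridge = 1e-8)
    pred <- predict(head, augment(E_te, blocks_te[[v]]))
    r2[s, v] <- score_predictions(pred, test$label)$r_squared
  }
}

tab <- data.frame(id = colnames(r2), augmentation = colnames(r2),
                  mean_r2 = colMeans(r2), sd_r2 = apply(r2, 2, sd))
write_table(tab, "results/augmentation_r2.tsv")
message("Held-out R^2 (mean over ", n_seeds, " seeds):")
for (v in colnames(r2)) {
  message(sprintf("  %-11s %.3f (sd %.3f)", v, mean(r2[, v]), sd(r2[, v])))
}
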