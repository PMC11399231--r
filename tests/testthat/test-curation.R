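test_that("translation-mismatch filter keeps matches and logs rejections", {
  cds <- cds_records(c("a", "b", "c"), c("ATGGCT", "ATGGCT", "ATGGC"),
                     validate = FALSE)
  prot <- data.frame(id = c("a", "b", "c"),
                     sequence = c("MA", "MV", "MA"))
  res <- filter_translation_mismatch(cds, prot)
  expect_identical(res$kept$id, "a")
  expect_setequal(res$log$id, c("b", "c"))
  expect_identical(res$log$mismatch_position[res$log$id == "b"], 2L)
  expect_match(res$log$reason[res$log$id == "c"], "frame")
  # empty input -> empty output
  res0 <- filter_translation_mismatch(cds[0, ], prot)
  expect_identical(nrow(res0$kept), 0L)
  expect_identical(nrow(res0$log), 0L)
  # planted mismatches are recovered exactly
  set.seed(31)
  seqs <- vapply(sample.int(1e6, 10), function(s) random_cds(20, s),
                 character(1))
  cds <- cds_records(sprintf("p%02d", 1:10), seqs)
  prot <- data.frame(id = cds$id, sequence = translate_cds(cds$sequence))
  bad <- c(2, 5, 9)
  prot$sequence[bad] <- sub("M", "W", prot$sequence[bad])
  res <- filter_translation_mismatch(cds, prot)
  expect_setequal(res$log$id, cds$id[bad])
  expect_identical(nrow(res$kept), 7L)
})

test_that("degeneracy grouping partitions by translated protein", {
  g <- group_degenerate(c("GCT", "GCC", "ATG"))
  expect_length(g, 2L)
  expect_setequal(g[["A"]], c(1L, 2L))
  expect_identical(g[["M"]], 3L)
  # all-distinct proteins -> singletons
  g <- group_degenerate(c("ATG", "GCT", "TGG"))
  expect_true(all(lengths(g) == 1L))
  # a full synonymous scan of one codon yields groups matching synonym sets
  code <- genetic_code()
  seqs <- paste0("ATG", code$synonym_sets[["L"]])
  g <- group_degenerate(seqs)
  expect_identical(lengths(g)[["ML"]], 6L)
})

test_that("Complete set removes exactly the train CDS degenerate with test", {
  train <- cds_records(c("t1", "t2"), c("GCT", "ATG"))
  test <- cds_records("x1", "GCC")
  out <- build_complete_set(train, test)
  expect_identical(out$id, "t2")
  # disjoint proteomes leave train untouched
  train2 <- cds_records(c("t1", "t2"), c("TGG", "ATG"))
  expect_identical(build_complete_set(train2, test)$id, train2$id)
  # resulting protein sets are disjoint (property)
  scan <- gen_mutation_scan(8, seed = 11)
  v <- scan$variants
  test_idx <- seq(1, nrow(v), by = 7)
  out <- build_complete_set(v[-test_idx, ], v[test_idx, ])
  expect_length(intersect(translate_cds(out$sequence, mode = "lenient"),
                          translate_cds(v$sequence[test_idx],
                                        mode = "lenient")), 0L)
})

test_that("Unique set is nondegenerate, maximal, and seed-reproducible", {
  cds <- cds_records(c("a", "b", "c"), c("GCT", "GCC", "ATG"))
  u <- build_unique_set(cds, seed = 1)
  expect_identical(nrow(u), 2L)
  expect_true("c" %in% u$id)  # singleton group always kept
  scan <- gen_mutation_scan(6, seed = 13)
  u1 <- build_unique_set(scan$variants, seed = 5)
  u2 <- build_unique_set(scan$variants, seed = 5)
  expect_identical(u1, u2)  # bit-identical under the same seed
  # nondegenerate: pairwise-distinct translations
  expect_false(anyDuplicated(translate_cds(u1$sequence, mode = "lenient")) > 0)
  # maximal: one representative per degeneracy group
  expect_identical(nrow(u1), length(group_degenerate(scan$variants)))
  # raw labels are retained, not averaged
  expect_true(all(u1$label %in% scan$variants$label))
  # different seeds differ only within multi-member groups
  u3 <- build_unique_set(scan$variants, seed = 6)
  keys1 <- translate_cds(u1$sequence, mode = "lenient")
  keys3 <- translate_cds(u3$sequence, mode = "lenient")
  expect_setequal(keys1, keys3)
  sizes <- lengths(group_degenerate(scan$variants))
  singletons <- names(sizes)[sizes == 1L]
  expect_identical(u1$id[keys1 %in% singletons], u3$id[keys3 %in% singletons])
})

test_that("degenerate test pairs lose exactly one member under seeded removal", {
  set.seed(17)
  seqs <- vapply(sample.int(1e6, 5), function(s) random_cds(15, s),
                 character(1))
  test <- cds_records(sprintf("q%d", 1:6),
                      c(seqs, permute_synonymous(seqs[3], seed = 2)))
  dd <- dedupe_test_degenerates(test, seed = 4)
  expect_identical(nrow(dd$kept), 5L)
  expect_length(dd$removed, 1L)
  expect_true(dd$removed %in% c("q3", "q6"))
  expect_identical(dedupe_test_degenerates(test, seed = 4)$removed, dd$removed)
})

test_that("single-codon mutation application is exact and validated", {
  m <- mutation_descriptor(2, "GCT", "GCC")
  out <- apply_codon_mutation("ATGGCT", m)
  expect_identical(out$sequence, "ATGGCC")
  expect_identical(out$mutation, "A2A")
  expect_error(
    apply_codon_mutation("ATGGCT", mutation_descriptor(2, "GCA", "GCC")),
    "reference-inconsistency")
  expect_error(
    apply_codon_mutation("ATGGCT", mutation_descriptor(3, "GCT", "GCC")),
    "out of range")
  # a full scan at one position gives 63 variants, one residue changed at most
  ref <- "ATGGCTTGG"
  code <- genetic_code()
  alts <- setdiff(names(code$table), "GCT")
  variants <- lapply(alts, function(a) {
    apply_codon_mutation(ref, mutation_descriptor(2, "GCT", a))
  })
  expect_length(variants, 63L)
  ref_prot <- translate_cds(ref)
  for (v in variants) {
    p <- translate_cds(v$sequence, mode = "lenient", drop_terminal_stop = FALSE)
    expect_identical(nchar(p), 3L)
    expect_lte(sum(strsplit(p, "")[[1]] != strsplit(ref_prot, "")[[1]][1:3]), 1L)
  }
})

test_that("fitness weighting and wildtype normalization follow the readout", {
  expect_equal(fitness_weighted_average(10, 10), 1)
  expect_equal(fitness_weighted_average(c(5, 5), c(1, 100)), 1)
  expect_equal(fitness_weighted_average(c(0, 10), c(1, 100)), 2)
  expect_error(fitness_weighted_average(c(0, 0), c(1, 100)), "zero total")
  expect_error(fitness_weighted_average(c(1, 1), c(0, 100)), "positive")
  expect_equal(normalize_fitness(2, 2), 1)
  w <- normalize_fitness(3, 2)
  expect_equal(w, 1.5)
  expect_true(w > 1)  # more fit than wildtype
  expect_equal(normalize_fitness(0, 2), 0)
  expect_error(normalize_fitness(1, 0), "nonzero")
  # w > 1 iff f > f_WT (property)
  set.seed(23)
  f <- runif(50, 0, 4)
  expect_identical(normalize_fitness(f, 2) > 1, f > 2)
})
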