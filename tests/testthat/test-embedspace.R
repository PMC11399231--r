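test_that("mean pooling is the row mean and permutation-symmetric", {
  expect_equal(mean_pool(matrix(c(1, 2), 1)), c(1, 2))
  expect_equal(mean_pool(rbind(c(0, 0), c(2, 2))), c(1, 1))
  m <- matrix(rnorm(30), 10, 3)
  expect_equal(mean_pool(m), mean_pool(m[sample(10), ]))
  expect_error(mean_pool(matrix(numeric(0), 0, 2)), "empty")
})

test_that("knn matches simple geometry and breaks ties by row index", {
  E <- embedding_set(c("a", "b", "c"), matrix(c(0, 1, 10), ncol = 1))
  rep <- knn(E, 1)
  expect_equal(rep$neighbor_indices[, 1], c(2L, 1L, 2L))
  # duplicated points: tie broken to the lower index
  E2 <- embedding_set(c("a", "b", "c", "d"),
                      matrix(c(0, 0, 0, 5), ncol = 1))
  rep2 <- knn(E2, 2)
  expect_equal(rep2$neighbor_indices[4, ], c(1L, 2L))
  expect_equal(rep2$neighbor_indices[3, ], c(1L, 2L))
  expect_error(knn(E, 3), "k must satisfy")
  zero <- embedding_set(c("a", "b"), rbind(c(0, 0), c(1, 1)))
  expect_error(knn(zero, 1, metric = "cosine"), "zero-norm")
})

test_that("knn equals the exhaustive all-pairs oracle on random instances", {
  set.seed(77)
  for (i in 1:8) {
    n <- sample(10:60, 1)
    d <- sample(1:8, 1)
    k <- sample.int(n - 1, 1)
    mat <- matrix(rnorm(n * d), n, d)
    if (i %% 2 == 0) mat[2, ] <- mat[1, ]  # planted duplicate rows
    E <- embedding_set(sprintf("r%03d", seq_len(n)), mat)
    for (metric in c("euclidean", "cosine")) {
      expect_identical(knn(E, k, metric)$neighbor_indices,
                       knn_oracle(mat, k, metric))
    }
  }
})

test_that("neighborhood statistics are invariant to rotation and translation", {
  scan <- gen_mutation_scan(8, seed = 21)
  E <- gen_structured_embeddings(scan$variants, "amino_acid", d = 6, seed = 22)
  rep <- knn(E, 10)
  base_acc <- aa_accuracy(E, rep)$mean
  base_med <- position_distance_stats(E, rep)$global_median
  set.seed(23)
  q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))  # random orthogonal matrix
  shift <- matrix(rnorm(6), nrow(E$matrix), 6, byrow = TRUE)
  E2 <- embedding_set(E$ids, E$matrix %*% q + shift, E$metadata)
  rep2 <- knn(E2, 10)
  expect_equal(aa_accuracy(E2, rep2)$mean, base_acc)
  expect_equal(position_distance_stats(E2, rep2)$global_median, base_med)
})

test_that("position distances and aa accuracy follow their definitions", {
  meta <- data.frame(mutated_position = c(1L, 2L, 100L),
                     mutant_aa = c("A", "V", "L"))
  E <- embedding_set(c("a", "b", "c"), matrix(c(0, 1, 2), ncol = 1), meta)
  rep <- knn(E, 1)
  s <- position_distance_stats(E, rep)
  expect_equal(sort(as.vector(s$distances)), c(1, 1, 98))
  # same position everywhere -> all zero
  meta0 <- data.frame(mutated_position = rep(7L, 3), mutant_aa = c("A", "A", "A"))
  E0 <- embedding_set(c("a", "b", "c"), matrix(c(0, 1, 2), ncol = 1), meta0)
  s0 <- position_distance_stats(E0, knn(E0, 2))
  expect_equal(s0$global_median, 0)
  expect_equal(aa_accuracy(E0, knn(E0, 2))$mean, 1)
  # all-distinct labels -> zero accuracy
  expect_equal(aa_accuracy(E, rep)$mean, 0)
})

test_that("random baseline matches enumeration and the permutation oracle", {
  expect_equal(random_baseline_accuracy(c("A", "A", "B", "B")), 1/3)
  expect_equal(random_baseline_accuracy(c("A", "A", "B", "B")),
               baseline_enumeration_oracle(c("A", "A", "B", "B")))
  expect_equal(random_baseline_accuracy(rep("Z", 9)), 1)
  set.seed(111)
  for (i in 1:5) {
    labels <- sample(LETTERS[1:4], 30, replace = TRUE)
    expect_equal(random_baseline_accuracy(labels),
                 baseline_enumeration_oracle(labels))
    # permutation oracle over a fixed random geometry
    mat <- matrix(rnorm(30 * 4), 30, 4)
    nbr <- knn(embedding_set(sprintf("x%d", 1:30), mat), 5)$neighbor_indices
    draws <- baseline_permutation_oracle(labels, nbr, B = 2000, seed = i)
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - random_baseline_accuracy(labels)), 3 * se)
  }
})

test_that("joint concatenation aligns by id and detects metadata conflicts", {
  ids <- c("a", "b", "c")
  e1 <- embedding_set(ids, matrix(rnorm(12), 3, 4),
                      data.frame(species = c("x", "y", "z")))
  e2 <- embedding_set(rev(ids), matrix(1:18, 3, 6),
                      data.frame(label = c(3, 2, 1)))
  out <- joint_concat(e1, e2)
  expect_identical(dim(out$matrix), c(3L, 10L))
  expect_identical(out$ids, ids)
  expect_equal(out$metadata$label, c(1, 2, 3))  # realigned by id
  # same rows in order gives the same result
  e2o <- embedding_set(ids, e2$matrix[match(ids, e2$ids), ],
                       data.frame(label = c(1, 2, 3)))
  expect_equal(joint_concat(e1, e2o), out)
  e3 <- embedding_set(ids, matrix(0, 3, 2),
                      data.frame(species = c("x", "WRONG", "z")))
  expect_error(joint_concat(e1, e3), "metadata conflict.*'b'")
  e4 <- embedding_set(c("a", "b", "d"), matrix(0, 3, 2))
  expect_error(joint_concat(e1, e4), "id mismatch")
})

test_that("linear head: exact fit, null fit, and rank-invariant Spearman", {
  set.seed(303)
  n <- 400; d <- 8
  x <- matrix(rnorm(n * d), n, d)
  beta <- rnorm(d)
  ids <- sprintf("s%03d", 1:n)
  # labels exactly linear -> training R^2 = 1
  E <- embedding_set(ids, x, data.frame(label = drop(x %*% beta) + 2))
  head <- fit_linear_head(E, ridge = 0)
  sc <- score_predictions(predict(head, E), E$metadata$label)
  expect_equal(sc$r_squared, 1)
  expect_equal(sc$spearman, 1)
  # Spearman is invariant to monotone transforms of a perfect prediction
  sc2 <- score_predictions(predict(head, E), exp(E$metadata$label / 10))
  expect_equal(sc2$spearman, 1)
  # labels independent of embeddings -> out-of-sample R^2 near 0
  E_tr <- embedding_set(ids, x, data.frame(label = rnorm(n)))
  E_te <- embedding_set(sprintf("t%04d", 1:2000),
                        matrix(rnorm(2000 * d), 2000, d),
                        data.frame(label = rnorm(2000)))
  head0 <- fit_linear_head(E_tr, ridge = 0)
  sc0 <- score_predictions(predict(head0, E_te), E_te$metadata$label)
  expect_lt(abs(sc0$r_squared), 0.05)
  # singular system without ridge errors; with ridge it fits
  xs <- cbind(x[, 1], x[, 1])
  Es <- embedding_set(ids, xs, data.frame(label = x[, 1]))
  expect_error(fit_linear_head(Es, ridge = 0), "singular")
  expect_s3_class(fit_linear_head(Es, ridge = 1e-6), "linear_head")
})

test_that("k-sweep reports stable statistics across neighborhood sizes", {
  scan <- gen_mutation_scan(8, seed = 41)
  E <- gen_structured_embeddings(scan$variants, "position",
                                 cluster_scale = 10, noise_sd = 1, seed = 42)
  sw <- knn_sweep(E, ks = c(5, 10, 20))
  expect_identical(sw$k, c(5, 10, 20))
  expect_true(all(sw$median_position_distance == 0))
})
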