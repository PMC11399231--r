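# Independent oracles and fixture builders, deliberately naive so they do not
# share code paths with the implementation under test.

# random frame-valid CDS over sense codons (first codon ATG), scalar loop
random_cds <- function(n_codons, seed) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  set.seed(seed)
  paste(c("ATG", sample(sense, n_codons - 1L, replace = TRUE)), collapse = "")
}

random_cds_set <- function(n, n_codons, seed) {
  set.seed(seed)
  seeds <- sample.int(1e6, n)
  cds_records(id = sprintf("s%04d", seq_len(n)),
              sequence = vapply(seeds, function(s) random_cds(n_codons, s),
                                character(1L)))
}

# exhaustive all-pairs-distance k-NN, scalar arithmetic, explicit tie-break
knn_oracle <- function(mat, k, metric = "euclidean") {
  n <- nrow(mat)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) {
      if (metric == "euclidean") {
        d[j] <- sqrt(sum((mat[i, ] - mat[j, ])^2))
      } else {
        d[j] <- 1 - sum(mat[i, ] * mat[j, ]) /
          (sqrt(sum(mat[i, ]^2)) * sqrt(sum(mat[j, ]^2)))
      }
    }
    d[i] <- Inf
    ord <- order(d, seq_len(n))
    out[i, ] <- ord[seq_len(k)]
  }
  out
}

# exact expectation of neighborhood label accuracy by full enumeration of
# single-neighbor draws (expectation is linear in the k draws)
baseline_enumeration_oracle <- function(labels) {
  n <- length(labels)
  acc <- 0
  for (q in seq_len(n)) {
    others <- labels[-q]
    acc <- acc + mean(others == labels[q])
  }
  acc / n
}

# Monte-Carlo baseline via label permutation over a fixed neighbor graph
baseline_permutation_oracle <- function(labels, nbr, B, seed) {
  set.seed(seed)
  n <- length(labels)
  vapply(seq_len(B), function(b) {
    lab <- sample(labels)
    mean(matrix(lab[nbr], nrow = n) == lab)
  }, numeric(1L))
}
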