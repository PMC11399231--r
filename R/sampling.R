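#' Permute synonymous codons within a sequence
#'
#' Translation-preserving shuffle: for each amino acid, the multiset of
#' codons observed at its positions in this one sequence is kept exactly,
#' but their order across those positions is a uniform random permutation.
#' Per-sequence codon counts — and hence GC content and the sequence's
#' codon-usage fingerprint — are conserved; only local codon-position
#' relationships are destroyed.
#'
#' @param seq A single frame-valid DNA string.
#' @param seed Integer seed.
#' @param code A [genetic_code()].
#' @param freeze_terminal_stop Keep a terminal stop codon fixed in place
#'   (default `TRUE`); internal stops, if any, are shuffled among
#'   themselves either way.
#' @return The permuted DNA string.
#' @export
permute_synonymous <- function(seq, seed, code = genetic_code(),
                               freeze_terminal_stop = TRUE) {
  codons <- split_codons(seq)
  aa <- unname(code$table[codons])
  if (anyNA(aa)) {
    stop("alphabet error: non-ACGT codon in sequence", call. = FALSE)
  }
  n <- length(codons)
  movable <- rep(TRUE, n)
  if (freeze_terminal_stop && aa[n] == "*") movable[n] <- FALSE
  with_seed(seed, {
    for (sym in unique(aa[movable])) {
      idx <- which(aa == sym & movable)
      if (length(idx) > 1L) codons[idx] <- codons[idx[sample.int(length(idx))]]
    }
  })
  paste(codons, collapse = "")
}

#' Resample codons uniformly over their synonym sets
#'
#' Translation-preserving randomization: each codon is independently
#' replaced by a uniform draw from the synonym set of the amino acid it
#' encodes. Unlike [permute_synonymous()], this discards the sequence's
#' codon-usage information entirely — the output's synonymous-codon
#' frequencies converge to the uniform distribution.
#'
#' @inheritParams permute_synonymous
#' @param freeze_terminal_stop Keep a terminal stop codon fixed (default
#'   `FALSE`; a resampled stop is still a stop, so terminality is
#'   preserved either way).
#' @return The resampled DNA string.
#' @export
sample_uniform <- function(seq, seed, code = genetic_code(),
                           freeze_terminal_stop = FALSE) {
  codons <- split_codons(seq)
  aa <- unname(code$table[codons])
  if (anyNA(aa)) {
    stop("alphabet error: non-ACGT codon in sequence", call. = FALSE)
  }
  n <- length(codons)
  movable <- rep(TRUE, n)
  if (freeze_terminal_stop && aa[n] == "*") movable[n] <- FALSE
  with_seed(seed, {
    for (i in which(movable)) {
      syn <- code$synonym_sets[[aa[i]]]
      codons[i] <- syn[sample.int(length(syn), 1L)]
    }
  })
  paste(codons, collapse = "")
}

#' Apply a codon sampling strategy to a dataset
#'
#' The three strategies compared throughout the package: `true_cds`
#' (identity — the curated coding sequences as retrieved), `permutation`
#' (within-sequence synonymous shuffle, [permute_synonymous()]), and
#' `uniform` (independent uniform resampling, [sample_uniform()]). The
#' randomized strategies derive one stream per record by stable hashing
#' of the record id combined with the master seed, so results do not
#' depend on dataset order.
#'
#' @param cds A `cds_records` table.
#' @param strategy One of `"true_cds"`, `"permutation"`, `"uniform"`.
#' @param seed Master integer seed (ignored for `true_cds`).
#' @param code A [genetic_code()].
#' @param ... Passed on to the per-sequence transform.
#' @return A `cds_records` table with transformed sequences; ids and all
#'   metadata untouched.
#' @export
apply_strategy <- function(cds, strategy = c("true_cds", "permutation", "uniform"),
                           seed = 0L, code = genetic_code(), ...) {
  strategy <- match.arg(strategy)
  if (strategy == "true_cds") return(cds)
  fn <- switch(strategy, permutation = permute_synonymous,
               uniform = sample_uniform)
  out <- cds
  out$sequence <- vapply(seq_len(nrow(cds)), function(i) {
    fn(cds$sequence[i], seed = derive_seed(seed, cds$id[i]), code = code, ...)
  }, character(1L))
  out
}
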