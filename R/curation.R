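#' Filter CDS whose translation does not match their protein
#'
#' Curation rule for paired CDS/protein datasets: a CDS is kept only if
#' its strict translation equals the protein sequence (terminal stop
#' ignored). Frame and alphabet failures are recorded as rejections, not
#' errors, so a whole retrieval batch can be screened in one pass.
#'
#' @param cds A `cds_records` table (may be built with `validate = FALSE`
#'   to let malformed retrievals reach the filter).
#' @param proteins Data frame with columns `id` and `sequence` (amino
#'   acids), matched to `cds` by `id`.
#' @param code A [genetic_code()].
#' @return A list with `kept` (the surviving `cds_records`) and `log`
#'   (data frame of rejected ids with `reason` and `mismatch_position`).
#' @export
filter_translation_mismatch <- function(cds, proteins, code = genetic_code()) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  prot_seq <- stats::setNames(proteins$sequence, proteins$id)
  keep <- logical(nrow(cds))
  reasons <- character(nrow(cds))
  positions <- rep(NA_integer_, nrow(cds))
  for (i in seq_len(nrow(cds))) {
    pid <- cds$id[i]
    if (!pid %in% names(prot_seq)) {
      reasons[i] <- "no protein record"
      next
    }
    v <- validate_pair(cds$sequence[i], prot_seq[[pid]], code = code)
    keep[i] <- v$match
    reasons[i] <- v$reason
    positions[i] <- v$mismatch_position
  }
  log <- data.frame(
    id = cds$id[!keep],
    reason = reasons[!keep],
    mismatch_position = positions[!keep],
    stringsAsFactors = FALSE
  )
  kept <- cds[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, log = log)
}

# Degeneracy key: strict translation, terminal stop ignored, uppercase.
degeneracy_key <- function(seqs, code = genetic_code()) {
  translate_cds(seqs, code = code, mode = "lenient", drop_terminal_stop = TRUE)
}

#' Group coding sequences by translated protein
#'
#' Two CDS are degenerate when they translate to the identical protein;
#' this partitions a dataset into its degeneracy groups (the grouping
#' that label-averaging over synonymous variants presupposes).
#'
#' @param cds A `cds_records` table or character vector of DNA strings.
#' @param code A [genetic_code()].
#' @return A named list of integer row indices, keyed by the shared
#'   translated protein.
#' @export
group_degenerate <- function(cds, code = genetic_code()) {
  seqs <- if (is.data.frame(cds)) cds$sequence else cds
  keys <- degeneracy_key(seqs, code = code)
  split(seq_along(seqs), keys)
}

#' Build the Complete training set
#'
#' Removes from the training set every CDS that is degenerate with (i.e.
#' translates to the same protein as) any CDS in the test set, so that no
#' protein appears on both sides of the split while all remaining
#' synonymous variants are retained for training.
#'
#' @param train,test `cds_records` tables.
#' @param code A [genetic_code()].
#' @return The filtered training `cds_records`; the test set is never
#'   modified.
#' @export
build_complete_set <- function(train, test, code = genetic_code()) {
  test_proteins <- unique(degeneracy_key(test$sequence, code = code))
  keep <- !(degeneracy_key(train$sequence, code = code) %in% test_proteins)
  out <- train[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the Unique training set
#'
#' A random, maximal, nondegenerate subset: exactly one CDS per
#' degeneracy group, chosen uniformly at random under the given seed.
#' Retained records keep their raw labels (no averaging over the
#' synonymous variants that were dropped).
#'
#' @param cds A `cds_records` table.
#' @param seed Integer seed; the same seed always yields the same subset.
#' @param code A [genetic_code()].
#' @return A `cds_records` subset with pairwise-distinct translations,
#'   in the original row order.
#' @export
build_unique_set <- function(cds, seed, code = genetic_code()) {
  groups <- group_degenerate(cds, code = code)
  groups <- groups[order(names(groups))]  # stable iteration order
  chosen <- with_seed(seed, vapply(groups, function(idx) {
    if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
  }, integer(1L)))
  out <- cds[sort(unname(chosen)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop degenerate pairs from a test set
#'
#' Test-set rule for mostly-nondegenerate datasets: within every test-set
#' degeneracy group of size greater than one, keep a single member chosen
#' uniformly at random (seeded) and remove the rest.
#'
#' @inheritParams build_unique_set
#' @return A list with `kept` (the deduplicated `cds_records`) and
#'   `removed` (ids that were dropped).
#' @export
dedupe_test_degenerates <- function(cds, seed, code = genetic_code()) {
  kept <- build_unique_set(cds, seed = seed, code = code)
  list(kept = kept, removed = setdiff(cds$id, kept$id))
}

#' Apply a single-codon substitution to a reference CDS
#'
#' @param reference A single DNA string or a one-row `cds_records`.
#' @param m A [mutation_descriptor()].
#' @return A `cds_records` row: the mutated sequence with the descriptor
#'   string attached, differing from the reference at exactly one codon.
#' @export
apply_codon_mutation <- function(reference, m) {
  ref_seq <- if (is.data.frame(reference)) reference$sequence[1L] else reference
  ref_id <- if (is.data.frame(reference)) reference$id[1L] else "ref"
  codons <- split_codons(ref_seq)
  if (m$position > length(codons)) {
    stop("position ", m$position, " out of range (", length(codons),
         " codons)", call. = FALSE)
  }
  if (codons[m$position] != m$ref_codon) {
    stop("reference-inconsistency error: codon at position ", m$position,
         " is ", codons[m$position], ", not ", m$ref_codon, call. = FALSE)
  }
  codons[m$position] <- m$alt_codon
  cds_records(
    id = paste0(ref_id, "_", format(m), "_", m$alt_codon),
    sequence = paste(codons, collapse = ""),
    mutation = format(m)
  )
}

#' Fitness from allele counts across a concentration gradient
#'
#' Unnormalized fitness of an allele read out of a selection experiment
#' in which the mutant library is split over sub-libraries exposed to
#' increasing antibiotic concentrations: the count-weighted average of
#' the log concentration at which the allele's reads survive. Alleles
#' whose reads concentrate on high-concentration plates score high.
#'
#' @param counts Nonnegative allele counts, one per sub-library.
#' @param concentrations Strictly positive concentrations (same length).
#' @param log_base Base of the logarithm (default 10).
#' @return The unnormalized fitness, a count-weighted mean of
#'   `log(concentrations, log_base)`.
#' @examples
#' fitness_weighted_average(c(5, 5), c(1, 100))  # 1.0
#' @export
fitness_weighted_average <- function(counts, concentrations, log_base = 10) {
  if (length(counts) != length(concentrations)) {
    stop("counts and concentrations must have equal length", call. = FALSE)
  }
  if (any(concentrations <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("undefined fitness: zero total count", call. = FALSE)
  sum(counts * log(concentrations, base = log_base)) / total
}

#' Normalize fitness by wildtype
#'
#' `w = f / f_WT`, so that `w > 1` marks an allele more fit than
#' wildtype and `w < 1` one less fit.
#'
#' @param f Unnormalized fitness (vectorized).
#' @param f_wt Wildtype fitness; must be nonzero.
#' @return Normalized fitness `w`.
#' @export
normalize_fitness <- function(f, f_wt) {
  if (length(f_wt) != 1L || f_wt == 0) {
    stop("wildtype fitness must be a single nonzero value", call. = FALSE)
  }
  f / f_wt
}
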