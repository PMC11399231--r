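#' The standard genetic code
#'
#' Builds the code object used throughout the package: the 64-entry
#' codon-to-amino-acid table and the synonym sets it induces (one set of
#' codons per amino-acid symbol, with `"*"` for the three stop codons).
#' The table is taken from [Biostrings::GENETIC_CODE]; an alternative
#' 64-entry named character vector can be injected for non-standard codes.
#'
#' @param table Named character vector of length 64 mapping codons
#'   (3-letter strings over A/C/G/T) to single-letter amino-acid symbols.
#'   Defaults to the standard nuclear code.
#' @return An object of class `genetic_code` with elements `table` and
#'   `synonym_sets`.
#' @examples
#' code <- genetic_code()
#' code$synonym_sets[["L"]]  # the six leucine codons
#' @export
genetic_code <- function(table = Biostrings::GENETIC_CODE) {
  table <- toupper(unlist(as.list(table)))
  if (length(table) != 64L || anyDuplicated(names(table)) ||
      !all(nchar(names(table)) == 3L)) {
    stop("genetic code table must map exactly the 64 codons", call. = FALSE)
  }
  structure(
    list(
      table = table,
      synonym_sets = split(names(table), unname(table))
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  n_stop <- length(x$synonym_sets[["*"]])
  cat("<genetic_code> 64 codons,",
      length(x$synonym_sets) - (n_stop > 0), "amino acids,",
      n_stop, "stop codons\n")
  invisible(x)
}

# uppercase, RNA U -> DNA T; tolerant of FASTA dialects
normalize_dna <- function(seq) {
  chartr("u", "T", chartr("U", "T", toupper(seq)))
}

#' Split a coding sequence into codons
#'
#' @param seq A single DNA string whose length is divisible by 3.
#' @return Character vector of 3-letter codons.
#' @export
split_codons <- function(seq) {
  seq <- normalize_dna(seq)
  n <- nchar(seq)
  if (n == 0L || n %% 3L != 0L) {
    stop("frame error: sequence length ", n, " is not a positive multiple of 3",
         call. = FALSE)
  }
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a coding sequence
#'
#' Codon-by-codon translation under an injectable genetic code, with the
#' strictness semantics used for dataset curation: `strict` mode refuses
#' non-ACGT characters and internal stop codons (a curated CDS must be a
#' clean open reading frame), while `lenient` mode renders any codon
#' containing a non-ACGT character as `"X"` and leaves internal stops as
#' `"*"`. A terminal stop codon is dropped by default so translations can
#' be compared against protein-database sequences, which omit it.
#'
#' @param seq Character vector of DNA strings (each frame-valid).
#' @param code A [genetic_code()].
#' @param mode `"strict"` (default, curation semantics) or `"lenient"`.
#' @param drop_terminal_stop Drop a trailing `"*"` from the translation
#'   (default `TRUE`).
#' @return Character vector of amino-acid strings, one symbol per codon.
#' @examples
#' translate_cds("ATGGCT")            # "MA"
#' translate_cds("ATGTAA")            # "M"  (terminal stop dropped)
#' translate_cds("ATGNNN", mode = "lenient")  # "MX"
#' @export
translate_cds <- function(seq, code = genetic_code(),
                          mode = c("strict", "lenient"),
                          drop_terminal_stop = TRUE) {
  mode <- match.arg(mode)
  vapply(seq, function(s) {
    codons <- split_codons(s)
    aa <- unname(code$table[codons])
    if (anyNA(aa)) {
      if (mode == "strict") {
        bad <- codons[which(is.na(aa))[1L]]
        stop("alphabet error: codon '", bad, "' contains non-ACGT characters",
             call. = FALSE)
      }
      aa[is.na(aa)] <- "X"
    }
    n <- length(aa)
    stops <- which(aa == "*")
    if (mode == "strict" && any(stops < n)) {
      stop("premature-stop error: internal stop codon at codon ",
           stops[stops < n][1L], call. = FALSE)
    }
    if (drop_terminal_stop && n > 0L && aa[n] == "*") aa <- aa[-n]
    paste(aa, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Validate a CDS / protein pair
#'
#' Checks that a coding sequence translates exactly to a given protein
#' sequence (terminal stop ignored, case-insensitive). Curation pipelines
#' drop any CDS whose translation does not match its protein record.
#'
#' @param cds_seq A single DNA string.
#' @param protein_seq A single amino-acid string.
#' @param code A [genetic_code()].
#' @return A list with `match` (logical), `mismatch_position` (1-based
#'   residue index of the first disagreement, or `NA`), and `reason`
#'   (`"ok"`, `"mismatch"`, `"length"`, or the caught translation error).
#' @export
validate_pair <- function(cds_seq, protein_seq, code = genetic_code()) {
  if (!nzchar(cds_seq) || !nzchar(protein_seq)) {
    stop("both sequences must be nonempty", call. = FALSE)
  }
  trans <- tryCatch(
    translate_cds(cds_seq, code = code, mode = "strict"),
    error = function(e) e
  )
  if (inherits(trans, "error")) {
    return(list(match = FALSE, mismatch_position = NA_integer_,
                reason = conditionMessage(trans)))
  }
  prot <- sub("\\*$", "", toupper(protein_seq))
  if (identical(trans, prot)) {
    return(list(match = TRUE, mismatch_position = NA_integer_, reason = "ok"))
  }
  a <- strsplit(trans, "")[[1L]]
  b <- strsplit(prot, "")[[1L]]
  m <- min(length(a), length(b))
  diff <- which(a[seq_len(m)] != b[seq_len(m)])
  pos <- if (length(diff)) diff[1L] else m + 1L
  reason <- if (length(a) != length(b) && !length(diff)) "length" else "mismatch"
  list(match = FALSE, mismatch_position = as.integer(pos), reason = reason)
}

#' GC content of nucleotide sequences
#'
#' Fraction of G or C bases, case-insensitive. Characters outside
#' A/C/G/T (ambiguity codes, gaps) are excluded from both numerator and
#' denominator.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Numeric vector of values in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  vapply(seq, function(s) {
    if (!nzchar(s)) stop("gc_content: empty sequence", call. = FALSE)
    chars <- strsplit(normalize_dna(s), "")[[1L]]
    acgt <- chars[chars %in% c("A", "C", "G", "T")]
    if (!length(acgt)) stop("gc_content: no ACGT characters", call. = FALSE)
    sum(acgt %in% c("G", "C")) / length(acgt)
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Codon usage profile of a set of coding sequences
#'
#' Aggregates codon counts over all sequences and derives overall
#' frequencies plus per-amino-acid conditional frequencies (the relative
#' use of each synonymous codon given the encoded amino acid).
#'
#' @param seqs Character vector of frame-valid DNA strings, or a
#'   `cds_records` table (its `sequence` column is used).
#' @param code A [genetic_code()].
#' @return An object of class `codon_usage_profile` with `counts` and
#'   `frequencies` (named 64-vectors in code-table order) and
#'   `per_aa_frequencies` (list keyed by amino-acid symbol; each element
#'   sums to 1 for amino acids present).
#' @export
codon_usage <- function(seqs, code = genetic_code()) {
  if (is.data.frame(seqs)) seqs <- seqs$sequence
  codons <- unlist(lapply(seqs, split_codons), use.names = FALSE)
  bad <- setdiff(unique(codons), names(code$table))
  if (length(bad)) {
    stop("alphabet error: codon '", bad[1L], "' not in the code table",
         call. = FALSE)
  }
  counts <- table(factor(codons, levels = names(code$table)))
  counts <- stats::setNames(as.integer(counts), names(code$table))
  total <- sum(counts)
  freqs <- if (total > 0) counts / total else counts * 0
  per_aa <- lapply(code$synonym_sets, function(syn) {
    sub <- counts[syn]
    s <- sum(sub)
    if (s > 0) sub / s else stats::setNames(rep(NA_real_, length(syn)), syn)
  })
  structure(
    list(counts = counts, frequencies = freqs, per_aa_frequencies = per_aa,
         code = code),
    class = "codon_usage_profile"
  )
}

#' @export
print.codon_usage_profile <- function(x, ...) {
  cat("<codon_usage_profile>", sum(x$counts), "codons,",
      sum(x$counts > 0), "of 64 observed\n")
  invisible(x)
}

#' Export a codon usage profile as a table
#'
#' @param x A `codon_usage_profile`.
#' @param ... Unused.
#' @return A data frame with columns `codon`, `amino_acid`, `count`,
#'   `frequency`.
#' @export
as.data.frame.codon_usage_profile <- function(x, ...) {
  data.frame(
    codon = names(x$counts),
    amino_acid = unname(x$code$table[names(x$counts)]),
    count = unname(x$counts),
    frequency = unname(x$frequencies),
    stringsAsFactors = FALSE
  )
}

#' Map k-mer tokens to the residues they cover
#'
#' Nucleotide models tokenized on k-mers with k a multiple of 3 assign
#' each token to k/3 amino-acid residues (a 6-mer token covers two
#' residues, so residue-level predictions are read off two per token; a
#' 3-mer token maps to exactly one residue). Tokens and residues are
#' 1-based.
#'
#' @param k Token width in nucleotides; a positive multiple of 3.
#' @param n_tokens Number of tokens.
#' @return A list of length `n_tokens`; element `t` is the integer vector
#'   of residue indices covered by token `t`.
#' @examples
#' kmer_token_residue_map(6, 3)  # token 1 -> residues 1:2, ...
#' @export
kmer_token_residue_map <- function(k, n_tokens) {
  if (length(k) != 1L || k < 3L || k %% 3L != 0L) {
    stop("k must be a positive multiple of 3", call. = FALSE)
  }
  if (n_tokens < 1L) stop("n_tokens must be >= 1", call. = FALSE)
  r <- k %/% 3L
  lapply(seq_len(n_tokens), function(t) ((t - 1L) * r + 1L):(t * r))
}
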