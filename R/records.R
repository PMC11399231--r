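#' Construct a table of CDS records
#'
#' The package's working container for coding sequences is a plain data
#' frame with class `cds_records`: one row per CDS with its identifier,
#' sequence, and optional species, task label, and mutation descriptor
#' string. All downstream operations (curation, sampling, features)
#' accept and return this table so metadata rides along with sequences.
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of DNA strings (uppercased, U mapped
#'   to T on ingestion).
#' @param species Optional character vector.
#' @param label Optional numeric task label (units are task-dependent:
#'   melting point in degrees C, normalized fitness, log10 stability).
#' @param mutation Optional protein-level mutation string such as
#'   `"S26C"`.
#' @param validate Check frame and strict ACGT alphabet (default `TRUE`).
#' @return A `cds_records` data frame.
#' @export
cds_records <- function(id, sequence, species = NA_character_,
                        label = NA_real_, mutation = NA_character_,
                        validate = TRUE) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate id: '", id[duplicated(id)][1L], "'", call. = FALSE)
  }
  sequence <- vapply(sequence, normalize_dna, character(1L), USE.NAMES = FALSE)
  if (validate) {
    n <- nchar(sequence)
    if (any(n == 0L | n %% 3L != 0L)) {
      stop("frame error: sequence length must be a positive multiple of 3 (id '",
           id[which(n == 0L | n %% 3L != 0L)[1L]], "')", call. = FALSE)
    }
    bad <- grepl("[^ACGT]", sequence)
    if (any(bad)) {
      stop("alphabet error: non-ACGT characters (id '", id[bad][1L], "')",
           call. = FALSE)
    }
  }
  out <- data.frame(
    id = id, sequence = sequence,
    species = rep_len(as.character(species), length(id)),
    label = rep_len(as.numeric(label), length(id)),
    mutation = rep_len(as.character(mutation), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cds_records", "data.frame")
  out
}

#' @export
print.cds_records <- function(x, ...) {
  cat("<cds_records>", nrow(x), "sequences")
  sp <- unique(x$species[!is.na(x$species)])
  if (length(sp)) cat(",", length(sp), "species")
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Describe a single-codon substitution
#'
#' A mutation descriptor records one codon substitution against a
#' reference CDS: the 1-based codon position, the reference and
#' alternative codons, and the derived amino acids. Its protein-level
#' display form is `"<refAA><pos><altAA>"` (e.g. `"S26C"`); synonymous
#' substitutions display with equal flanking symbols (e.g. `"A4A"`).
#'
#' @param position 1-based codon index.
#' @param ref_codon,alt_codon Reference and alternative codons; must
#'   differ.
#' @param code A [genetic_code()].
#' @return An object of class `mutation_descriptor`.
#' @export
mutation_descriptor <- function(position, ref_codon, alt_codon,
                                code = genetic_code()) {
  ref_codon <- normalize_dna(ref_codon)
  alt_codon <- normalize_dna(alt_codon)
  if (identical(ref_codon, alt_codon)) {
    stop("ref_codon and alt_codon must differ", call. = FALSE)
  }
  for (cdn in c(ref_codon, alt_codon)) {
    if (!cdn %in% names(code$table)) {
      stop("'", cdn, "' is not a codon of the code table", call. = FALSE)
    }
  }
  if (position < 1L) stop("position must be >= 1", call. = FALSE)
  structure(
    list(position = as.integer(position),
         ref_codon = ref_codon, alt_codon = alt_codon,
         ref_aa = unname(code$table[ref_codon]),
         alt_aa = unname(code$table[alt_codon])),
    class = "mutation_descriptor"
  )
}

#' @export
format.mutation_descriptor <- function(x, ...) {
  paste0(x$ref_aa, x$position, x$alt_aa)
}

#' @export
print.mutation_descriptor <- function(x, ...) {
  cat("<mutation_descriptor>", format(x),
      paste0("(", x$ref_codon, "->", x$alt_codon, ")\n"))
  invisible(x)
}

# Deterministic per-record random streams: a stable 31-bit string hash
# combined with the master seed, so outputs do not depend on dataset order.
stable_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

derive_seed <- function(master_seed, id) {
  as.integer((as.numeric(master_seed) * 1000003 + stable_hash(id)) %% 2147483647)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
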