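#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] with the package's
#' ingestion rules: sequences uppercased (U mapped to T for DNA),
#' duplicate ids rejected, headers truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @param type `"dna"` (default) or `"protein"`.
#' @return A data frame with columns `id` and `sequence`.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate id in FASTA: '", ids[duplicated(ids)][1L], "'",
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (type == "dna") seqs <- vapply(seqs, normalize_dna, character(1L),
                                    USE.NAMES = FALSE)
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records A data frame with `id` and `sequence` columns (e.g. a
#'   `cds_records` table).
#' @param path Output path.
#' @param width Line-wrapping width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (anyDuplicated(records$id)) {
    stop("duplicate id: '", records$id[duplicated(records$id)][1L], "'",
         call. = FALSE)
  }
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Read a delimited metadata table
#'
#' Tab-separated by default; comma-separated input is detected from the
#' header line. An `id` column is mandatory; unknown columns are
#' preserved as-is.
#'
#' @param path Path to a TSV/CSV file with a header.
#' @param required Character vector of required column names (always
#'   includes `"id"`).
#' @return A data frame.
#' @export
read_table <- function(path, required = character()) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
  out <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  required <- union("id", required)
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out$id <- as.character(out$id)
  out
}

#' Write a delimited metadata table
#'
#' Tab-separated with header, no quoting of numerics, preserving column
#' order.
#'
#' @param x A data frame with an `id` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (!"id" %in% names(x)) stop("table must have an 'id' column", call. = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
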