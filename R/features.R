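#' Fit per-species codon-usage centroids
#'
#' Species leave identifiable codon-preference fingerprints in their
#' coding sequences. This fits a transparent nearest-centroid model of
#' that signal: the centroid of a species is the mean of its sequences'
#' per-sequence codon frequency vectors (64 entries summing to 1 each).
#'
#' @param train A `cds_records` table with a `species` column; every
#'   species needs at least one sequence.
#' @param code A [genetic_code()].
#' @return An object of class `species_centroids`: `centroids` (S x 64
#'   matrix, rows ordered by species name), `n` (sequences per species).
#' @export
fit_species_centroids <- function(train, code = genetic_code()) {
  if (any(is.na(train$species))) {
    stop("all training records need a species", call. = FALSE)
  }
  freq <- codon_frequency_matrix(train$sequence, code = code)
  species <- sort(unique(train$species))
  centroids <- t(vapply(species, function(sp) {
    colMeans(freq[train$species == sp, , drop = FALSE])
  }, numeric(64L)))
  structure(
    list(centroids = centroids,
         n = stats::setNames(as.integer(table(train$species)[species]), species)),
    class = "species_centroids"
  )
}

#' @export
print.species_centroids <- function(x, ...) {
  cat("<species_centroids>", nrow(x$centroids), "species, fitted on",
      sum(x$n), "sequences\n")
  invisible(x)
}

# N x 64 matrix of per-sequence codon frequencies, columns in code-table order.
codon_frequency_matrix <- function(seqs, code = genetic_code()) {
  t(vapply(seqs, function(s) {
    cdn <- split_codons(s)
    counts <- table(factor(cdn, levels = names(code$table)))
    as.numeric(counts) / length(cdn)
  }, numeric(64L), USE.NAMES = FALSE))
}

#' Classify sequences by nearest codon-usage centroid
#'
#' Assigns each sequence to the species whose centroid is nearest its
#' codon frequency vector in Euclidean distance; exact ties go to the
#' lexicographically first species name.
#'
#' @param cds A `cds_records` table or character vector of DNA strings.
#' @param centroids A fitted [fit_species_centroids()] object.
#' @param code A [genetic_code()].
#' @return A data frame with `id`, `species` (the call), and one distance
#'   column per candidate species.
#' @export
classify_species <- function(cds, centroids, code = genetic_code()) {
  seqs <- if (is.data.frame(cds)) cds$sequence else cds
  ids <- if (is.data.frame(cds)) cds$id else as.character(seq_along(seqs))
  freq <- codon_frequency_matrix(seqs, code = code)
  cent <- centroids$centroids
  # squared Euclidean distances via ||x||^2 + ||c||^2 - 2 x.c
  d2 <- outer(rowSums(freq^2), rowSums(cent^2), "+") - 2 * freq %*% t(cent)
  d2[d2 < 0] <- 0
  dist <- sqrt(d2)
  colnames(dist) <- rownames(cent)
  call <- rownames(cent)[apply(dist, 1L, which.min)]  # which.min = first tie
  out <- data.frame(id = ids, species = call, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(dist))
}

#' Feature blocks for embedding augmentation
#'
#' A feature block is a small named matrix aligned by id to an embedding
#' set, ready to be appended to it with [augment()].
#'
#' @param name Block name.
#' @param matrix Numeric N x f matrix.
#' @param ids Character vector of row ids (length N).
#' @return An object of class `feature_block`.
#' @export
feature_block <- function(name, matrix, ids) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != length(ids)) {
    stop("feature block rows must match ids", call. = FALSE)
  }
  rownames(matrix) <- ids
  structure(list(name = name, matrix = matrix, ids = as.character(ids)),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat("<feature_block>", x$name, ":", nrow(x$matrix), "x", ncol(x$matrix), "\n")
  invisible(x)
}

#' GC-content feature block
#'
#' One z-scored GC-content column per sequence. Normalization statistics
#' (mean and population standard deviation) are estimated on the training
#' split and must be reused, via `stats`, when building the block for any
#' other split — otherwise test information leaks into the feature scale.
#'
#' @param cds A `cds_records` table.
#' @param stats Optional list `(center, scale)` from a previous call
#'   (training-split statistics). When `NULL` they are estimated from
#'   `cds` itself.
#' @return A [feature_block()] with an attached `stats` attribute.
#' @export
gc_feature <- function(cds, stats = NULL) {
  gc <- gc_content(cds$sequence)
  if (is.null(stats)) {
    center <- mean(gc)
    scale <- sqrt(mean((gc - center)^2))  # population convention
    stats <- list(center = center, scale = scale)
  }
  z <- if (stats$scale > 0) (gc - stats$center) / stats$scale else gc * 0
  blk <- feature_block("gc_content", matrix(z, ncol = 1L,
                                            dimnames = list(NULL, "gc_z")),
                       cds$id)
  attr(blk, "stats") <- stats
  blk
}

#' One-hot species feature block
#'
#' One indicator column per species, with the category order fixed by the
#' training split. A species unseen at training time yields an all-zero
#' row and a warning rather than an error, so held-out data can still be
#' scored.
#'
#' @param cds A `cds_records` table with a `species` column.
#' @param levels Optional character vector fixing the column order
#'   (training-split categories). Defaults to the sorted species in
#'   `cds`.
#' @return A [feature_block()] with an attached `levels` attribute.
#' @export
one_hot_species <- function(cds, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(cds$species))
  m <- matrix(0, nrow = nrow(cds), ncol = length(levels),
              dimnames = list(NULL, paste0("species_", levels)))
  hit <- match(cds$species, levels)
  seen <- !is.na(hit)
  if (any(!seen)) {
    warning("unseen species at prediction time: ",
            paste(unique(cds$species[!seen]), collapse = ", "),
            " (all-zero rows emitted)", call. = FALSE)
  }
  m[cbind(which(seen), hit[seen])] <- 1
  blk <- feature_block("species_onehot", m, cds$id)
  attr(blk, "levels") <- levels
  blk
}

#' Append feature blocks to an embedding set
#'
#' Column-wise concatenation of one or more [feature_block()]s onto an
#' [embedding_set()], aligned by id. Row count, id order and metadata are
#' never changed; the embedding dimension grows by the sum of block
#' widths, in argument order.
#'
#' @param embeddings An [embedding_set()].
#' @param blocks A list of [feature_block()]s (empty list = identity).
#' @return The augmented [embedding_set()].
#' @export
augment <- function(embeddings, blocks) {
  if (!length(blocks)) return(embeddings)
  mat <- embeddings$matrix
  for (blk in blocks) {
    if (!inherits(blk, "feature_block")) {
      stop("blocks must be feature_block objects", call. = FALSE)
    }
    hit <- match(embeddings$ids, blk$ids)
    if (anyNA(hit)) {
      stop("misaligned ids: block '", blk$name, "' lacks id '",
           embeddings$ids[which(is.na(hit))[1L]], "'", call. = FALSE)
    }
    mat <- cbind(mat, blk$matrix[hit, , drop = FALSE])
  }
  rownames(mat) <- NULL
  embedding_set(embeddings$ids, mat, embeddings$metadata)
}
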