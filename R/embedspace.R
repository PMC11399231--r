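#' An embedding set: matrix plus aligned metadata
#'
#' Container for per-sequence embeddings: an N x d numeric matrix whose
#' rows are aligned, by position, to a metadata data frame (typical
#' columns: `mutated_position`, `mutant_aa`, `species`, `label`).
#'
#' @param ids Character vector of unique row ids.
#' @param matrix Numeric N x d matrix, d >= 1.
#' @param metadata Data frame with N rows (default: empty columns).
#' @return An object of class `embedding_set`.
#' @export
embedding_set <- function(ids, matrix,
                          metadata = data.frame(row.names = seq_along(ids))) {
  ids <- as.character(ids)
  matrix <- as.matrix(matrix)
  if (anyDuplicated(ids)) stop("duplicate embedding ids", call. = FALSE)
  if (nrow(matrix) != length(ids) || nrow(metadata) != length(ids)) {
    stop("ids, matrix rows and metadata rows must agree", call. = FALSE)
  }
  if (ncol(matrix) < 1L) stop("embedding dimension must be >= 1", call. = FALSE)
  rownames(metadata) <- NULL
  structure(list(ids = ids, matrix = matrix, metadata = metadata),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat("<embedding_set>", nrow(x$matrix), "x", ncol(x$matrix),
      "| metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Mean-pool token embeddings
#'
#' Collapses a T x d matrix of per-token embeddings to a single d-vector
#' by averaging over tokens — the pooling used before any sequence-level
#' comparison or prediction.
#'
#' @param token_embeddings Numeric T x d matrix, T >= 1.
#' @return Numeric d-vector.
#' @export
mean_pool <- function(token_embeddings) {
  m <- as.matrix(token_embeddings)
  if (nrow(m) < 1L) stop("mean_pool: empty input", call. = FALSE)
  colMeans(m)
}

#' k-nearest neighbors in embedding space
#'
#' For every row of the embedding set, finds the k other rows minimizing
#' the chosen metric (Euclidean distance by default; cosine distance
#' 1 - cos as an alternative). The query itself is always excluded, and
#' distance ties are broken by ascending row index so reports are fully
#' deterministic.
#'
#' @param embeddings An [embedding_set()].
#' @param k Neighborhood size, `1 <= k <= N - 1`.
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @return An object of class `neighborhood_report`: `k`, `metric`,
#'   `ids`, and `neighbor_indices` (N x k integer matrix of row indices,
#'   nearest first).
#' @export
knn <- function(embeddings, k, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  x <- embeddings$matrix
  n <- nrow(x)
  if (k < 1L || k > n - 1L) {
    stop("k must satisfy 1 <= k <= N - 1", call. = FALSE)
  }
  if (metric == "euclidean") {
    sq <- rowSums(x^2)
    d <- outer(sq, sq, "+") - 2 * tcrossprod(x)
    d[d < 0] <- 0
  } else {
    nrm <- sqrt(rowSums(x^2))
    if (any(nrm == 0)) {
      stop("cosine metric undefined for zero-norm rows", call. = FALSE)
    }
    d <- 1 - tcrossprod(x / nrm)
  }
  nbr <- matrix(0L, nrow = n, ncol = k)
  idx <- seq_len(n)
  for (i in idx) {
    di <- d[i, ]
    di[i] <- Inf
    # order() is stable on the second key, giving the ascending-index tie rule
    nbr[i, ] <- order(di, idx)[seq_len(k)]
  }
  structure(list(k = as.integer(k), metric = metric, ids = embeddings$ids,
                 neighbor_indices = nbr),
            class = "neighborhood_report")
}

#' @export
print.neighborhood_report <- function(x, ...) {
  cat("<neighborhood_report> N =", length(x$ids), ", k =", x$k,
      ", metric =", x$metric, "\n")
  invisible(x)
}

#' Mutated-position distances within neighborhoods
#'
#' For each query, the absolute differences between its mutated position
#' and those of its k neighbors. Reported both ways the headline median
#' can be read: pooled over all N x k query-neighbor pairs
#' (`global_median`) and as the median of per-query medians
#' (`median_of_query_medians`).
#'
#' @param embeddings The [embedding_set()] the report was computed from;
#'   its metadata must contain `mutated_position`.
#' @param report A [knn()] `neighborhood_report`.
#' @return A list: `distances` (N x k matrix), `per_query_median`,
#'   `global_median`, `median_of_query_medians`, `global_mean`.
#' @export
position_distance_stats <- function(embeddings, report) {
  pos <- embeddings$metadata$mutated_position
  if (is.null(pos) || anyNA(pos)) {
    stop("metadata must contain complete 'mutated_position'", call. = FALSE)
  }
  nbr_pos <- matrix(pos[report$neighbor_indices], nrow = length(pos))
  dmat <- abs(nbr_pos - pos)
  per_query <- apply(dmat, 1L, stats::median)
  list(distances = dmat,
       per_query_median = per_query,
       global_median = stats::median(dmat),
       median_of_query_medians = stats::median(per_query),
       global_mean = mean(dmat))
}

#' Mutant-amino-acid neighborhood accuracy
#'
#' For each query, the fraction of its k neighbors carrying the same
#' mutant amino acid, and the dataset mean of those fractions.
#'
#' @param embeddings The [embedding_set()]; metadata must contain
#'   `mutant_aa`.
#' @param report A [knn()] `neighborhood_report`.
#' @return A list: `per_query` (length-N fractions) and `mean`.
#' @export
aa_accuracy <- function(embeddings, report) {
  aa <- embeddings$metadata$mutant_aa
  if (is.null(aa) || anyNA(aa)) {
    stop("metadata must contain complete 'mutant_aa'", call. = FALSE)
  }
  nbr_aa <- matrix(aa[report$neighbor_indices], nrow = length(aa))
  per_query <- rowMeans(nbr_aa == aa)
  list(per_query = per_query, mean = mean(per_query))
}

#' Exact neighborhood accuracy under random arrangement
#'
#' The expected mutant-amino-acid accuracy when embeddings carry no label
#' information, i.e. when each query's k neighbors are k uniform draws
#' without replacement from the other N - 1 rows. For a query with label
#' a, each neighbor matches with probability (n_a - 1)/(N - 1), so the
#' expectation is the mean of that quantity over queries — independent
#' of k.
#'
#' @param labels Character vector of per-row labels.
#' @param k Neighborhood size (accepted for interface symmetry; the
#'   expectation does not depend on it).
#' @return The expected accuracy, a single number in `[0, 1]`.
#' @export
random_baseline_accuracy <- function(labels, k = NULL) {
  n <- length(labels)
  if (n < 2L) stop("need at least two rows", call. = FALSE)
  counts <- table(labels)
  mean((as.numeric(counts[labels]) - 1) / (n - 1))
}

#' Monte-Carlo interval for the random-arrangement baseline
#'
#' Simulates the distribution of the mean neighborhood accuracy under
#' the null that embeddings carry no label information, giving a
#' quantile interval against which an observed mean accuracy can be
#' judged. Two equivalent nulls are offered: with `report = NULL`, each
#' query's neighbors are redrawn as k uniform picks without replacement
#' from the other N - 1 rows; given a [knn()] `report`, the neighbor
#' graph is held fixed and the labels are permuted across rows (much
#' faster for large N).
#'
#' @param labels Character vector of per-row labels.
#' @param k Neighborhood size (ignored when `report` is supplied).
#' @param B Number of Monte-Carlo replicates (default 1000).
#' @param seed Integer seed.
#' @param probs Interval quantiles (default 95%).
#' @param report Optional `neighborhood_report` for the label-shuffle
#'   null.
#' @return A list: `interval` (the quantiles), `mean`, `draws` (the B
#'   simulated mean accuracies).
#' @export
baseline_mc_interval <- function(labels, k, B = 1000L, seed = 1L,
                                 probs = c(0.025, 0.975), report = NULL) {
  n <- length(labels)
  draws <- with_seed(seed, {
    if (is.null(report)) {
      vapply(seq_len(B), function(b) {
        acc <- vapply(seq_len(n), function(i) {
          nbr <- sample.int(n - 1L, k)
          nbr[nbr >= i] <- nbr[nbr >= i] + 1L  # skip self
          mean(labels[nbr] == labels[i])
        }, numeric(1L))
        mean(acc)
      }, numeric(1L))
    } else {
      nbr <- report$neighbor_indices
      vapply(seq_len(B), function(b) {
        lab <- sample(labels)
        mean(matrix(lab[nbr], nrow = n) == lab)
      }, numeric(1L))
    }
  })
  list(interval = stats::quantile(draws, probs), mean = mean(draws),
       draws = draws)
}

#' Neighborhood statistics across a sweep of k
#'
#' Robustness utility: recomputes the headline neighborhood statistics
#' for several neighborhood sizes.
#'
#' @param embeddings An [embedding_set()] with `mutated_position` and/or
#'   `mutant_aa` metadata.
#' @param ks Integer vector of neighborhood sizes.
#' @param metric Passed to [knn()].
#' @return A data frame with one row per k: `k`, `median_position_distance`
#'   (NA when positions are absent), `mean_aa_accuracy` (NA when labels
#'   are absent).
#' @export
knn_sweep <- function(embeddings, ks, metric = "euclidean") {
  has_pos <- !is.null(embeddings$metadata$mutated_position)
  has_aa <- !is.null(embeddings$metadata$mutant_aa)
  rows <- lapply(ks, function(k) {
    rep <- knn(embeddings, k, metric = metric)
    data.frame(
      k = k,
      median_position_distance =
        if (has_pos) position_distance_stats(embeddings, rep)$global_median
        else NA_real_,
      mean_aa_accuracy =
        if (has_aa) aa_accuracy(embeddings, rep)$mean else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Concatenate two embedding sets row-wise by id
#'
#' Joint representation: rows are aligned by id (order taken from the
#' first set), matrices concatenated column-wise, and metadata merged.
#' A metadata column present in both sets must agree on every id;
#' disagreement is an error naming the offending id.
#'
#' @param e1,e2 [embedding_set()]s over the identical id set.
#' @return An [embedding_set()] of dimension `d1 + d2`.
#' @export
joint_concat <- function(e1, e2) {
  if (!setequal(e1$ids, e2$ids) || length(e1$ids) != length(e2$ids)) {
    stop("id mismatch between embedding sets", call. = FALSE)
  }
  hit <- match(e1$ids, e2$ids)
  m2 <- e2$matrix[hit, , drop = FALSE]
  meta2 <- e2$metadata[hit, , drop = FALSE]
  meta <- e1$metadata
  for (col in names(meta2)) {
    if (col %in% names(meta)) {
      both <- !is.na(meta[[col]]) & !is.na(meta2[[col]])
      bad <- both & meta[[col]] != meta2[[col]]
      if (any(bad)) {
        stop("metadata conflict on '", col, "' for id '",
             e1$ids[which(bad)[1L]], "'", call. = FALSE)
      }
      meta[[col]] <- ifelse(is.na(meta[[col]]), meta2[[col]], meta[[col]])
    } else {
      meta[[col]] <- meta2[[col]]
    }
  }
  embedding_set(e1$ids, cbind(e1$matrix, m2), meta)
}

#' Fit a single-layer (linear/ridge) prediction head
#'
#' Ordinary least squares with an optional ridge penalty on an embedding
#' set's matrix — the minimal sequence-level regression head used to
#' score representations. With `ridge = 0` the system must be
#' overdetermined and nonsingular.
#'
#' @param embeddings An [embedding_set()].
#' @param labels Numeric response; defaults to `metadata$label`.
#' @param ridge Nonnegative ridge penalty (default 0). The intercept is
#'   never penalized.
#' @return An object of class `linear_head` with `coef` and `intercept`.
#' @export
fit_linear_head <- function(embeddings, labels = embeddings$metadata$label,
                            ridge = 0) {
  x <- embeddings$matrix
  y <- as.numeric(labels)
  if (anyNA(y)) stop("labels must be complete", call. = FALSE)
  if (ridge < 0) stop("ridge must be nonnegative", call. = FALSE)
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  xtx <- crossprod(xc) + diag(ridge, ncol(x))
  beta <- tryCatch(solve(xtx, crossprod(xc, yc)), error = function(e) {
    stop("singular system; increase ridge", call. = FALSE)
  })
  structure(list(coef = drop(beta),
                 intercept = mean(y) - sum(attr(xc, "scaled:center") * beta),
                 ridge = ridge),
            class = "linear_head")
}

#' @export
predict.linear_head <- function(object, embeddings, ...) {
  drop(embeddings$matrix %*% object$coef) + object$intercept
}

#' Score predictions: R-squared and Spearman rank correlation
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @return A list with `r_squared` (coefficient of determination,
#'   `1 - SS_res/SS_tot`) and `spearman` (rank correlation).
#' @export
score_predictions <- function(predicted, observed) {
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  list(r_squared = 1 - ss_res / ss_tot,
       spearman = stats::cor(predicted, observed, method = "spearman"))
}
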