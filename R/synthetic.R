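#' A synthetic species model
#'
#' One species in a multi-species corpus generator: per-amino-acid
#' synonymous codon usage drawn from a symmetric Dirichlet (small
#' concentration `alpha` gives peaky, highly species-specific usage;
#' large `alpha` approaches uniform usage and erases the fingerprint),
#' plus a melting-point-like label profile (mean and residual sd in
#' degrees C) and a GC slope linking label to sequence GC fraction.
#'
#' @param name Species name.
#' @param alpha Dirichlet concentration for codon usage (default 0.5,
#'   clearly separated species).
#' @param label_mean Mean label for the species (degrees C).
#' @param label_sd Residual label noise sd (default 2).
#' @param gc_slope Label change per unit GC fraction (default 150, i.e.
#'   1.5 degrees per percentage point of GC).
#' @param seed Integer seed for the usage draw.
#' @param code A [genetic_code()].
#' @return An object of class `species_model` with a `usage` list
#'   (per-amino-acid probability vectors over the synonym sets).
#' @export
species_model <- function(name, alpha = 0.5, label_mean = 55, label_sd = 2,
                          gc_slope = 150, seed = 1L, code = genetic_code()) {
  if (alpha <= 0 || label_sd < 0) {
    stop("alpha must be positive and label_sd nonnegative", call. = FALSE)
  }
  usage <- with_seed(seed, lapply(code$synonym_sets, function(syn) {
    g <- stats::rgamma(length(syn), shape = alpha)
    while (sum(g) == 0) g <- stats::rgamma(length(syn), shape = alpha)
    stats::setNames(g / sum(g), syn)
  }))
  structure(list(name = name, alpha = alpha, usage = usage,
                 label_mean = label_mean, label_sd = label_sd,
                 gc_slope = gc_slope),
            class = "species_model")
}

#' Default panel of synthetic species
#'
#' Five species with codon-usage fingerprints drawn at Dirichlet
#' concentration `alpha` and label means spaced 5 degrees C apart
#' (distinct melting-point-like profiles).
#'
#' @param n_species Number of species (default 5).
#' @param alpha Dirichlet concentration (default 0.5).
#' @param seed Integer seed.
#' @param ... Passed to [species_model()].
#' @return A list of `species_model`s.
#' @export
default_species_models <- function(n_species = 5L, alpha = 0.5, seed = 1L, ...) {
  means <- 45 + 5 * (seq_len(n_species) - 1L)
  lapply(seq_len(n_species), function(i) {
    species_model(name = sprintf("sp%02d", i), alpha = alpha,
                  label_mean = means[i], seed = derive_seed(seed, sprintf("sp%02d", i)),
                  ...)
  })
}

#' Generate a multi-species CDS corpus with planted structure
#'
#' For each species: random proteins (uniform over the 20 amino acids),
#' codons drawn per amino acid from that species' usage, and labels
#' `label_mean + gc_slope * (gc - 0.5) + N(0, label_sd)`. The corpus
#' carries three recoverable signals — species codon fingerprints,
#' a GC-content effect on the label, and species-level label profiles.
#'
#' @param models List of [species_model()]s.
#' @param n_per_species Sequences per species.
#' @param protein_length Protein length in residues (codons per CDS).
#' @param seed Integer master seed.
#' @param code A [genetic_code()].
#' @return A `cds_records` table of `n_per_species * length(models)` rows.
#' @export
gen_species_corpus <- function(models, n_per_species, protein_length,
                               seed = 1L, code = genetic_code()) {
  aas <- setdiff(names(code$synonym_sets), "*")
  rows <- with_seed(seed, lapply(models, function(m) {
    seqs <- vapply(seq_len(n_per_species), function(i) {
      prot <- sample(aas, protein_length, replace = TRUE)
      codons <- vapply(prot, function(a) {
        u <- m$usage[[a]]
        names(u)[sample.int(length(u), 1L, prob = u)]
      }, character(1L))
      paste(codons, collapse = "")
    }, character(1L))
    gc <- gc_content(seqs)
    lab <- m$label_mean + m$gc_slope * (gc - 0.5) +
      stats::rnorm(n_per_species, 0, m$label_sd)
    data.frame(id = paste0(m$name, "_", seq_len(n_per_species)),
               sequence = seqs, species = m$name, label = lab,
               mutation = NA_character_, stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cds_records", "data.frame")
  out
}

#' Generate a complete single-codon mutation scan
#'
#' Emulates a deep mutational scan of one reference gene: a random
#' reference CDS of `length_codons` codons, every single-codon
#' substitution at every position (63 variants per position), and a
#' planted normalized-fitness label. The wildtype fitness is fixed at 1
#' on the normalized scale; variant fitness is `1 - severity + noise`,
#' with severity keyed either by mutated position (`position_effect`) or
#' by mutant amino acid (`aa_effect`). Synonymous variants get severity
#' 0, stop gains the maximal severity, so most variants land below the
#' wildtype while synonymous noise straddles 1.
#'
#' @param length_codons Reference length in codons, >= 2.
#' @param fitness_model `"position_effect"` or `"aa_effect"`.
#' @param seed Integer master seed.
#' @param noise_sd Gaussian noise sd on the normalized fitness scale
#'   (default 0.05).
#' @param max_severity Fitness drop of the most deleterious class
#'   (default 0.8).
#' @param include_stops Keep stop-gain variants (default `TRUE`).
#' @param code A [genetic_code()].
#' @return An object of class `mutation_scan`: `reference` (one-row
#'   `cds_records`), `variants` (`cds_records` with columns `position`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa` appended),
#'   `degeneracy_groups` (from [group_degenerate()] over the variants),
#'   and `f_wt` (wildtype fitness, 1).
#' @export
gen_mutation_scan <- function(length_codons,
                              fitness_model = c("position_effect", "aa_effect"),
                              seed = 1L, noise_sd = 0.05, max_severity = 0.8,
                              include_stops = TRUE, code = genetic_code()) {
  fitness_model <- match.arg(fitness_model)
  if (length_codons < 2L) stop("length_codons must be >= 2", call. = FALSE)
  sense <- names(code$table)[code$table != "*"]
  ref_codons <- with_seed(seed, c("ATG", sample(sense, length_codons - 1L,
                                                replace = TRUE)))
  ref_seq <- paste(ref_codons, collapse = "")
  reference <- cds_records("ref", ref_seq)
  all_codons <- names(code$table)

  # planted severity maps
  aas <- sort(setdiff(unique(unname(code$table)), "*"))
  severity_pos <- with_seed(derive_seed(seed, "pos_severity"),
                            stats::runif(length_codons, 0, max_severity))
  severity_aa <- with_seed(derive_seed(seed, "aa_severity"),
                           stats::setNames(stats::runif(length(aas), 0,
                                                        max_severity), aas))

  rows <- vector("list", length_codons)
  for (p in seq_len(length_codons)) {
    alts <- setdiff(all_codons, ref_codons[p])
    alt_aa <- unname(code$table[alts])
    if (!include_stops) {
      keep <- alt_aa != "*"
      alts <- alts[keep]
      alt_aa <- alt_aa[keep]
    }
    ref_aa <- unname(code$table[ref_codons[p]])
    pre <- if (p > 1L) paste(ref_codons[seq_len(p - 1L)], collapse = "") else ""
    post <- if (p < length_codons) {
      paste(ref_codons[(p + 1L):length_codons], collapse = "")
    } else ""
    seqs <- paste0(pre, alts, post)
    synonymous <- alt_aa == ref_aa
    sev <- switch(fitness_model,
      position_effect = ifelse(synonymous, 0, severity_pos[p]),
      aa_effect = ifelse(synonymous, 0,
                         ifelse(alt_aa == "*", max_severity,
                                severity_aa[alt_aa]))
    )
    if (fitness_model == "position_effect") {
      sev[alt_aa == "*" & !synonymous] <- max_severity
    }
    rows[[p]] <- data.frame(
      id = paste0("v_p", p, "_", alts),
      sequence = seqs,
      species = NA_character_,
      mutation = paste0(ref_aa, p, alt_aa),
      position = p,
      ref_codon = ref_codons[p],
      alt_codon = alts,
      ref_aa = ref_aa,
      alt_aa = alt_aa,
      severity = sev,
      stringsAsFactors = FALSE
    )
  }
  variants <- do.call(rbind, rows)
  noise <- with_seed(derive_seed(seed, "fitness_noise"),
                     stats::rnorm(nrow(variants), 0, noise_sd))
  variants$label <- 1 - variants$severity + noise
  variants$severity <- NULL
  variants <- variants[, c("id", "sequence", "species", "label", "mutation",
                           "position", "ref_codon", "alt_codon",
                           "ref_aa", "alt_aa")]
  rownames(variants) <- NULL
  class(variants) <- c("cds_records", "data.frame")
  structure(
    list(reference = reference, variants = variants,
         degeneracy_groups = group_degenerate(variants, code = code),
         f_wt = 1, fitness_model = fitness_model, seed = seed),
    class = "mutation_scan"
  )
}

#' @export
print.mutation_scan <- function(x, ...) {
  cat("<mutation_scan>", nchar(x$reference$sequence) / 3, "codons,",
      nrow(x$variants), "variants,",
      length(x$degeneracy_groups), "distinct proteins (",
      x$fitness_model, ")\n")
  invisible(x)
}

#' Generate embeddings with planted neighborhood structure
#'
#' Plants one of two local organizing principles into a synthetic
#' embedding matrix for a mutation scan — or none. Each distinct key
#' (mutated position, or mutant amino acid) is assigned a fixed random
#' d-vector center; a variant's embedding is
#' `cluster_scale * center(key) + N(0, noise_sd^2 I)`. With
#' `principle = "random"` the rows are pure isotropic noise, the
#' negative control for neighborhood statistics.
#'
#' @param variants A `cds_records` table with `position` and `alt_aa`
#'   columns (e.g. `gen_mutation_scan(...)$variants`, possibly filtered).
#' @param principle `"position"`, `"amino_acid"`, or `"random"`.
#' @param cluster_scale Separation of cluster centers (default 10).
#' @param noise_sd Isotropic noise sd (default 1).
#' @param d Embedding dimension (default 16).
#' @param seed Integer seed.
#' @return An [embedding_set()] whose metadata carries
#'   `mutated_position`, `mutant_aa`, and `label`.
#' @export
gen_structured_embeddings <- function(variants,
                                      principle = c("position", "amino_acid",
                                                    "random"),
                                      cluster_scale = 10, noise_sd = 1,
                                      d = 16L, seed = 1L) {
  principle <- match.arg(principle)
  if (cluster_scale < 0 || noise_sd < 0) {
    stop("cluster_scale and noise_sd must be nonnegative", call. = FALSE)
  }
  n <- nrow(variants)
  key <- switch(principle,
                position = as.character(variants$position),
                amino_acid = variants$alt_aa,
                random = rep("0", n))
  levels <- sort(unique(key))
  centers <- with_seed(derive_seed(seed, "centers"),
                       matrix(stats::rnorm(length(levels) * d), ncol = d,
                              dimnames = list(levels, NULL)))
  noise <- with_seed(derive_seed(seed, "noise"),
                     matrix(stats::rnorm(n * d, 0, noise_sd), ncol = d))
  mat <- noise
  if (principle != "random") {
    mat <- mat + cluster_scale * centers[key, , drop = FALSE]
  }
  rownames(mat) <- NULL
  embedding_set(
    variants$id, mat,
    data.frame(mutated_position = variants$position,
               mutant_aa = variants$alt_aa,
               species = variants$species,
               label = variants$label,
               stringsAsFactors = FALSE)
  )
}
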