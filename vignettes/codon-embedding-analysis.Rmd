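---
title: "Methods: codon-level curation, sampling nulls, and neighborhood probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-level curation, sampling nulls, and neighborhood probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonlens)
```

## The scientific setting

Sequence representation models come in two flavours that see the same protein
through different alphabets: nucleotide-level models consume the coding DNA
sequence (CDS), amino-acid-level models the translated protein. Because the
genetic code is degenerate — 61 sense codons encode 20 amino acids — the CDS
carries information the protein does not: synonymous codon choice, codon
usage bias, GC content, and, through usage bias, the species of origin.
Comparing the two model families fairly therefore raises a set of
methodological questions that are independent of any particular model:

* **Curation.** Does a retrieved CDS really encode the protein it is paired
  with? (Translation-match filtering.)
* **Degeneracy-aware splits.** In a mutation scan where many CDS translate to
  the same protein, how do you build training sets that do not leak test
  proteins? (The *Complete* and *Unique* set rules.)
* **Sampling nulls.** How much of a result depends on the *true* codons
  rather than on any synonymous-equivalent sequence? (Within-sequence
  permutation and uniform resampling.)
* **Global features.** How much of a performance gap is carried by features
  as coarse as GC content or species identity? (Feature augmentation of
  embeddings.)
* **Local embedding structure.** By what principle does a model organize its
  embedding neighborhoods — mutated position, or mutant amino acid?
  (The k-nearest-neighbor protocol.)

This package implements that machinery, and exercises it end-to-end on
synthetic data in which every signal is planted and therefore known. It does
not train or ship any language model: embeddings enter as plain matrices.

## Degeneracy-aware dataset construction

Two CDS are *degenerate* when they translate to the identical protein
(terminal stop ignored, case-insensitive). All curation logic keys on this
relation:

* `filter_translation_mismatch()` drops CDS whose strict translation does not
  equal the paired protein, recording the first mismatching residue.
* `build_complete_set(train, test)` removes from the training set every CDS
  degenerate with *any* test CDS — all surviving synonymous variants are
  kept, so the training set is as large as the split allows.
* `build_unique_set(cds, seed)` keeps exactly one CDS per degeneracy group,
  chosen uniformly at random under the seed. Retained records keep their raw
  labels; no averaging over the dropped synonymous variants is performed.
* `dedupe_test_degenerates()` applies the same rule to a test set that
  contains the occasional degenerate pair: one member survives, seeded.

Fitness labels for selection experiments follow the count-weighted
log-concentration readout: with allele counts $c_p$ on plates at drug
concentrations $A_p$,
$$f = \frac{\sum_p c_p \log_{10} A_p}{\sum_p c_p}, \qquad w = f / f_{WT},$$
so $w > 1$ flags an allele more fit than wildtype. The experimental
literature states this readout only as "a weighted average of the allele
counts on each plate by the log concentration"; the formula above is the
direct reading of that phrase, the base of the logarithm is injectable, and
the function is a plain injectable step so an alternative weighting can be
swapped in without touching the curation code.

**Stop-codon variants.** A full single-codon substitution library contains
stop gains (they are among the 63 alternatives at every position). Whether a
published scan retained them is usually unstated. The generator and the
curation operations keep them by default, translating them leniently with
`*` so degeneracy grouping is well defined, and `include_stops = FALSE`
removes them; nothing downstream depends on the choice.

## Sampling strategies as translation-preserving transforms

The two randomization strategies are implemented as exact,
translation-commuting sequence transforms:

* `permute_synonymous()` — for each amino acid, the multiset of codons at its
  positions *within one sequence* is preserved exactly; only their order is
  randomized. Consequences that tests rely on: translation, per-sequence
  codon counts, GC content, and the sequence's codon-usage fingerprint are
  all invariant; only codon-position relationships are destroyed.
* `sample_uniform()` — every codon is independently redrawn uniformly from
  its synonym set. Translation is invariant, but per-amino-acid codon
  frequencies converge to uniform, which provably erases any species
  fingerprint carried by usage bias.

Permutation is within-sequence (not across the dataset) because that is the
variant that conserves per-sequence usage — the property that separates it
cleanly from uniform resampling in the species-classification experiment.
A terminal stop codon is frozen in place during permutation so that
terminality is never disturbed; for uniform resampling a redrawn stop is
still a stop, so no freezing is needed (a flag exists for both). Start
codons are not treated specially: ATG is a synonym-set singleton, so the
common case is automatically fixed.

**Seeding.** `apply_strategy()` derives one random stream per record by a
stable 31-bit hash of the record id mixed with the master seed. Outputs are
therefore independent of dataset row order and bit-reproducible, which the
test suite asserts.

## Species features and the nearest-centroid stand-in

Species identification from codon usage is implemented as a transparent
nearest-centroid classifier: a species centroid is the mean per-sequence
codon-frequency vector (64 entries summing to 1), and a query is assigned to
the nearest centroid in Euclidean distance, ties broken by species name
order. This is deliberately the simplest classifier that can read the
codon-usage fingerprint: the package's experiments need an *interpretable
readout of whether usage information survives a transform*, not a
state-of-the-art species classifier. A multinomial-likelihood scorer would
be the natural extension point.

Augmentation features mirror that philosophy. "Normalized GC content" is
implemented as a z-score whose mean and *population* standard deviation are
estimated on the training split only and reused on held-out data (two
training sequences with GC 0.4/0.6 get scores −1/+1). Species enter as a
one-hot block with category order frozen by the training split; an unseen
species at prediction time yields an all-zero row plus a warning, not an
error. `augment()` appends blocks to pooled embeddings — the single-layer
head then sees them exactly as extra dimensions.

## The k-neighborhood protocol

For embeddings $f(s_i) \in \mathbb{R}^d$, the $k$-neighborhood of $s_i$ is
the set of $k$ other sequences minimizing the embedding distance. Euclidean
distance is the default; cosine distance is provided for parity but is not a
true metric and is known to be less reliable in high dimensions, which is why
it is not the default. Ties are broken by ascending row index, making every
report fully deterministic — important because the statistics below are
frozen into tests.

Two statistics summarize what a neighborhood shares with its query:

* **position distance** — $|pos_q - pos_n|$ over the $k$ neighbors; the
  headline number is a median. Whether "the median" of such an analysis is
  the pooled median over all $N \times k$ pairs or the median of per-query
  medians is ambiguous, so `position_distance_stats()` emits both (they
  coincide on strongly clustered data).
* **amino-acid accuracy** — the fraction of neighbors sharing the query's
  mutant amino acid, averaged over queries.

The reference point for accuracy is the exact expectation under a random
arrangement: if neighbors were $k$ uniform draws without replacement from
the other $N-1$ rows, a query with label $a$ matches each neighbor with
probability $(n_a - 1)/(N - 1)$, so
$$\mathbb{E}[\mathrm{acc}] = \frac{1}{N}\sum_q \frac{n_{\ell(q)} - 1}{N - 1},$$
independent of $k$. `random_baseline_accuracy()` computes this closed form;
it is validated in the tests against exhaustive enumeration at $N = 4$ and
against a $10^4$-replicate permutation oracle at random label vectors.
`baseline_mc_interval()` additionally gives the Monte-Carlo distribution of
the *mean* accuracy under the null, either by redrawing neighbors (small
$N$) or by permuting labels over a fixed neighbor graph (large $N$; the two
nulls have the same expectation, and the label-shuffle form preserves the
graph's edge-overlap correlation structure). Observed-vs-null comparisons
are made as two-sided Monte-Carlo permutation tests with the add-one
p-value convention rather than by comparing against estimated quantile
endpoints, because near the 2.5% boundary the quantile estimator's own
error at affordable replicate counts exceeds the margins of interest; the
replicate count (20&nbsp;000 in the acceptance suite) keeps the p-value's
Monte-Carlo error near 0.001.

## The synthetic generators and what they emulate

Every experiment runs on generated data with planted ground truth; all
generators are pure functions of their seeds.

**Species corpus** (`gen_species_corpus()`). Each species draws
per-amino-acid codon usage from a symmetric Dirichlet with concentration
$\alpha$; proteins are uniform random amino-acid strings; labels are
$\mu_s + \beta\,(GC - 0.5) + \varepsilon$. The defaults are fixed once, from
considerations a thermostability practitioner would recognize, and are the
conditions under which all reported numbers are computed:

* $\alpha = 0.5$ — clearly peaky usage, i.e. well-separated species
  fingerprints; large $\alpha$ (uniform usage) is the hard regime used to
  demonstrate chance-level classification.
* species label means 45, 50, … °C — distinct melting-point-like profiles
  spaced 5 °C apart, comparable to the spread between real proteomes.
* $\beta = 150$ °C per unit GC fraction (1.5 °C per percentage point) and
  residual noise $\sigma = 2$ °C. These were chosen by a variance-share
  argument made before any experiment was run: with ~300-codon sequences the
  within-species GC standard deviation is ≈ 0.015, so the GC term
  contributes variance ≈ $(150 \times 0.015)^2 \approx 5$, species means
  ≈ 25, noise 4 — shares that make both the species and the GC contribution
  individually resolvable (> 0.05 of total) by a linear head at the corpus
  sizes used.

**Mutation scan** (`gen_mutation_scan()`). A random reference CDS (first
codon ATG), all 63 single-codon substitutions at every position, normalized
fitness planted as $1 - \text{severity} + \varepsilon$ with
$\varepsilon \sim N(0, 0.05^2)$. Severity is keyed by mutated position or by
mutant amino acid (uniform on $[0, 0.8]$ per key), is 0 for synonymous
variants, and maximal for stop gains. Wildtype sits at 1; most variants land
below it, synonymous noise straddles it — the shape of real deep mutational
scans.

**Structured embeddings** (`gen_structured_embeddings()`). Each distinct key
(position or mutant amino acid) gets a fixed standard-normal center in
$\mathbb{R}^d$; a row is `cluster_scale * center + noise`. The acceptance
experiments use `cluster_scale / noise_sd = 10` and $d = 16$ — separation an
order of magnitude above noise, the regime in which the protocol must
recover planted structure essentially perfectly — and `principle = "random"`
as the matched negative control.

**What the generators do not emulate.** Real codon usage is not
Dirichlet-exchangeable across amino acids, real proteins are not uniform
residue strings, positions within real genes have correlated codon bias, and
real model embeddings are neither Gaussian nor isotropic with a single
organizing principle. Passing tests therefore certify the *machinery* —
that the transforms preserve what they must, that the statistics measure
what they claim, that planted structure of known strength is recovered and
absent structure is not invented. They do not certify any claim about what
actual trained models do to actual sequences.

## Problem sizes and numerical choices

The shipped experiments use: a 100-codon scan (6&nbsp;300 variants; 2&nbsp;001
distinct proteins in its nondegenerate subset), a 5-species corpus at 200
sequences × 300 codons per species with a 50/50 split, $k = 10$ with a sweep
over {5, 10, 20, 50}, five replicate seeds for the augmentation ladder, and
20&nbsp;000 Monte-Carlo replicates for null intervals — sizes at which every
planted effect is far from its detection threshold while the full pipeline
remains a desk-scale computation.

Other numerical conventions, in one place: codon positions are 1-based in
all I/O and descriptor strings and half-open 0-based only internally; k-mer
token maps are 1-based (token 1 of a 6-mer model covers residues 1–2);
distances are computed via the Gram-matrix identity with negative squared
distances clamped to 0; the ridge head never penalizes the intercept and
refuses a singular system at `ridge = 0`; `classify_species` ties go to the
lexicographically first species; empty sequences are domain errors, not
zeros.

## Known limitations

* Degeneracy comparison uses the translated protein string; it does not
  attempt alignment, so frame-shifted near-matches are simply mismatches.
* The nearest-centroid classifier ignores codon-count covariance; it is a
  readout, not a competitive classifier.
* `knn()` materializes the full $N \times N$ distance matrix — simple and
  exactly testable, with quadratic memory: fine to $N \sim 10^4$, not meant
  for $10^6$.
* The Monte-Carlo null for large $N$ conditions on the realized neighbor
  graph; its interval has correct coverage for the statistic but is not an
  interval for the closed-form baseline itself.
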