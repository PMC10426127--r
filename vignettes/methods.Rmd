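---
title: "Motif discovery and influence scoring from pooled single-cell data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif discovery and influence scoring from pooled single-cell data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scregmotif)
```

This vignette describes the model implemented by `scregmotif`, the
assumptions behind it, the tunable parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the method left room for interpretation.

## The regression model

The unit of analysis is a pair: a fixed-width DNA sequence (a promoter
window or an accessible-chromatin peak) and a vector of p pooled
measurements of its activity (log-transformed pooled expression of the
associated gene, or pooled accessibility of the peak). The model is a
shallow convolutional network:

1. a 2-D convolution with d filters of size (m, 4) and no bias over the
   one-hot encoded sequence (channels A, C, G, T; valid convolution,
   stride 1, forward strand only);
2. an ELU activation, `ELU(x) = x` for `x >= 0`, `exp(x) - 1` otherwise
   (alpha = 1), which bounds what follows below by -1;
3. global max pooling over positions, giving one activation per filter —
   the model sees *whether and how well* a motif matches somewhere in the
   sequence, not where;
4. a linear layer with bias mapping the d activations to the p pools. The
   bias absorbs everything about a pool's signal that is not explained by
   sequence content.

The assumptions this encodes: motif presence (not position, spacing, or
orientation) drives the signal; effects combine additively on the
log scale; and one filter can capture one motif because the architecture
is shallow — which is exactly what makes the filters directly
interpretable as motifs afterwards. Defaults are d = 600 and m = 12 at
atlas scale; the desk-scale analyses in this package's tests use d = 50 on
the reference fixture, which is ample for five planted motifs.

Because scanning is forward-strand only, motifs present on the reverse
strand are learned (if at all) as their reverse complements; the aligner
therefore compares both orientations.

## Pooling

Sparse per-cell counts are summed over pools before training. Seed cells
are chosen by covering-grid geometric sketching of a user-supplied
embedding: a binary search finds the largest axis-aligned grid side whose
number of occupied cubes still reaches the requested number of seeds, one
random cell is taken per occupied cube, and the selection is truncated at
random to exactly the requested count. This samples the *shape* of the
embedding rather than its density, so rare cell states receive seeds
(the test suite checks a 900:100 two-blob design, where a proportional
sampler would starve the minority blob).

A pool is its seed plus the q - 1 nearest cells by Euclidean distance in
the embedding, so pools have exactly q cells; `include_seed = FALSE`
switches to the seed-plus-q-neighbours convention (q + 1 cells) used by
some implementations, since published descriptions differ on whether the
seed is counted. Pooled values are `log(1 + sum of raw counts)` (natural
log). Each pool is annotated with its modal cell type (ties broken
lexicographically, so annotation is deterministic) and a purity fraction.

Embedding preprocessing — batch correction, PCA, removal of components
correlated with depth — is deliberately the caller's job: the package
consumes coordinates and never recomputes them.

Feature filtering follows detection-rate rules with a rescue clause:
features detected in fewer than `min_detect_frac` of pools are dropped;
features detected in fewer than `rescue_frac` are kept only if their mean
non-zero value exceeds `rescue_mean_threshold`. The three presets
(`kidney` 5%/16%/log10(3), `tabula-muris` 3%/8%/log10(4), `brain`
6%/15%/log10(4)) apply their rescue constants literally as numeric cutoffs
against the natural-log pooled values, reproducing the published recipes
verbatim even though the log bases differ; this is intentional and worth
knowing when porting thresholds to other datasets.

## Training

Data are split by nested cross-validation: K outer folds (default 10; the
outer test of each fold holds ~1/K of sequences), with each fold's
remainder split 80/20 into inner training and validation. Hyperparameters
are sampled from the stated priors — learning rate log-uniform on
[5e-4, 5e-2], conv-weight SD log-uniform on [1e-7, 1e-3], readout-weight
SD log-uniform on [1e-5, 1e-2], batch size uniform on {64, 128, 256, 512}
— and selected by synchronous successive halving (eta = 3, three rungs):
all candidates train briefly, the best third continues from its optimizer
state at triple the epoch budget, and so on. Two deliberate deviations
from the original tooling, made because they do not change selection
behaviour at this scale: candidates are drawn i.i.d. from the priors
rather than proposed by a Bayesian optimizer, and the rungs are
synchronous rather than asynchronous.

Final training uses Adam (moments 0.9/0.999, eps 1e-8 — standard values,
chosen because the method's description leaves them unstated) with MSE
loss. "Patience 1" is interpreted strictly: training stops at the first
epoch whose validation MSE fails to improve on the best so far, and the
best-so-far parameters are returned. One model is trained per outer fold,
and the ensemble size r equals K, which is how "the concatenated PPMs of
the K models" are produced downstream.

The entire network, backpropagation and optimizer are implemented in R on
BLAS matrix products; the convolution is a single matrix multiplication
against a precomputed window-design matrix, and the max-pool argmax breaks
ties toward the lowest position so motif extraction is deterministic.

Evaluation reports explained variance — squared Pearson correlation
between predicted and observed values per pool, averaged over pools — on
the outer test set, plus two negative controls: per-sequence nucleotide
shuffling (destroys motifs, preserves composition) and permutation of the
pool order (destroys cell-type specificity, preserves the sequence
signal). A trustworthy fit has intact R² clearly above both.

## Motifs, influence, and downstream analyses

For each filter, every training sequence contributes its best window (the
max-activating length-m subsequence) to a position frequency matrix,
*provided* the activation is strictly positive; sequences that never
activate a filter are excluded, and filters activated by nothing are
flagged empty. PPMs are plain column-normalized PFMs with no pseudocount;
a 1e-4 pseudocount is added only when writing MEME files so downstream
log-odds tools never see zeros.

Alignment to a motif database uses Tomtom (`-thresh 0.05`, otherwise
default options, since the original invocation is not fully specified)
when the executable is on the PATH. Otherwise a built-in comparator runs:
for each query-target pair, the best alignment over all ungapped offsets
with at least 4 overlapping columns and both orientations, ranked by the
*summed* per-column Pearson correlation (summing rather than averaging
rewards long good overlaps; short accidental overlaps would otherwise
dominate the null), with an empirical p-value from 1000 column-shuffled
copies of the query and BH q-values across all pairs. The reported `r` is
the mean per-column correlation of the winning alignment. Each motif takes
the cluster of its most significant hit (ties: lower p, then lexicographic
target id); clusters found in fewer than half of the K models are
discarded as irreproducible.

The influence of motif i on pool j is the mean, over the fold's validation
sequences, of the prediction change when every parameter of filter i is
zeroed. Because a zeroed filter yields ELU(0) = 0 and the readout is
linear, this equals `fc_weights[i, j] * mean_k a_ik` exactly; the package
computes that closed form and the test suite verifies it against
brute-force model re-evaluation to 1e-6. Influences are averaged over
pools per cell type and summed over motifs per retained cluster; rows of
any influence matrix can be z-transformed (population SD; constant rows
map to zero with a warning rather than NaN) to highlight cell-type
specificity against the large shared component.

Downstream, Spearman correlations (two-sided p-values by the large-sample
t approximation) relate cluster influence to TF expression and to
gene-set mean expression; gene sets with 50 or more genes are discarded,
the top 500 sets by maximum absolute correlation are kept (the "top 1%"
variant is available as an option), and their correlation profiles are
grouped by average-linkage hierarchical clustering (linkage unstated in
the source method; average chosen) cut at k = 3. The motif-space matrix
concatenates each model's post-ELU max-pooled activations run-major into a
sequences x (r·d) matrix; per-family sums of its columns define
co-occurrence gene sets via the 75%-of-maximum rule. Embedding that matrix
(UMAP etc.) is left to external tools: the package's tested surface ends
at the matrix.

## The synthetic-data generator

The generator is first-class, tested code, and defines the study
conditions under which the method is validated. Defaults: 2000 sequences
of 200 nt of i.i.d. background at 50% GC; five 12-nt motifs whose PPMs
put 0.85 on a random consensus base per column, each planted independently
with probability 0.5 at a uniform non-overlapping position (instances
drawn column-wise from the PPM; a planting that cannot be placed without
overlap after 100 tries is skipped with a warning — non-overlap keeps the
per-sequence counts unambiguous for truth-based scoring). Five cell
types; the effect of motif m in cell type t on log expression halves with
the circular distance between m's dominant type and t, with strengths
(2.0, 1.6, 1.2, -0.8, 0.9) — motif 4 is a repressor. The graded design
reflects that regulatory programs are shared across related cell types,
and it keeps rank-based recovery metrics meaningful: a design with exact
zeros off the diagonal caps the Spearman correlation between planted and
perfectly recovered effects at ~0.70 purely through rank ties.

Cell-level data: 1000 cells assigned evenly to the five types, embedded as
Gaussian blobs (SD 0.5, centers 10 apart — cleanly separated, as a good
batch-corrected embedding of distinct types would be); per-cell counts are
Poisson with rate `(exp(E) - 1) / q`, so a pure pool of q = 20 cells sums
to the intended expected value in expectation, and 50 pools are built by
the package's own sketching and pooling code. The generator also emits an
analytic target matrix (expected values plus Gaussian noise, exact at
`noise_sd = 0`) used where tests need noiseless targets, per-motif TF
expression proxies tracking effect magnitude (so activators correlate
positively with influence and the repressor negatively), and the planted
PPMs as a MEME database with one cluster per motif.

What the generator does *not* emulate: dropout curves and overdispersion
beyond Poisson, batch effects, doublets, correlated motif co-occurrence,
positional or strand preferences, and degenerate multi-TF motif families.
Passing the end-to-end tests therefore shows the machinery is correct and
the method recovers strong, clean signals — it does not by itself
establish performance on real atlases, where effect sizes are smaller and
confounding is richer.

## Problem sizes and numerical choices

The reference analyses in the tests and the acceptance script use the
fixture above with d = 50, m = 12, K = 3 folds, 8 search calibrations and
a 24-epoch budget — sizes chosen so a complete run takes a few minutes on
a single CPU while leaving the recovery margins wide (5/5 planted motifs
at mean per-column correlation > 0.99; Spearman ~0.9 between planted and
recovered effects; intact R² well above both permutation controls).
Unit-level oracles run at much smaller sizes (d = 3-5, L = 30-50).

Other fixed choices: coordinates are 0-based half-open internally, with
`coord_base = 1` as the default for gene tables (Ensembl-style exports)
and 0 for BED-like input; the strand-aware gene start is the anchor for
promoter windows; peak windows take the midpoint, rounding down for
odd-length peaks; N-containing windows are dropped at extraction, while
the encoder maps N to an all-zero column for user-supplied FASTA;
checkpoints are JSON at full precision; the pipeline derives stage seeds
from one global seed and skips stages whose configuration hash is
unchanged. The command-line entry point (`inst/scripts/scregmotif.R`) is a
thin wrapper over the exported functions, which are the primary interface.

## Known limitations

Forward-strand-only scanning halves sensitivity to reverse-strand motifs
unless data are augmented; the brute-force kNN search in pooling is
quadratic in cells and intended for up to ~10^5 cells; the fallback
aligner's empirical p-values are bounded below by 1/(n_shuffle + 1), so
with few database motifs the BH correction is coarse; and only a minority
of filters typically converge to clean motifs — the rest are filtered by
the positive-activation and reproducibility rules, which is expected
behaviour for this architecture, not a defect of a particular run.
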