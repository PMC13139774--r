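---
title: "Multi-scale contrastive embeddings of cancer mutation signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale contrastive embeddings of cancer mutation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cohort-level cancer clustering asks how entire cancer types — not individual
tumors — relate to each other through their somatic mutation landscapes.
`mscontab` implements a fully unsupervised pipeline for this task: each
cancer cohort's protein-coding single-nucleotide substitutions are summarized
into two complementary signature views, a pair of attentive tabular encoders
maps the views into a shared 64-dimensional space under a contrastive
objective, and the fused per-cohort embeddings are clustered and scored with
standard internal validity indices.

## Mutation signature views

All counting is over the 12 ordered strand-specific substitution categories
(A>C, A>G, ..., T>G, in fixed lexicographic order). Complementary pairs such
as C>T and G>A are deliberately **not** collapsed into the 6
pyrimidine-centric classes: their counts are not equal in real extracts and
the asymmetry itself carries signal about replication-independent processes.

* **Gene view** (`build_gene_signature`): the cohort's genes are ranked by
  total mutation count (ties alphabetical, for platform-independent
  determinism), the top 25 retained, and each gene's mutations tallied per
  substitution category. The 25 x 12 count matrix is flattened row-major to a
  300-dimensional vector; cohorts with fewer than 25 mutated genes are
  zero-padded so the encoder input width never changes. Columns of the
  stacked matrix are *rank slots* (`gene_rank01|C>T`), not gene identities,
  because each cohort has its own top-25 list; the lists themselves are kept
  alongside for the overlap analyses.
* **Chromosome view** (`build_chromosome_signature`): substitutions are
  tallied per (chromosome, category) over the 24 canonical chromosomes
  (1–22, X, Y) and each chromosome's row is divided by its GRCh38
  primary-assembly length, giving loads in mutations per base pair; the
  24 x 12 matrix flattens to 288 dimensions. By default *all* retained coding
  SNVs contribute; `restrict_to_top_genes = TRUE` confines the tally to the
  cohort's top-25 genes for users who want both views drawn from the same
  gene population. We default to all records because the chromosome view is
  meant to capture genome-wide load, and restricting it to 25 genes would
  make it largely redundant with the gene view.

Record hygiene happens upstream in `filter_records`: structural checks first
(malformed rows, non-canonical chromosomes — mitochondrial and alt contigs
are excluded by the 24-chromosome design), then semantic ones (non-SNVs,
ref = alt, alternative-transcript gene identifiers containing `_ENST`,
non-coding rows when the input carries a coding annotation). Each record is
charged to the *first* rule it violates so the exclusion report is
deterministic, and `n_input = n_retained + sum(dropped)` always holds.

## Input scaling

The encoders consume `log1p`-transformed, per-feature-centered matrices in
which each view is divided by a single pooled scale (the root mean feature
variance), so the typical feature has unit spread but the *relative*
variances of features are preserved (`scaling = "log1p_center"`).

This choice is deliberate and matters more than it may appear. The more
common per-feature z-scoring (`"log1p_zscore"`, available as an option)
rescales every column to unit variance — including columns whose only
variation is sampling noise. Under a contrastive objective that treats every
cohort as its own class, those amplified noise directions are exactly what
the encoder uses to push same-cluster cohorts apart, and cohort-level
cluster structure degrades over training. With pooled scaling, noise
directions stay genuinely small and the cluster geometry survives the full
training schedule. The transform is stored with its parameters and is
exactly invertible on the training matrix.

## Encoders

Each view has its own TabNet-style encoder (`encoder_params`,
`tabnet_init`, `encode`): at each of 3 decision steps an attentive
transformer computes a sparse attention mask over input features via
**sparsemax** (the Euclidean projection onto the probability simplex,
computed by the sorted-threshold algorithm — masks sum to one and contain
exact zeros), the masked features pass through a feature transformer of two
shared plus two step-specific GLU blocks with residual connections scaled by
sqrt(0.5), and the rectified decision outputs are summed into a
64-dimensional latent. A running prior, updated multiplicatively by
(gamma − mask) with gamma = 1.3, discourages re-attending to features already
used. The per-step masks are retained and can be aggregated into per-feature
importances (`feature_importance`), which map back to named features.

Hyperparameters (3 steps, decision and attention widths 64, gamma 1.3, block
layout) follow the original TabNet defaults and are all exposed in
`encoder_params`. Batch-statistics-based normalization is deliberately
absent: with mini-batches of 8 cohorts, batch statistics are noisy and break
run-to-run determinism, and a batch-free per-feature affine immediately after
a linear layer is a redundant reparameterization, so the affine freedom is
simply carried by the linear layers themselves.

Forward and backward passes are written out explicitly (no autodiff
framework); gradients flow through the masks, the sparsemax projections, the
prior chain and all GLU blocks, and are verified against central finite
differences in the test suite. The Adam update runs as a fused C++ kernel
over the flattened parameter vectors.

## Contrastive objective

The two views of the same cohort form a positive pair; all other projections
in the mini-batch are negatives. Latents pass through per-view 2-layer
projection heads (64-64-64, ReLU) and are L2-normalized, and the NT-Xent
loss with temperature tau = 0.5 is averaged over all 2N anchors of a batch
(both view directions). The softmax denominator excludes the anchor itself
(the standard SimCLR convention); a variant that instead excludes the
positive is available via `denominator = "exclude_positive"` for exactness
studies, but is not the default because the anchor's own exp(1/tau)
self-similarity term would dominate its denominator.

Training (`train_ms_contab`) follows a fixed protocol: 100 epochs of Adam at
learning rate 1e-3 with shuffled without-replacement mini-batches of 8
cohorts (a trailing batch of 1 is merged into its predecessor, since an
anchor needs at least one negative), seed 42 by default. Every source of
randomness — weight initialization and batch order — derives from the single
config seed, so two runs on one platform are bit-identical.

After training, a full-batch evaluation pass produces the per-view
projections `Zg`, `Zc`, and the embedding used downstream is their fusion
(`fuse_embeddings`): by default each view is row-normalized, averaged and
re-normalized, keeping the embedding at 64 dimensions; concatenation
(128-dim) is the alternative. Clustering the fused *projections* (rather
than the pre-projection latents, or either single view) is a design choice:
the normalized mean keeps the embedding at the same 64 dimensions as each
view, and the pre-projection latents empirically retain less cluster
structure here, so the projections are the right object to cluster.

## Downstream evaluation

`kmeans_cluster` (best of 10 seeded restarts by within-cluster SS, labels
canonicalized by first appearance) feeds `internal_metrics`, which computes
silhouette, Davies–Bouldin and Calinski–Harabasz with the Euclidean metric
in whichever space it is given; results carry a `space_tag` (`original` vs
`projected_2d`) because the two differ severalfold and must never be mixed
silently. A point in a singleton cluster contributes a silhouette term of 0.
The implementations are checked in the tests against hand-derived fixture
values and against an independent reference implementation to 1e-9.

The rest of the analysis surface mirrors what one wants to report for a
two-cluster pan-cancer structure: cosine similarity matrices ordered by
cluster, within/between-cluster mean similarities, cluster prototypes (the
member with maximal mean cosine similarity to co-members), 3-nearest-neighbor
tables, cluster-level substitution spectra and length-normalized chromosome
loads (unweighted cohort means), and top-gene set overlaps (per-cluster union
of member top-25 lists, shared/unique Venn counts). Two-dimensional t-SNE and
UMAP projections are treated as an external contract — deterministic given a
seed — and delegated to the installed Python scientific stack, with a pure-R
PCA projection always available.

## Baselines and ablations

Five comparison embeddings run through the identical downstream pipeline
(`run_baseline`): NMF on the raw non-negative concatenated views (Lee–Seung
multiplicative updates; the rank is configurable because a rank equal to the
number of cohorts is degenerate), Ward hierarchical clustering cut at k
(labels only, scored on the concatenated features), a shallow reconstruction
autoencoder (588-128-64 bottleneck), a SimCLR-style single-MLP contrastive
model over feature-dropout + Gaussian-jitter augmentations of the
concatenated views (a single-view contrastive model needs an augmentation
recipe; dropout p = 0.1 and jitter sd = 0.1 are our choices), and
DeepCluster-style alternation of k-means pseudo-labels with classification
updates.

The ablation grid (`run_ablation`) removes one component at a time: the
gene-view TabNet, the chromosome-view TabNet, or both are replaced by
2-layer MLPs of matched output width, or the contrastive objective is
removed. For the last mode the default is to keep both TabNet encoders *at
their seeded initialization* (no training signal at all). An alternative
that trains with a mean-squared alignment between the paired projections is
available (`no_contrastive_variant = "mse_align"`), but it is not the
default: MSE alignment drives the two views toward a collapsed embedding,
and near-duplicate points make silhouette approach 1 regardless of any
biological structure — a comparison that would reward the pathology rather
than measure the contribution of the loss. The untrained variant reproduces
the expected degradation direction.

## The synthetic cohort generator

`generate_dataset` emits COSMIC-shaped mutation tables with planted
cohort-cluster structure so the whole pipeline is testable offline. Defaults
(40 cohorts, 2 equal clusters) encode a contrast modeled on the high-burden
solid-tumor vs lower-burden hormone/hematopoietic split: cluster 1 has mean
burden 30,000 mutations per cohort, C>T/G>A-dominated spectra (0.26 each)
and elevated load on chromosomes 19, 1, 7, 9; cluster 2 has mean burden
10,000, a flatter spectrum with relatively elevated G>T (0.12), and
length-proportional chromosome rates. Gene propensities follow a power law
over a 500-symbol vocabulary with 60% of the top-25 slots shared between
clusters and the rest cluster-specific, echoing the shared-backbone /
unique-driver structure of real top-gene lists. Burden scale is drawn per
cohort from a Poisson around the cluster mean; each cohort's substitution
mixture is a Dirichlet perturbation of its cluster bias with concentration
1e4.

Two generator choices deserve justification. The burden scale matches real
cohort-level extracts, which pool thousands of tumors — tens of thousands of
coding SNVs per cancer type is conservative — and at that depth the
multinomial sampling noise of a cohort's signature is small. The Dirichlet
concentration makes cluster membership essentially determine a cohort's
substitution mixture. Together they make the planted structure crisp at
cohort scale, which is what a recovery harness needs: under these conditions
the full pipeline recovers the planted labels exactly (ARI = 1.0 across
seeds), and under `separation_dial(cfg, 0)` — which collapses all
cluster profiles onto their common mean — recovery falls to chance
(median ARI about 0). The dial interpolates every cluster-level profile
(gene propensities, spectra, chromosome rates, burden) linearly toward the
across-cluster mean, so intermediate levels give intermediate separability.

What the generator does **not** emulate: trinucleotide context, selection,
clonal structure, hypermutator samples, inter-gene correlation, and realistic
within-cluster biological heterogeneity (real cancer types inside one
cluster differ far more than Dirichlet-1e4 cohorts do). Passing the recovery
tests therefore demonstrates that the machinery is correct and that the
objective preserves strong planted structure through a full training run —
not that real COSMIC data would split this cleanly, and none of the
published real-data metric values are reproduced or asserted here.

## Numerical and degenerate-input choices

* Sparsemax on ties projects to the uniform face (e.g. a constant vector
  maps to uniform); its backward pass uses the support-restricted Jacobian.
* `kmeans_cluster(k = n)` short-circuits to the identity clustering (zero
  within-SS) rather than relying on the underlying routine's behavior.
* Calinski–Harabasz is reported as `Inf` when the within-cluster scatter is
  exactly zero; Davies–Bouldin is 0 in that case.
* Empty cohorts produce all-zero signatures with a warning, never an error;
  features constant across cohorts scale to exactly 0.
* A trailing training batch of size 1 is merged into the previous batch.
* The NT-Xent log-sum-exp is computed with max-shifting for stability.

## Problem sizes and determinism

The shipped tests train the full model (40 cohorts, 100 epochs) across five
seeds for the recovery, null-calibration and ablation comparisons, and use
12-cohort configurations for the faster unit checks; these sizes were chosen
so the planted-structure properties are measured on the same conditions the
generator defaults define while keeping the suite practical to run
routinely. All heavy results are memoized and shared across test blocks.
Every training run, generator draw and clustering restart is governed by an
explicit integer seed, and repeated runs with the same seed are
bit-identical on a given platform.

## Known limitations

* The 12-category representation ignores sequence context; no 96-channel
  signatures, indels or doublet substitutions.
* Cohort counts (not per-sample profiles) are the unit of analysis;
  hypermutator samples are neither detected nor down-weighted before the
  top-25 ranking.
* Internal validity indices cannot distinguish "meaningful clusters" from
  geometric artifacts (the MSE-alignment collapse above is the cautionary
  example); planted-label ARI is the only correctness measure, and it exists
  only for synthetic data.
* t-SNE/UMAP are external dependencies; only the PCA projection is
  guaranteed in a minimal R installation.
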