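---
title: "Predicting open chromatin interactions from DNA sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting open chromatin interactions from DNA sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Chromatin loops bring distal regulatory elements into contact with
promoters. Assays that map them genome-wide (ChIA-PET, Hi-C) are costly,
so they are rarely run on large clinical cohorts; open chromatin assays
(DNase-seq, ATAC-seq) are routine. `seqloop` implements a predictor of
*open chromatin interactions*: given only the open chromatin regions of a
sample and the genome sequence, it scores every candidate pair of anchors
for the probability that they interact.

The model has three stages, trained in order:

1. **Sequence feature extractor** (stage 1). A small convolutional
   network reads the one-hot encoded DNA of each anchor. Both the forward
   and the reverse-complement sequence of each anchor are passed through
   the *same* extractor, giving four feature blocks per pair — left-F,
   left-RC, right-F, right-RC — of one value per last-layer kernel
   (global max pooling). The extractor is pretrained end-to-end with a
   small dense head on a *distance-matched* dataset (negatives sampled so
   that their genomic-distance distribution matches the positives, which
   prevents distance from trivially separating the classes), then frozen.
2. **Gradient-boosted trees** (stage 2). With the extractor frozen, a
   gradient-boosted-tree classifier is trained on the four feature blocks
   (optionally plus the raw anchor distance in bp) using an *extended*
   dataset with many more negatives. Tree ensembles handle the
   heavily imbalanced, interaction-style feature space better than the
   dense head, and their gain-based importances are interpretable.
3. **From-open-chromatin model** (stage 3). Candidate anchors are built
   from open chromatin peaks by merging peaks within 3,000 bp and
   extending the merged regions by 1,000 bp on each side — the parameter
   combination selected on validation data for this anchor-construction
   task. All same-chromosome anchor pairs within a span cap are
   enumerated, labeled by overlap with known loops, and a final boosted
   classifier is trained on them. At prediction time the pipeline needs
   only a peak file and a genome.

Evaluation uses precision-recall throughout because the from-open task is
extremely imbalanced (empirically around 1:100 or worse); the auPRC
baseline under uninformative scores equals the positive-class prevalence.
Train/validation/test splits are *by chromosome*: random pair-level
splitting leaks anchor sequences between folds and inflates performance.

## Architecture and tunable parameters

| parameter | default | meaning |
|---|---|---|
| `input_length` | 1000 bp | window centered on the anchor midpoint |
| conv layer 1 | 64 kernels x 19 bp | motif-scale detectors (DeepBind-scale) |
| max pooling | width 10, non-overlapping | positional tolerance |
| conv layer 2 | 32 kernels x 11 | composite features; interpreted as "last-layer kernels" |
| head | 128 hidden units | pretraining only, discarded after stage 1 |
| optimizer | Adam, lr 1e-3, batch 128 | up to 30 epochs, early stopping on validation auPRC, patience 5 |
| GB trees | 500 trees, depth 6, eta 0.05, subsample 0.8 | early stopping on validation auPRC (50 rounds) |

Two convolutional layers are the minimum for the package's
interpretation toolkit: first-layer kernels are converted to PWMs and
matched to motif databases, and last-layer kernels are ranked by the
importance of the features they generate.

Class imbalance in stage 1 is handled by down-weighting negatives to an
effective 1:1; the boosted stages see the raw imbalance (their ranking
objective tolerates it). `N` bases are encoded as all-zero rows (absence
of evidence) rather than 0.25. Distance enters the classifiers raw in bp
— trees are invariant to monotone transforms.

### Kernel initialization

Randomly initialized convolutional kernels almost never align with any
shared sequence motif, and at the sample sizes realistic for loop
datasets, gradient training then memorizes individual anchors rather
than discovering shared features: training loss falls while held-out
auPRC stays at prevalence. `train_stage1()` therefore defaults to
*discriminative k-mer seeding* (`kernel_init = "kmer"`): 8-mers are
counted in positive versus negative training anchor sequences, scored by
a two-proportion z statistic, and the top-scoring k-mers are written
into the first-layer kernels (match weight +0.75, mismatch -0.25,
zero-mean columns) with the random initialization kept at low amplitude
elsewhere. All refinement — widening the seeds into the full motif,
discarding unhelpful seeds — is left to gradient training.
`kernel_init = "random"` restores pure He initialization.

## Dataset construction

* **Distance-matched negatives** (`sample_distance_matched_negatives`):
  candidates are re-pairings of the observed positive anchors (keeping
  sequence composition matched), positives' distances are binned into 50
  log10-spaced bins, and each bin contributes `ratio` (default 5) times
  its positive count, sampled without replacement. Bins whose candidates
  are exhausted re-allocate their deficit to the nearest remaining
  candidates with a warning.
* **Extended negatives** (`build_extended_negatives`): uniform draws over
  the same candidate space within the positive distance range, default
  25 per positive.
* **From-open pairs** (`enumerate_and_label_pairs`): all anchor pairs
  within `max_span` (default 2 Mb); a pair is positive iff its left
  anchor overlaps one anchor of a known loop and its right anchor
  overlaps the other anchor of the same loop (minimum overlap 1 bp,
  configurable).
* Coordinates are BED-convention (0-based, half-open) everywhere; the
  merge rule unions intervals whose gap (`next start - current end`) is
  at most the merging distance; pair distance is the absolute difference
  of anchor midpoints (midpoints are stable under symmetric extension).

## Interpretation

* **Kernel PWMs** (`kernels_to_pwms`): DeepBind-style — kernel-width
  windows from probe sequences are scored by the convolution; windows
  whose response exceeds half the kernel's maximum (and is positive) are
  aligned and counted with pseudocount 1. Kernels with fewer than 10
  activating windows are marked inactive.
* **Database matching** (`match_pwm_to_database`): candidate alignments
  over all offsets (minimum 5 aligned columns) and both orientations are
  ranked by Pearson correlation weighted by the square root of the
  aligned width — without the length weighting, 5-column alignments
  against low-complexity column runs (e.g. a G-run) dominate and the
  self-match guarantee breaks. Significance is an empirical p-value
  against position-shuffled queries; detection counts across models use
  Benjamini-Hochberg at 0.05 over kernels x motifs.
* **Convergence analysis** (`convergence_analysis`): mean importance per
  (anchor, orientation) block and Pearson correlations of kernel-matched
  importance vectors across anchors. The convergence flag is true iff a
  convergent block combination (left-F with right-RC, or its mirror)
  dominates the opposite combination in mean importance *and* its
  cross-strand correlation exceeds the mean same-strand correlation —
  the signature expected when loop anchors carry motifs oriented toward
  each other, as CTCF sites at loop anchors do. Note that the two
  convergent combinations are equivalent up to which strand the kernels
  happen to be tuned to; a kernel tuned to the reverse-complement of the
  underlying motif produces the mirror pattern.

## Cohort statistics

Predictions from many samples over a pooled anchor universe form a
binary presence matrix (each sample thresholded at its own
F-score-selected operating point). On it the package computes
conservation profiles (fraction of interactions seen in exactly k
samples), two-sided Fisher exact tests for differential presence between
two groups with BH adjustment (degenerate all-present/all-absent rows
get p = 1 and a flag), attribution of each differential interaction to
its anchors (both / one-side / neither anchors themselves differential
in the same direction), and promoter IFC scores — the ratio of mean
promoter-touching interaction counts between groups, computed over
promoter windows supplied as BED (±2 kb around the TSS is the intended
default), with an optional Kruskal-Wallis test across expression
classes. Matching of pairs across samples is by exact identity over the
pooled universe, which is why predictions must be expressed over pooled
anchors.

## The synthetic study generator

`simulate_loop_study()` generates every input the pipeline consumes: an
order-0 random genome at configurable GC; uniformly placed,
non-overlapping open regions; positive loops with log-normal distances
(median 100 kb, sdlog 1 — ChIA-PET-like span scales); a sharp,
non-palindromic 19-bp planted PWM embedded *convergently* (forward
instance in the left anchor, reverse complement in the right), each
anchor independently with the embedding probability; background motif
instances in random orientation in non-anchor regions; distance-matched
(1:5) and extended (1:25) negative tiers drawn from the non-anchor
regions by the *same* distance-sampling procedure as the positives, so
the tiers stay distance-matched; signal tracks enriched at positive
anchors; and a six-sample cohort (2 uCLL-like vs 4 mCLL-like) with a
planted differential subset. Everything is byte-deterministic under the
config seed, and a manifest records every planted instance.

The test suite's study uses eight 8-Mb chromosomes, 12,000 open regions
of 500 bp, 2,000 positive loops, embedding probability 0.9 and
background rate 0.1, with the extractor configured at input length 500,
32x19 + 16x11 kernels and hidden width 64 — sizes chosen so the full
study trains in minutes on one CPU while leaving the learning problem
non-trivial.

**What the generator does not emulate.** The background sequence has no
repeat structure or composition bias; open regions are uniform; and —
most importantly — the convergent signature is *anchor-intrinsic*: any
left-type anchor paired with any right-type anchor within range looks
convergent, so pairing-specific information beyond distance does not
exist in the simulation. This caps the precision of the from-open
pipeline at realistic loop densities (a handful of
sequence-indistinguishable re-combinations per true pair), which mirrors
the real-data regime where from-open auPRCs are far below the
within-loop-set values. Passing tests therefore demonstrate that the
machinery recovers planted signal and ranks true pairs far above chance;
they do not imply near-perfect genome-wide loop calling on real data.

## Numerical choices and degenerate inputs

* Determinism: all RNG flows through explicit seeds; stage-1 training is
  single-threaded with caller-supplied shuffling orders, boosting runs
  with `nthread = 1`. Two runs with the same seed are byte-identical.
* auPRC uses average-precision (step) integration with tied scores
  grouped into one threshold; trapezoidal PR interpolation is avoided as
  optimistic. The F-score scan breaks ties toward the larger threshold
  and scores F = 0 when no positives are predicted.
* Fisher tests on degenerate rows return p = 1 with a flag; correlation
  of constant importance vectors is reported as NA with a warning and
  the convergence flag stays false.
* Extractor checkpoints store parameters as `%.17g` strings so the
  doubles round-trip exactly through JSON.
* Anchor windows at chromosome edges are shifted inward (and N-padded if
  the chromosome is shorter than the window).

## Known limitations

* The extractor is deliberately small; it is not meant to compete with
  GPU-scale genomics architectures, and no architecture search is done.
* k-mer seeding assumes discriminative sequence content is local
  (motif-like); purely distributed signals would need `kernel_init =
  "random"` and far more data.
* Cross-sample matching of interactions requires a pooled anchor
  universe; there is no fuzzy overlap-based matching of predictions made
  over different anchor sets.
* Scores are probabilities under the training prevalence, not calibrated
  contact frequencies.
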