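# seqloop

Predicting open chromatin interactions from DNA sequence.

Chromatin loops connect distal regulatory elements to the genes they
control, but the assays that map them (ChIA-PET, Hi-C) are too costly to
run on large cohorts. Open chromatin profiling (ATAC-seq, DNase-seq) is
routine. `seqloop` predicts which pairs of open chromatin regions
interact, using only the genome sequence at the two anchors and the
distance between them.

The predictor is a three-stage pipeline:

1. a convolutional **sequence feature extractor** reads the one-hot DNA
   of each anchor in both orientations (left-F, left-RC, right-F,
   right-RC blocks share one extractor), pretrained on a
   *distance-matched* dataset — negatives sampled so that their genomic
   distance distribution matches the positives, so distance alone cannot
   separate the classes — and then frozen;
2. **gradient-boosted trees** score anchor pairs from the frozen
   sequence features (optionally plus raw distance in bp), trained on an
   extended dataset with many more negatives;
3. the **from-open-chromatin model** builds candidate anchors from peaks
   (merge within 3,000 bp, extend by 1,000 bp), enumerates all
   same-chromosome pairs within a span cap, and scores them genome-wide;
   an operating threshold is chosen by an F-score scan.

Scores are evaluated by the area under the precision-recall curve
(auPRC), whose baseline equals the positive-class prevalence, on
chromosome-holdout splits (random pair splits leak anchor sequence
between folds). Interpretation utilities convert first-layer kernels to
position weight matrices, match them against motif databases
(MEME/JASPAR formats), and quantify the convergent-orientation
importance signature expected at CTCF-anchored loops: important sequence
features sit on opposite strands of the two anchors, facing each other.
Cohort utilities compare predicted interaction sets across samples
(conservation profiles, Fisher-exact differential interactions, promoter
interaction fold changes).

A synthetic data generator with planted convergent motifs emulates every
input the pipeline consumes (genome FASTA, peak BED, loop BEDPE,
bedGraph tracks, multi-sample cohorts), so the whole framework is
testable end to end without external downloads.

## Worked example

Simulate a small study (four 2-Mb chromosomes, 400 planted convergent
loops), train stages 1–2, and interrogate what was learned:

```r
library(seqloop)

cfg <- sim_config(chroms = setNames(rep(2e6, 4), paste0("chr", 1:4)),
                  n_regions = 2000, n_positives = 400,
                  dist_meanlog = log(5e4), seed = 7)
study <- simulate_loop_study(cfg)

dm <- dataset_tier(study$pairs, "matched")
sp <- split_by_chromosome(dm, test = "chr4", validation = "chr3")

extractor <- build_extractor(input_length = 500, n_kernels1 = 32, width1 = 19,
                             pool = 10, n_kernels2 = 16, width2 = 11,
                             hidden = 64, seed = 7)
extractor <- freeze(train_stage1(extractor, sp$train, sp$validation,
                                 study$genome, epochs = 12, patience = 12,
                                 seed = 7))
print(extractor)
#> Sequence feature extractor (loop_extractor)
#>   input length       500 bp
#>   conv layer 1       32 kernels x 19 bp
#>   max pooling        width 10
#>   conv layer 2       16 kernels x 11 bp
#>   pair feature dim   64 (4 blocks x 16 kernels)
#>   trained: yes (best epoch 12)   frozen: yes

feats <- featurize_pairs(extractor, sp$train, study$genome)
gb <- train_gb(feats, sp$train$label, stage = "extended", seed = 7)
scores <- predict(gb, featurize_pairs(extractor, sp$test, study$genome))
ev <- auprc(scores, sp$test$label)
#> held-out auPRC: 0.577 (prevalence 0.167)
```

The held-out chromosome auPRC (0.577) is ~3.5x the prevalence baseline
(0.167) on this deliberately small run; the full-scale study in the test
suite (2,000 loops on a 64-Mb genome) reaches auPRC ≈ 0.87. The
first-layer kernels recover the planted motif:

```r
pwms <- kernels_to_pwms(extractor, probes, layer = "first")
#> best kernel-PWM match to the planted motif: r = 0.87
#> planted consensus:  TGGCCACCAGGGGGCGCTA
#> learned consensus:  GCGTGGCCACCAGGGGGCG
```

and the stage-2 importances show the convergent pattern — cross-strand
block correlations exceed same-strand ones:

```r
cv <- convergence_analysis(feature_importance_report(gb))
#>   left_F  left_RC  right_F right_RC
#>   0.0062   0.0245   0.0160   0.0159
#>    LF_RF   LF_RRC   LRC_RF  LRC_RRC
#>   -0.322    0.061    0.163   -0.199
#> convergent: TRUE
```

(The mean importance per block is low because importances are spread
over 64 features; the flag compares the convergent block combinations
and their correlations.)

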