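# Shared fixtures. The heavy ones (full-scale study with a trained
# extractor) are memoized so the whole suite trains once.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# The architecture used for all synthetic studies in this suite.
study_extractor <- function(seed = 13L) {
  build_extractor(input_length = 500L, n_kernels1 = 32L, width1 = 19L,
                  pool = 10L, n_kernels2 = 16L, width2 = 11L, hidden = 64L,
                  seed = seed)
}

# Small study for fast unit tests (no extractor training).
small_study <- function() {
  memo_fixture("small_study", {
    cfg <- sim_config(chroms = stats::setNames(rep(2e6, 4), paste0("chr", 1:4)),
                      n_regions = 2000L, n_positives = 400L, ratio = 5L,
                      ratio_extended = 10L, dist_meanlog = log(5e4), seed = 7L)
    st <- simulate_loop_study(cfg)
    st$config <- cfg
    st
  })
}

# Full-scale study under the headline conditions (2,000 positive loops,
# 500 bp anchors, embedding probability 0.9, seed 13) with the trained,
# frozen extractor and the stage-2 classifier.
acceptance_study <- function() {
  memo_fixture("acceptance_study", {
    cfg <- sim_config(seed = 13L)
    st <- simulate_loop_study(cfg)
    dm <- dataset_tier(st$pairs, "matched")
    ext <- dataset_tier(st$pairs, "extended")
    sp <- split_by_chromosome(dm)
    spe <- split_by_chromosome(ext)
    ex <- study_extractor(seed = 13L)
    ex <- train_stage1(ex, sp$train, sp$validation, st$genome,
                       epochs = 20L, patience = 5L, seed = 13L)
    ex <- freeze(ex)
    ftr <- featurize_pairs(ex, spe$train, st$genome)
    fva <- featurize_pairs(ex, spe$validation, st$genome)
    gb <- train_gb(ftr, spe$train$label, fva, spe$validation$label,
                   stage = "extended", seed = 13L)
    fte <- featurize_pairs(ex, sp$test, st$genome)
    test_eval <- auprc(predict(gb, fte), sp$test$label)
    list(config = cfg, study = st, dm = dm, ext = ext, split = sp,
         split_ext = spe, extractor = ex, gb = gb,
         test_auprc = test_eval$auprc, test_prevalence = test_eval$prevalence)
  })
}

# Probe sequences (positive anchors) for motif extraction on the
# full-scale study.
acceptance_probes <- function(n = 800L) {
  memo_fixture("acceptance_probes", {
    fx <- acceptance_study()
    anc <- seqloop:::positive_anchor_set(fx$study$positives)
    anc <- anc[with_seed_idx(nrow(anc), n, 99L), , drop = FALSE]
    vapply(seq_len(nrow(anc)), function(i)
      fetch_sequence(fx$study$genome, anc$chrom[i], anc$start[i], anc$end[i]),
      character(1))
  })
}

with_seed_idx <- function(n, k, seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(n, min(n, k))
}

# Null study: embedding probability 0, otherwise the same procedure.
null_study <- function() {
  memo_fixture("null_study", {
    cfg <- sim_config(chroms = stats::setNames(rep(8e6, 4), paste0("chr", 1:4)),
                      n_regions = 6000L, n_positives = 800L,
                      embed_prob = 0, background_rate = 0.1, seed = 13L)
    st <- simulate_loop_study(cfg)
    dm <- dataset_tier(st$pairs, "matched")
    sp <- split_by_chromosome(dm, test = "chr2", validation = "chr3")
    ex <- study_extractor(seed = 13L)
    ex <- train_stage1(ex, sp$train, sp$validation, st$genome,
                       epochs = 20L, patience = 5L, seed = 13L)
    ex <- freeze(ex)
    gb <- train_gb(featurize_pairs(ex, sp$train, st$genome), sp$train$label,
                   stage = "extended", seed = 13L)
    ev <- auprc(predict(gb, featurize_pairs(ex, sp$test, st$genome)),
                sp$test$label)
    list(auprc = ev$auprc, prevalence = ev$prevalence)
  })
}

# From-open study: the frozen full-scale extractor applied cross-sample
# to a lower-density study; genome-wide enumeration, scoring and
# F-score threshold selection.
from_open_study <- function() {
  memo_fixture("from_open_study", {
    fx <- acceptance_study()
    cfg <- sim_config(chroms = stats::setNames(rep(1e7, 3), paste0("chr", 1:3)),
                      n_regions = 900L, n_positives = 150L, ratio = 5L,
                      ratio_extended = 10L, seed = 29L)
    st <- simulate_loop_study(cfg)
    anchors <- build_anchors_from_open_chromatin(st$regions, 3000L, 1000L,
                                                 st$chrom_lengths)
    cand <- enumerate_and_label_pairs(anchors, st$positives, max_span = 5e5)
    spc <- split_by_chromosome(cand, test = "chr3", validation = "chr2")
    ftr <- featurize_pairs(fx$extractor, spc$train, st$genome,
                           include_distance = TRUE)
    fva <- featurize_pairs(fx$extractor, spc$validation, st$genome,
                           include_distance = TRUE)
    fte <- featurize_pairs(fx$extractor, spc$test, st$genome,
                           include_distance = TRUE)
    gb <- train_gb(ftr, spc$train$label, fva, spc$validation$label,
                   stage = "from_open", seed = 13L)
    sval <- predict(gb, fva)
    ste <- predict(gb, fte)
    thr <- f_score_threshold_scan(sval, spc$validation$label)$best_threshold
    cm <- confusion_at(ste, spc$test$label, thr)
    list(study = st, gb = gb, split = spc, threshold = thr,
         test_auprc = auprc(ste, spc$test$label)$auprc,
         test_prevalence = mean(spc$test$label == "positive"),
         recovery = cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]),
         fdr = cm[["FP"]] / (cm[["TP"]] + cm[["FP"]]))
  })
}

# Random DNA string.
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Tiny extractor config for unit tests.
tiny_extractor <- function(seed = 1L, L = 60L) {
  build_extractor(input_length = L, n_kernels1 = 4L, width1 = 5L, pool = 3L,
                  n_kernels2 = 3L, width2 = 4L, hidden = 8L, seed = seed)
}
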