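# Gradient-boosted classifiers, importance mapping, and the genome-wide
# from-open-chromatin predictor.

sep_toy <- function(n = 20) {
  x <- matrix(c(rep(1, n / 2), rep(-1, n / 2), rnorm(n)), n, 2,
              dimnames = list(NULL, c("sig", "noise")))
  list(x = x, y = as.integer(x[, 1] > 0))
}

test_that("GB training separates separable data and validates inputs", {
  set.seed(1)
  toy <- sep_toy()
  gb <- train_gb(toy$x, toy$y, stage = "functional", nrounds = 30, seed = 1)
  expect_equal(auprc(predict(gb, toy$x), toy$y)$auprc, 1)
  bad <- toy$x; bad[3, 2] <- NaN
  expect_error(train_gb(bad, toy$y, stage = "functional"), "noise")
  expect_error(train_gb(toy$x, rep(1, 20), stage = "functional"),
               "single class")
  gb2 <- train_gb(toy$x, toy$y, stage = "functional", nrounds = 30, seed = 1)
  expect_identical(predict(gb, toy$x), predict(gb2, toy$x))
})

test_that("GB on permuted labels stays at the prevalence baseline", {
  set.seed(44)
  x <- matrix(rnorm(3000), 300, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- sample(c(rep(1, 60), rep(0, 240)))
  xt <- matrix(rnorm(3000), 300, 10, dimnames = list(NULL, paste0("f", 1:10)))
  yt <- sample(c(rep(1, 60), rep(0, 240)))
  gb <- train_gb(x, y, stage = "functional", nrounds = 100, seed = 2)
  a <- auprc(predict(gb, xt), yt)
  expect_lt(abs(a$auprc - a$prevalence), 0.1)
})

test_that("pair scoring is manifest-checked and batch-order invariant", {
  st <- small_study()
  ex <- freeze(study_extractor(seed = 3))
  dmfull <- dataset_tier(st$pairs, "matched")
  dm <- rbind(dmfull[dmfull$label == "positive", ][1:20, ],
              dmfull[dmfull$label == "negative", ][1:60, ])
  f <- featurize_pairs(ex, dm, st$genome)
  gb <- train_gb(f, dm$label, stage = "extended", nrounds = 20, seed = 1)
  scored <- predict_pairs(gb, ex, dm, st$genome)
  expect_equal(scored$score, predict(gb, f))
  shuf <- sample(nrow(dm))
  scored2 <- predict_pairs(gb, ex, dm[shuf, ], st$genome)
  expect_equal(scored2$score, scored$score[shuf])
  fd <- featurize_pairs(ex, dm, st$genome, include_distance = TRUE)
  expect_error(predict(gb, fd), "manifest mismatch")
})

test_that("importance report covers every feature with block mapping", {
  st <- small_study()
  dm <- dataset_tier(st$pairs, "matched")
  dm <- rbind(dm[dm$label == "positive", ][1:25, ],
              dm[dm$label == "negative", ][1:100, ])
  dt <- assemble_feature_table(dm, feature_mode = "distance_only")
  gbd <- train_gb(dt$features, dt$labels, stage = "functional",
                  nrounds = 20, seed = 1)
  rep_d <- feature_importance_report(gbd)
  expect_equal(nrow(rep_d), 1L)
  expect_equal(rep_d$block, "distance")

  ex <- freeze(study_extractor(seed = 3))
  f <- featurize_pairs(ex, dm[1:100, ], st$genome, include_distance = TRUE)
  gb <- train_gb(f, dm$label[1:100], stage = "extended", nrounds = 30, seed = 1)
  imp <- feature_importance_report(gb)
  expect_equal(nrow(imp), ncol(f))
  expect_gt(sum(imp$importance), 0)
  expect_setequal(unique(imp$block),
                  c("left_F", "left_RC", "right_F", "right_RC", "distance"))
  expect_equal(sum(is.na(imp$kernel)), 1L)  # only distance is unmapped
})

test_that("adding distance never hurts training-set auPRC", {
  st <- small_study()
  dm <- dataset_tier(st$pairs, "matched")
  sp <- split_by_chromosome(dm, test = "chr4", validation = character(0))
  ex <- freeze(study_extractor(seed = 3))
  f0 <- featurize_pairs(ex, sp$train, st$genome, include_distance = FALSE)
  f1 <- featurize_pairs(ex, sp$train, st$genome, include_distance = TRUE)
  # subsample = 1: exact greedy boosting, so the extra feature is only
  # used where it improves the objective
  gb0 <- train_gb(f0, sp$train$label, stage = "extended", nrounds = 60,
                  subsample = 1, seed = 1)
  gb1 <- train_gb(f1, sp$train$label, stage = "extended", nrounds = 60,
                  subsample = 1, seed = 1)
  a0 <- auprc(predict(gb0, f0), sp$train$label)$auprc
  a1 <- auprc(predict(gb1, f1), sp$train$label)$auprc
  # near-equality: greedy finite-depth fitting makes this approximate even
  # though boosting can in principle ignore an uninformative feature
  expect_gte(a1, a0 - 0.005)
})

test_that("from-open pipeline recovers planted loops far above chance", {
  fo <- from_open_study()
  # well above the random baseline: the from-open regime yields a small
  # auPRC that is nonetheless a large multiple of prevalence
  expect_gt(fo$test_auprc, 5 * fo$test_prevalence)
  expect_gte(fo$recovery, 0.15)
  expect_lte(fo$fdr, 0.92)
  # stage-2 style invariant: auPRC beats prevalence on the extended tier
  expect_gt(fo$test_auprc, fo$test_prevalence)
})

test_that("predict_from_open_chromatin emits scored BEDPE-ready pairs", {
  fo <- from_open_study()
  fx <- acceptance_study()
  peaks <- fo$study$regions[fo$study$regions$chrom == "chr3", ][1:60, ]
  pred <- predict_from_open_chromatin(peaks, fo$study$genome, fx$extractor,
                                      fo$gb, max_span = 5e5,
                                      threshold = fo$threshold,
                                      include_distance = TRUE)
  expect_true(all(c("score", "predicted") %in% names(pred)))
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  # the scored pair set equals the enumeration of the built anchors
  anchors <- build_anchors_from_open_chromatin(peaks, 3000, 1000,
                                               fo$study$chrom_lengths)
  cand <- enumerate_and_label_pairs(anchors,
                                    anchor_pairs(character(), integer(),
                                                 integer(), character(),
                                                 integer(), integer()),
                                    max_span = 5e5)
  expect_equal(seqloop:::pair_key(pred), seqloop:::pair_key(cand))
  # a threshold above 1 predicts nothing
  pred2 <- predict_from_open_chromatin(peaks, fo$study$genome, fx$extractor,
                                       fo$gb, max_span = 5e5,
                                       threshold = 1 + 1e-9,
                                       include_distance = TRUE)
  expect_equal(sum(pred2$predicted), 0L)
  # empty peak set yields an empty result
  empty <- predict_from_open_chromatin(peaks[0, ], fo$study$genome,
                                       fx$extractor, fo$gb)
  expect_equal(nrow(empty), 0L)
  # model file round trip preserves scores
  path <- tempfile(fileext = ".json")
  save_gb_model(fo$gb, path)
  gb2 <- load_gb_model(path)
  f <- featurize_pairs(fx$extractor, fo$split$test[1:20, ], fo$study$genome,
                       include_distance = TRUE)
  expect_equal(predict(gb2, f), predict(fo$gb, f), tolerance = 1e-12)
})
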