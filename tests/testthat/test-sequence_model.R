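# One-hot encoding, extractor construction, feature extraction and
# stage-1 training mechanics.

test_that("one-hot encoding centers, pads and zeroes N", {
  m <- one_hot_encode("ACGT", 4)
  expect_equal(m, diag(4), ignore_attr = TRUE)
  p <- one_hot_encode("AC", 4)
  expect_equal(rowSums(p), c(0, 1, 1, 0))
  expect_equal(unname(p[2, "A"]), 1)
  expect_equal(one_hot_encode("N", 1), matrix(0, 1, 4), ignore_attr = TRUE)
  # center crop of a longer sequence
  cr <- one_hot_encode("GGACGTGG", 4)
  expect_equal(cr, diag(4), ignore_attr = TRUE)
  expect_true(all(rowSums(one_hot_encode("ANGT", 4)) %in% c(0, 1)))
})

test_that("extractor construction is seeded and validates its geometry", {
  e1 <- tiny_extractor(seed = 4)
  e2 <- tiny_extractor(seed = 4)
  expect_identical(e1$params, e2$params)
  e3 <- tiny_extractor(seed = 5)
  expect_false(identical(e1$params, e3$params))
  expect_error(build_extractor(input_length = 20, n_kernels1 = 4, width1 = 5,
                               pool = 4, n_kernels2 = 3, width2 = 10),
               "spatial size")
})

test_that("pair features are four blocks and orientation-equivariant", {
  ex <- tiny_extractor()
  s <- random_dna(60, seed = 1)
  t <- random_dna(60, seed = 2)
  f <- extract_pair_features(ex, s, t)
  k2 <- ex$config$n_kernels2
  expect_equal(ncol(f), 4 * k2)
  expect_true(all(is.finite(f)))
  # replacing the left sequence by its reverse complement swaps the left
  # F/RC blocks and leaves the right blocks untouched
  f2 <- extract_pair_features(ex, reverse_complement(s), t)
  expect_equal(f2[1, 1:k2], f[1, (k2 + 1):(2 * k2)], ignore_attr = TRUE)
  expect_equal(f2[1, (k2 + 1):(2 * k2)], f[1, 1:k2], ignore_attr = TRUE)
  expect_equal(f2[1, (2 * k2 + 1):(4 * k2)], f[1, (2 * k2 + 1):(4 * k2)])
  # full RC of both sides is a block permutation
  f3 <- extract_pair_features(ex, reverse_complement(s), reverse_complement(t))
  perm <- c((k2 + 1):(2 * k2), 1:k2, (3 * k2 + 1):(4 * k2), (2 * k2 + 1):(3 * k2))
  expect_equal(unname(f3[1, ]), unname(f[1, perm]))
  # global pooling: doubling L leaves the feature dimension unchanged
  ex2 <- tiny_extractor(L = 120)
  expect_equal(ncol(extract_pair_features(ex2, random_dna(120), random_dna(120))),
               4 * k2)
})

test_that("extractor features match a plain-R sliding-window oracle", {
  ex <- tiny_extractor(seed = 9)
  set.seed(33)
  for (rep in 1:10) {
    s <- random_dna(60)
    codes <- seqloop:::seq_to_codes(s, 60)
    want <- oracle_forward_features(codes, ex$params, ex$config)
    got <- seqloop:::cpp_extract_features(matrix(codes, ncol = 1),
                                          ex$params, ex$config, FALSE)
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
  }
})

test_that("kernel responses are invariant to motif shifts of one pool stride", {
  ex <- tiny_extractor(L = 90)
  base <- strrep("A", 90)
  motif <- "GCGTTGCC"
  plant <- function(at) {
    s <- base
    substr(s, at, at + nchar(motif) - 1) <- motif
    s
  }
  f1 <- extract_pair_features(ex, plant(30), base)
  f2 <- extract_pair_features(ex, plant(30 + ex$config$pool), base)
  expect_lt(max(abs(f1[1, 1:ex$config$n_kernels2] -
                      f2[1, 1:ex$config$n_kernels2])), 1e-6)
})

test_that("stage-1 training is reproducible, freezable and logged", {
  st <- small_study()
  dm <- dataset_tier(st$pairs, "matched")
  sp <- split_by_chromosome(dm, test = "chr4", validation = "chr3")
  tr <- rbind(sp$train[sp$train$label == "positive", ][1:30, ],
              sp$train[sp$train$label == "negative", ][1:90, ])
  ex <- build_extractor(input_length = 500, n_kernels1 = 8, width1 = 19,
                        pool = 10, n_kernels2 = 4, width2 = 11, hidden = 16,
                        seed = 2)
  va <- rbind(sp$validation[sp$validation$label == "positive", ][1:15, ],
              sp$validation[sp$validation$label == "negative", ][1:45, ])
  fit1 <- train_stage1(ex, tr, va, st$genome,
                       epochs = 2, patience = 5, seed = 11)
  fit2 <- train_stage1(ex, tr, va, st$genome,
                       epochs = 2, patience = 5, seed = 11)
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$log, fit2$log)
  expect_equal(nrow(fit1$log), 2L)
  expect_true(all(c("epoch", "train_loss", "val_auprc") %in% names(fit1$log)))
  # single-class training set refused
  tr_pos <- tr[tr$label == "positive", ]
  expect_error(train_stage1(ex, tr_pos, va, st$genome),
               "both classes")
  # freezing makes parameters immutable and later stages leave them intact
  fz <- freeze(fit1)
  expect_error(train_stage1(fz, tr, va, st$genome), "frozen")
  before <- fz$params
  f <- featurize_pairs(fz, tr, st$genome)
  gb <- train_gb(f, tr$label, stage = "extended", nrounds = 30, seed = 1)
  expect_identical(fz$params, before)
  expect_identical(unname(featurize_pairs(fz, tr[1:5, ], st$genome)[, ]),
                   unname(f[1:5, , drop = FALSE][, ]))
  expect_s3_class(gb, "loop_gb")
})

test_that("checkpoints round-trip the extractor at full precision", {
  ex <- tiny_extractor(seed = 8)
  path <- tempfile(fileext = ".json")
  save_extractor(ex, path)
  ex2 <- load_extractor(path)
  expect_equal(ex2$params, ex$params, tolerance = 0)
  expect_equal(ex2$config, ex$config)
  s <- random_dna(60, seed = 3)
  expect_identical(extract_pair_features(ex, s, s),
                   extract_pair_features(ex2, s, s))
})
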