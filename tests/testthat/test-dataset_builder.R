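# Dataset tiers: positive extraction, distance-matched and extended
# negative sampling, anchor construction, pair enumeration, splits.

make_loops <- function(n, chroms = c("chr1", "chr2"), seed = 3) {
  set.seed(seed)
  ch <- sample(chroms, n, replace = TRUE)
  s1 <- sample(0:1e6, n)
  s2 <- s1 + sample(5e3:2e5, n)
  anchor_pairs(ch, s1, s1 + 1000, ch, s2, s2 + 1000)
}

test_that("positive extraction drops inter-chromosomal loops and filters by open regions", {
  loops <- anchor_pairs(c("chr1", "chr1"), c(100, 100), c(200, 200),
                        c("chr1", "chr2"), c(5000, 5000), c(6000, 6000))
  pos <- extract_positive_pairs(loops)
  expect_equal(nrow(pos), 1L)
  expect_equal(pos$label, "positive")

  open <- genomic_intervals(c("chr1", "chr1"), c(150, 5500), c(180, 5600))
  pos2 <- extract_positive_pairs(loops, open)
  expect_equal(nrow(pos2), 1L)
  # left anchor misses all open regions -> dropped
  open_miss <- genomic_intervals("chr1", 5500, 5600)
  expect_warning(pos3 <- extract_positive_pairs(loops, open_miss),
                 "no positive pairs")
  expect_equal(nrow(pos3), 0L)

  # duplicates collapse
  dup <- rbind(loops[1, ], loops[1, ])
  expect_equal(nrow(extract_positive_pairs(dup)), 1L)
})

test_that("positive extraction agrees with a brute-force overlap filter", {
  set.seed(9)
  loops <- make_loops(500)
  open <- genomic_intervals(sample(c("chr1", "chr2"), 300, replace = TRUE),
                            s <- sample(0:1.2e6, 300), s + 400)
  got <- extract_positive_pairs(loops, open)
  ov <- function(ch, s1, e1) {
    any(open$chrom == ch & pmin(e1, open$end) - pmax(s1, open$start) >= 1)
  }
  keep <- vapply(seq_len(nrow(loops)), function(i) {
    ov(loops$chrom1[i], loops$start1[i], loops$end1[i]) &&
      ov(loops$chrom2[i], loops$start2[i], loops$end2[i])
  }, logical(1))
  want <- loops[keep & !loops$inter_chrom, ]
  want <- want[!duplicated(seqloop:::pair_key(want)), ]
  expect_setequal(seqloop:::pair_key(got), seqloop:::pair_key(want))
})

test_that("distance-matched sampler hits the target ratio with matched distances", {
  # synthetic positives: 5,000 pairs over 16 chromosomes, log-normal spans
  set.seed(21)
  n <- 5000
  ch <- sample(paste0("chr", 1:8), n, replace = TRUE)
  s1 <- sample(0:5e7, n)
  d <- round(pmin(pmax(rlnorm(n, log(1e5), 0.8), 1e4), 2e6))
  pos <- anchor_pairs(ch, s1, s1 + 500, ch, s1 + d, s1 + d + 500)
  pos$label <- "positive"
  neg <- suppressWarnings(
    sample_distance_matched_negatives(pos, ratio = 5L, seed = 4L))
  expect_true(all(neg$label == "negative"))
  r <- nrow(neg) / nrow(pos)
  expect_gte(r, 4.5)
  expect_lte(r, 5.5)
  # no negative equals a positive
  expect_length(intersect(seqloop:::pair_key(neg), seqloop:::pair_key(pos)), 0)
  # distance distributions match
  ks <- suppressWarnings(ks.test(log10(pos$distance), log10(neg$distance)))
  expect_lt(unname(ks$statistic), 0.05)
  # determinism
  neg2 <- suppressWarnings(
    sample_distance_matched_negatives(pos, ratio = 5L, seed = 4L))
  expect_identical(neg, neg2)
})

test_that("extended negatives are plentiful, positive-free and deterministic", {
  pos <- make_loops(200, seed = 5)
  pos$label <- "positive"
  neg <- suppressWarnings(build_extended_negatives(pos, 25L, seed = 2L))
  expect_gte(nrow(neg), 0.9 * 25 * nrow(pos))
  expect_length(intersect(seqloop:::pair_key(neg), seqloop:::pair_key(pos)), 0)
  expect_identical(neg,
                   suppressWarnings(build_extended_negatives(pos, 25L, seed = 2L)))
  rng <- range(pos$distance)
  expect_true(all(neg$distance >= rng[1] & neg$distance <= rng[2]))
})

test_that("anchors from open chromatin reduce to merge-and-extend", {
  peaks <- genomic_intervals(rep("chr1", 3), c(100, 2000, 20000),
                             c(600, 2500, 20500))
  a <- build_anchors_from_open_chromatin(peaks, 3000, 1000,
                                         c(chr1 = 1e6))
  expect_equal(nrow(a), 2L)           # first two merge (gap 1400 <= 3000)
  expect_equal(a$start[1], 0L)        # extension clamps at 0
  ident <- build_anchors_from_open_chromatin(peaks, 0, 0)
  expect_equal(ident[, c("chrom", "start", "end")],
               peaks[, c("chrom", "start", "end")], ignore_attr = TRUE)
})

test_that("pair enumeration and labeling match the brute-force oracle", {
  anchors <- genomic_intervals(rep("chr1", 3), c(0, 5000, 9000),
                               c(1000, 6000, 10000))
  loops <- anchor_pairs("chr1", 100, 900, "chr1", 9100, 9900)
  pairs <- enumerate_and_label_pairs(anchors, loops, max_span = 1e9)
  expect_equal(nrow(pairs), 3L)  # C(3,2)
  expect_equal(sum(pairs$label == "positive"), 1L)
  # one-anchor-only match stays negative
  lab01 <- pairs$label[pairs$start2 == 5000]
  expect_equal(lab01, "negative")

  set.seed(31)
  for (rep in 1:6) {
    n <- sample(30:120, 1)
    anc <- genomic_intervals(sample(c("c1", "c2"), n, replace = TRUE),
                             s <- sample(seq(0, 3e5, by = 700), n), s + 500)
    anc <- anc[!duplicated(paste(anc$chrom, anc$start)), ]
    lp <- make_loops(15, chroms = c("c1", "c2"), seed = rep)
    lp$start1 <- lp$start1 %% 250000L; lp$end1 <- lp$start1 + 2000L
    lp$start2 <- lp$start1 + sample(3e3:5e4, nrow(lp)); lp$end2 <- lp$start2 + 2000L
    got <- enumerate_and_label_pairs(anc, lp, max_span = 5e4)
    want <- oracle_enumerate_label(anc, lp, max_span = 5e4)
    key <- function(df) paste(df$chrom1, df$start1, df$start2, df$label)
    expect_setequal(key(got), key(want))
  }
})

test_that("chromosome holdout splits partition pairs without leakage", {
  pairs <- make_loops(100, chroms = c("chr1", "chr2", "chr5"))
  sp <- split_by_chromosome(pairs, test = "chr5", validation = "chr2")
  expect_equal(nrow(sp$train) + nrow(sp$validation) + nrow(sp$test),
               nrow(pairs))
  expect_true(all(sp$test$chrom1 == "chr5"))
  expect_true(all(sp$train$chrom1 == "chr1"))
  expect_length(intersect(seqloop:::pair_key(sp$train),
                          seqloop:::pair_key(sp$test)), 0)
  # two-way split with empty validation
  sp2 <- split_by_chromosome(pairs, test = "chr5", validation = character(0))
  expect_equal(nrow(sp2$validation), 0L)
  # explicit train set leaving a chromosome unassigned is an error
  expect_error(split_by_chromosome(pairs, test = "chr5",
                                   validation = "chr2", train = "chr9"),
               "not assigned")
})
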