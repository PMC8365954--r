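# Cohort statistics: presence matrices, conservation, Fisher-exact
# differential interactions, anchor attribution, IFC.

toy_cohort <- function() {
  # 3 interactions over a 4-anchor universe, 2 samples sharing one pair
  universe <- genomic_intervals(rep("chr1", 4),
                                c(0, 1000, 2000, 3000),
                                c(500, 1500, 2500, 3500))
  p1 <- anchor_pairs(rep("chr1", 2), c(0, 1000), c(500, 1500),
                     rep("chr1", 2), c(2000, 3000), c(2500, 3500))
  p1$score <- c(0.9, 0.8)
  p2 <- anchor_pairs(rep("chr1", 2), c(0, 2000), c(500, 2500),
                     rep("chr1", 2), c(2000, 3000), c(2500, 3500))
  p2$score <- c(0.7, 0.95)
  list(universe = universe, preds = list(s1 = p1, s2 = p2))
}

test_that("presence matrix is built over the pooled universe", {
  tc <- toy_cohort()
  m <- build_presence_matrix(tc$preds, tc$universe, thresholds = 0.5)
  expect_equal(dim(m), c(3L, 2L))
  shared <- seqloop:::pair_key(tc$preds$s1)[1]
  expect_equal(unname(m[shared, ]), c(1L, 1L))
  expect_equal(sum(m), 4L)
  # identical samples give identical columns
  m2 <- build_presence_matrix(list(a = tc$preds$s1, b = tc$preds$s1),
                              tc$universe)
  expect_equal(unname(m2[, 1]), unname(m2[, 2]))
  # anchor outside the universe is an error
  stray <- tc$preds
  stray$s1$start1[1] <- 99L
  expect_error(build_presence_matrix(stray, tc$universe), "outside")
})

test_that("conservation profile is the row-sum histogram", {
  m <- matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE)
  pr <- conservation_profile(m)
  expect_equal(sum(pr), 1)
  expect_equal(unname(pr), c(1, 1, 1) / 3)
  all1 <- matrix(1, 5, 4)
  expect_equal(unname(conservation_profile(all1)), c(0, 0, 0, 1))
  # every interaction private to one sample
  priv <- diag(1, 6)
  expect_equal(unname(conservation_profile(priv))[1], 1)
  set.seed(50)
  rm <- matrix(rbinom(200, 1, 0.4), 40, 5)
  rm <- rm[rowSums(rm) > 0, ]
  expect_equal(unname(conservation_profile(rm)),
               unname(tabulate(rowSums(rm), 5) / nrow(rm)))
})

test_that("Fisher differential tests match exhaustive enumeration", {
  # presence 2/2 in A vs 0/4 in B -> p = 1/15
  m <- matrix(c(1, 1, 0, 0, 0, 0), 1, 6)
  colnames(m) <- paste0("s", 1:6)
  rownames(m) <- "chr1:0:10:chr1:100:110"
  groups <- c(rep("uCLL", 2), rep("mCLL", 4))
  res <- differential_interactions(m, groups)
  expect_equal(res$p_value, 1 / 15)
  expect_equal(res$direction, "uCLL")
  # equal rates give p = 1
  m2 <- matrix(c(1, 0, 1, 0, 1, 0), 1, 6, dimnames = dimnames(m))
  expect_equal(differential_interactions(m2, groups)$p_value, 1)
  # degenerate rows are flagged with p = 1
  m3 <- matrix(1, 1, 6, dimnames = dimnames(m))
  r3 <- differential_interactions(m3, groups)
  expect_true(r3$degenerate)
  expect_equal(r3$p_value, 1)
  # group relabeling symmetry (swap the two labels)
  swapped <- ifelse(groups == "uCLL", "mCLL", "uCLL")
  expect_equal(differential_interactions(m, swapped)$p_value, res$p_value)

  set.seed(60)
  nm <- matrix(rbinom(6000, 1, runif(1000, 0.1, 0.9)), 1000, 6)
  rownames(nm) <- paste0("k", 1:1000, ":0:1:k:2:3")
  colnames(nm) <- paste0("s", 1:6)
  got <- differential_interactions(nm, groups)
  for (i in seq_len(nrow(nm))) {
    if (got$degenerate[i]) next
    want <- oracle_fisher2x2(got$present_A[i], got$absent_A[i],
                             got$present_B[i], got$absent_B[i])
    expect_equal(got$p_value[i], want, tolerance = 1e-12)
  }
  # BH adjustment is monotone in raw p
  ord <- order(got$p_value)
  expect_true(all(diff(got$p_adj[ord]) >= -1e-12))
  expect_true(all(got$p_adj >= got$p_value - 1e-12))
})

test_that("anchor attribution partitions differential interactions", {
  # construct: interaction 1 differential with both anchors differential,
  # interaction 2 differential with neither anchor differential
  groups <- c(rep("A", 5), rep("B", 5))
  ints <- matrix(c(rep(1, 5), rep(0, 5),
                   rep(1, 5), rep(0, 5)), 2, 10, byrow = TRUE)
  rownames(ints) <- c("c:0:10:c:100:110", "c:200:210:c:300:310")
  colnames(ints) <- paste0("s", 1:10)
  anchors <- rbind("c 0 10" = c(rep(1, 5), rep(0, 5)),
                   "c 100 110" = c(rep(1, 5), rep(0, 5)),
                   "c 200 210" = rep(1, 10),
                   "c 300 310" = rep(c(1, 0), 5))
  colnames(anchors) <- paste0("s", 1:10)
  diff <- differential_interactions(ints, groups)
  att <- anchor_change_attribution(diff, anchors, groups, alpha = 0.05)
  expect_equal(sum(att$counts), nrow(diff[diff$p_adj <= 0.05 &
                                            !diff$degenerate, ]))
  expect_equal(unname(att$counts["both"]), 1L)
  expect_equal(unname(att$counts["neither"]), 1L)
})

test_that("IFC is the ratio of mean promoter interaction counts", {
  tc <- toy_cohort()
  m <- build_presence_matrix(tc$preds, tc$universe)
  # promoter overlapping the first anchor touches interactions 1 and 3
  prom <- genomic_intervals(c("chr1", "chr1"), c(0, 900000), c(100, 900100),
                            name = c("gene1", "far_gene"))
  expect_message(res <- ifc_score(prom, m, groups = c("A", "B")),
                 "excluded")
  expect_equal(res$excluded, "far_gene")
  tab <- res$table
  # hand computation
  coords <- attr(m, "pairs")
  touch <- which(coords$start1 == 0)
  counts <- colSums(m[touch, , drop = FALSE])
  expect_equal(tab$ifc, unname(counts[1] / counts[2]))
  # undefined on zero denominator
  m0 <- m; m0[, 2] <- 0L
  attr(m0, "pairs") <- coords
  r0 <- ifc_score(prom[1, ], m0, groups = c("A", "B"))
  expect_true(r0$table$undefined)
  expect_true(is.na(r0$table$ifc))
})

test_that("planted differential interactions rank top in a simulated cohort", {
  st <- small_study()
  co <- simulate_signal_tracks(
    sim_config(chroms = st$config$chroms, n_regions = st$config$n_regions,
               n_positives = st$config$n_positives,
               presence_high = 0.95, presence_low = 0.05, seed = 7),
    st$regions, st$positives)
  diff <- differential_interactions(co$presence, co$groups)
  # enrichment of planted differentials among smallest p-values
  top <- order(diff$p_value)[seq_len(sum(co$differential))]
  frac_planted_top <- mean(co$differential[top])
  expect_gt(frac_planted_top, 2 * mean(co$differential))
  # fold 1.0 means no anchor enrichment in tracks
  flat <- simulate_signal_tracks(
    sim_config(chroms = st$config$chroms, n_regions = st$config$n_regions,
               n_positives = st$config$n_positives, signal_fold = 1,
               seed = 7),
    st$regions, st$positives)
  v <- flat$tracks[[1]]$value
  akeys <- unique(c(paste(st$positives$chrom1, st$positives$start1),
                    paste(st$positives$chrom2, st$positives$start2)))
  is_anchor <- paste(flat$tracks[[1]]$chrom, flat$tracks[[1]]$start) %in% akeys
  expect_lt(abs(mean(v[is_anchor]) - mean(v[!is_anchor])), 0.1)
})
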