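# Kernel-to-PWM extraction, motif database matching, detection counts,
# convergence analysis.

toy_db <- function() {
  set.seed(14)
  mk <- function(name, w) {
    m <- matrix(runif(w * 4), w, 4)
    pwm(m / rowSums(m), name = name, source = "database")
  }
  db <- list(mk("M_A", 10), mk("M_B", 12), planted_motif_pwm())
  names(db) <- vapply(db, `[[`, character(1), "name")
  db
}

test_that("PWM construction validates rows and computes consensus", {
  m <- matrix(c(0.7, 0.1, 0.1, 0.1,
                0.05, 0.85, 0.05, 0.05), 2, 4, byrow = TRUE)
  p <- pwm(m, "x")
  expect_equal(pwm_consensus(p), "AC")
  expect_error(pwm(m * 2, "x"), "sum to 1")
  expect_error(pwm(m[, 1:3], "x"), "4 columns")
  rc <- seqloop:::pwm_rc(p)
  expect_equal(pwm_consensus(rc), "GT")
})

test_that("MEME and JASPAR files round-trip PWMs", {
  db <- toy_db()
  f <- tempfile(fileext = ".meme")
  write_meme(db, f)
  back <- read_meme(f)
  expect_equal(names(back), names(db))
  expect_equal(back$planted$mat, db$planted$mat, tolerance = 1e-5)

  jf <- tempfile(fileext = ".pfm")
  counts <- round(db$M_A$mat * 100)
  writeLines(c(">MA0001.1 M_A",
               paste("A [", paste(counts[, 1], collapse = " "), "]"),
               paste("C [", paste(counts[, 2], collapse = " "), "]"),
               paste("G [", paste(counts[, 3], collapse = " "), "]"),
               paste("T [", paste(counts[, 4], collapse = " "), "]")), jf)
  jb <- read_jaspar(jf)
  expect_equal(names(jb), "MA0001.1")
  expect_equal(jb[[1]]$mat, db$M_A$mat, tolerance = 0.03)
})

test_that("a hand-set indicator kernel yields its own consensus as PWM", {
  ex <- build_extractor(input_length = 60, n_kernels1 = 3, width1 = 6,
                        pool = 3, n_kernels2 = 2, width2 = 4, hidden = 8,
                        seed = 5)
  target <- "TTAGGC"
  codes <- seqloop:::seq_to_codes(target, 6)
  W1 <- matrix(0, 3, 24)
  for (j in 1:6) {
    W1[1, (4 * (j - 1) + 1):(4 * j)] <- -1
    W1[1, 4 * (j - 1) + codes[j] + 1] <- 1
  }
  # kernel 2 stays random; kernel 3 is all-zero -> inactive
  W1[2, ] <- ex$params$W1[2, ]
  ex$params$W1 <- W1
  ex$params$b1[, 1] <- 0
  ex$trained <- TRUE
  set.seed(10)
  probes <- vapply(1:300, function(i) random_dna(80), character(1))
  # make sure the target occurs in some probes
  probes[1:30] <- vapply(probes[1:30], function(s) {
    substr(s, 20, 25) <- target; s
  }, character(1))
  pwms <- kernels_to_pwms(ex, probes, layer = "first",
                          activation_quantile = 0.9, stride = 1)
  expect_equal(pwm_consensus(pwms[[1]]), target)
  expect_null(pwms[[3]])
  # all rows of every derived PWM sum to 1
  expect_true(all(abs(rowSums(pwms[[1]]$mat) - 1) < 1e-9))
})

test_that("PWM database matching finds self-matches and respects orientation", {
  db <- toy_db()
  res <- match_pwm_to_database(db$planted, db, n_shuffles = 99, seed = 2)
  expect_equal(res$target[1], "planted")
  expect_equal(res$similarity[1], 1)
  expect_lte(res$p_value[1], 1 / 100)
  rcq <- seqloop:::pwm_rc(db$planted)
  res_rc <- match_pwm_to_database(rcq, db, n_shuffles = 99, seed = 2)
  expect_equal(res_rc$target[1], "planted")
  expect_equal(res_rc$orientation[1], "-")
  # near-uniform query matches nothing confidently
  set.seed(77)
  r <- matrix(runif(40), 10, 4)
  noisy <- pwm(0.9 * 0.25 + 0.1 * r / rowSums(r), "noisy")
  m_unif <- match_pwm_to_database(noisy, db, n_shuffles = 99, seed = 3)
  expect_true(all(m_unif$p_value > 0.05))
  short <- pwm(matrix(0.25, 4, 4), "short")
  expect_error(match_pwm_to_database(short, db), "width")
})

test_that("detection counts attribute kernels to their best motif", {
  ex <- build_extractor(input_length = 60, n_kernels1 = 2, width1 = 19,
                        pool = 3, n_kernels2 = 2, width2 = 4, hidden = 8,
                        seed = 5)
  consensus <- pwm_consensus(planted_motif_pwm())
  codes <- seqloop:::seq_to_codes(consensus, 19)
  for (j in 1:19) {
    ex$params$W1[1, (4 * (j - 1) + 1):(4 * j)] <- -1
    ex$params$W1[1, 4 * (j - 1) + codes[j] + 1] <- 1
  }
  ex$params$W1[2, ] <- 0
  ex$trained <- TRUE
  set.seed(20)
  probes <- vapply(1:200, function(i) random_dna(100), character(1))
  probes[1:60] <- vapply(probes[1:60], function(s) {
    substr(s, 30, 48) <- consensus; s
  }, character(1))
  counts <- motif_detection_counts(list(model1 = ex), toy_db(), probes,
                                   n_shuffles = 99, seed = 7)
  expect_equal(counts["planted", "model1"], 1L)
  expect_true(all(colSums(counts) <= ex$config$n_kernels1))
})

test_that("convergence analysis flags the cross-strand importance pattern", {
  k2 <- 8
  set.seed(3)
  v <- runif(k2)
  mk_imp <- function(lf, lrc, rf, rrc) {
    data.frame(feature = seqloop:::feature_names(k2),
               block = rep(c("left_F", "left_RC", "right_F", "right_RC"),
                           each = k2),
               kernel = rep(1:k2, 4),
               importance = c(lf, lrc, rf, rrc))
  }
  # convergent construction: left-F and right-RC share structure
  conv <- mk_imp(v, runif(k2) * 0.05, runif(k2) * 0.05, v * 0.9)
  res <- convergence_analysis(conv)
  expect_equal(unname(res$correlations["LF_RRC"]), 1, tolerance = 0.2)
  expect_true(res$convergent)
  expect_equal(res$orientation, "LF_RRC")
  expect_equal(res$top_kernel, which.max(v))
  # identical vectors in a pairing give correlation 1
  same <- mk_imp(v, v, v, v)
  res2 <- convergence_analysis(same)
  expect_equal(unname(res2$correlations["LF_RRC"]), 1)
  expect_false(res2$convergent)
  # all-equal importances are degenerate: NA correlations with a warning
  flat <- mk_imp(rep(1, k2), rep(1, k2), rep(1, k2), rep(1, k2))
  warns <- capture_warnings(res3 <- convergence_analysis(flat))
  expect_true(any(grepl("degenerate", warns)))
  expect_true(all(is.na(res3$correlations)))
  expect_false(res3$convergent)
  expect_error(convergence_analysis(data.frame(feature = "x", importance = 1)),
               "block mapping")
})
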