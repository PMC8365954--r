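# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive O(n^2) / enumeration
# algorithms and share no code with the implementation paths they check.

# Transitive-closure interval merging + extension, O(n^2).
oracle_merge_extend <- function(intervals, merge_distance, extension,
                                chrom_lengths = NULL) {
  out <- NULL
  for (ch in unique(intervals$chrom)) {
    df <- intervals[intervals$chrom == ch, , drop = FALSE]
    n <- nrow(df)
    grp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (grp[i] != grp[j]) {
            gap <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j])
            if (gap <= merge_distance) {
              grp[grp == grp[j]] <- grp[i]
              changed <- TRUE
            }
          }
        }
      }
      if (!changed) break
    }
    for (g in unique(grp)) {
      s <- max(0L, min(df$start[grp == g]) - extension)
      e <- max(df$end[grp == g]) + extension
      if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
        e <- min(e, chrom_lengths[[ch]])
      }
      out <- rbind(out, data.frame(chrom = ch, start = s, end = e,
                                   stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All-thresholds average precision by direct enumeration.
oracle_auprc <- function(scores, labels) {
  y <- as.integer(labels != 0)
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & y == 1)
    fp <- sum(pred & y == 0)
    rec <- tp / sum(y == 1)
    prec <- tp / (tp + fp)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# Pair enumeration + both-anchor labeling by double loop.
oracle_enumerate_label <- function(anchors, loops, max_span, min_overlap = 1L) {
  res <- NULL
  ov <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))
  for (ch in unique(anchors$chrom)) {
    a <- anchors[anchors$chrom == ch, , drop = FALSE]
    a <- a[order(a$start, a$end), , drop = FALSE]
    n <- nrow(a)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- abs((a$start[j] + a$end[j]) %/% 2 - (a$start[i] + a$end[i]) %/% 2)
        if (d > max_span) next
        lab <- "negative"
        for (k in seq_len(nrow(loops))) {
          if (loops$chrom1[k] != ch) next
          i_hits_1 <- ov(a$start[i], a$end[i], loops$start1[k], loops$end1[k]) >= min_overlap
          i_hits_2 <- ov(a$start[i], a$end[i], loops$start2[k], loops$end2[k]) >= min_overlap
          j_hits_1 <- ov(a$start[j], a$end[j], loops$start1[k], loops$end1[k]) >= min_overlap
          j_hits_2 <- ov(a$start[j], a$end[j], loops$start2[k], loops$end2[k]) >= min_overlap
          if ((i_hits_1 && j_hits_2) || (i_hits_2 && j_hits_1)) {
            lab <- "positive"
            break
          }
        }
        res <- rbind(res, data.frame(chrom1 = ch, start1 = a$start[i],
                                     end1 = a$end[i], chrom2 = ch,
                                     start2 = a$start[j], end2 = a$end[j],
                                     label = lab, stringsAsFactors = FALSE))
      }
    }
  }
  res
}

# Two-sided Fisher exact p for a 2x2 table by exhaustive hypergeometric
# enumeration: sum the probabilities of all tables with the same margins
# whose probability does not exceed the observed one.
oracle_fisher2x2 <- function(a, b, c, d) {
  m <- a + b      # row 1 total (group A size)
  n2 <- c + d     # row 2 total
  k <- a + c      # column 1 total (total present)
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  logp <- function(x) {
    lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)
  }
  p_obs <- logp(a)
  xs <- lo:hi
  sum(exp(logp(xs))[logp(xs) <= p_obs + 1e-7])
}

# Full forward pass of the extractor in plain R (one sequence), mirroring
# the documented architecture with naive loops.
oracle_forward_features <- function(codes, params, config) {
  L <- config$input_length; k1 <- config$n_kernels1; w1 <- config$width1
  pool <- config$pool; k2 <- config$n_kernels2; w2 <- config$width2
  P1 <- L - w1 + 1
  X <- matrix(0, L, 4)
  keep <- codes < 4
  X[cbind(which(keep), codes[keep] + 1)] <- 1
  Z1 <- matrix(0, k1, P1)
  for (p in seq_len(P1)) {
    xv <- as.vector(t(X[p:(p + w1 - 1), , drop = FALSE]))
    Z1[, p] <- params$W1 %*% xv + params$b1[, 1]
  }
  Q <- P1 %/% pool
  M1 <- matrix(0, k1, Q)
  for (q in seq_len(Q)) {
    M1[, q] <- pmax(apply(Z1[, ((q - 1) * pool + 1):(q * pool), drop = FALSE],
                          1, max), 0)
  }
  P2 <- Q - w2 + 1
  Z2 <- matrix(0, k2, P2)
  for (p in seq_len(P2)) {
    cv <- as.vector(M1[, p:(p + w2 - 1), drop = FALSE])
    Z2[, p] <- params$W2 %*% cv + params$b2[, 1]
  }
  pmax(apply(Z2, 1, max), 0)
}
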