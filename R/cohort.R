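# Cohort statistics over predicted interaction sets: presence matrices
# over a pooled anchor universe, conservation profiles, Fisher-exact
# differential interactions between sample groups, anchor-change
# attribution and promoter interaction-fold-change (IFC) scores.

#' Build an interaction presence matrix
#'
#' Rows are interactions over a shared (pooled) anchor universe, columns
#' are samples; an entry is 1 iff the pair is predicted in that sample
#' (score at or above that sample's own threshold, typically its
#' F-score-selected one). Rows observed in no sample are dropped.
#'
#' @param predictions Named list of per-sample pair `data.frame`s with a
#'   `score` column (or a logical `predicted` column).
#' @param anchor_universe Interval `data.frame`; every prediction's
#'   anchors must be drawn from this universe (exact identity).
#' @param thresholds Numeric vector (length 1 or one per sample) of score
#'   thresholds; ignored where a `predicted` column exists.
#' @return A `presence_matrix`: binary matrix with pair-key rownames and
#'   sample colnames, plus a `pairs` attribute holding the row
#'   coordinates.
#' @export
build_presence_matrix <- function(predictions, anchor_universe,
                                  thresholds = 0.5) {
  stop_if(is.null(names(predictions)), "predictions must be named by sample")
  thresholds <- rep_len(thresholds, length(predictions))
  ukey <- paste(anchor_universe$chrom, anchor_universe$start,
                anchor_universe$end)
  rows <- list()
  present <- list()
  for (i in seq_along(predictions)) {
    pred <- predictions[[i]]
    akeys <- c(paste(pred$chrom1, pred$start1, pred$end1),
               paste(pred$chrom2, pred$start2, pred$end2))
    bad <- setdiff(akeys, ukey)
    stop_if(length(bad) > 0L, "prediction anchor outside the universe: ",
            bad[1L])
    hit <- if (!is.null(pred$predicted)) pred$predicted
    else pred$score >= thresholds[i]
    rows[[i]] <- pred[hit, , drop = FALSE]
    present[[i]] <- pair_key(rows[[i]])
  }
  all_keys <- unique(unlist(present))
  mat <- vapply(present, function(k) as.integer(all_keys %in% k),
                integer(length(all_keys)))
  if (length(all_keys) == 1L) mat <- matrix(mat, nrow = 1L)
  dimnames(mat) <- list(all_keys, names(predictions))
  coords <- do.call(rbind, rows)
  coords <- coords[match(all_keys, pair_key(coords)),
                   c("chrom1", "start1", "end1", "chrom2", "start2", "end2"),
                   drop = FALSE]
  rownames(coords) <- NULL
  structure(mat, pairs = coords, class = c("presence_matrix", class(mat)))
}

#' Conservation profile
#'
#' The proportion of interactions present in exactly k of the n samples,
#' for k = 1..n. The k = 1 entry is the fraction of interactions private
#' to a single sample (the headline heterogeneity statistic).
#'
#' @param matrix A binary presence matrix (interactions x samples).
#' @return Numeric vector of proportions, names `"1"`..`"n"`; sums to 1.
#' @export
conservation_profile <- function(matrix) {
  n <- ncol(matrix)
  stop_if(n < 1L, "at least one sample required")
  k <- rowSums(matrix)
  counts <- tabulate(k, nbins = n)
  stats::setNames(counts / nrow(matrix), as.character(seq_len(n)))
}

#' Differential interactions between two groups
#'
#' Per interaction, a two-sided Fisher exact test on the 2x2
#' present/absent-by-group table, with Benjamini-Hochberg adjustment
#' across interactions. Rows present in every sample or in none are
#' degenerate: their p is 1 by convention and they are flagged.
#'
#' @param matrix A binary presence matrix.
#' @param groups Character/factor vector (one per sample, exactly two
#'   levels) or named vector matching column names.
#' @return `data.frame` with the 2x2 counts, `p_value`, `p_adj`,
#'   `direction` (group with the higher presence rate, or `"none"`), and
#'   `degenerate` flag.
#' @export
differential_interactions <- function(matrix, groups) {
  if (!is.null(names(groups))) groups <- groups[colnames(matrix)]
  groups <- as.character(groups)
  lev <- unique(groups)
  stop_if(length(lev) != 2L, "exactly two groups required")
  stop_if(length(groups) != ncol(matrix), "one group label per sample required")
  nA <- sum(groups == lev[1L]); nB <- sum(groups == lev[2L])
  presA <- rowSums(matrix[, groups == lev[1L], drop = FALSE])
  presB <- rowSums(matrix[, groups == lev[2L], drop = FALSE])
  degenerate <- (presA + presB == 0L) | (presA + presB == nA + nB)
  p <- vapply(seq_len(nrow(matrix)), function(i) {
    if (degenerate[i]) return(1)
    stats::fisher.test(matrix(c(presA[i], nA - presA[i],
                                presB[i], nB - presB[i]), 2L, 2L))$p.value
  }, numeric(1))
  rateA <- presA / nA; rateB <- presB / nB
  data.frame(key = rownames(matrix),
             present_A = as.integer(presA), absent_A = as.integer(nA - presA),
             present_B = as.integer(presB), absent_B = as.integer(nB - presB),
             group_A = lev[1L], group_B = lev[2L],
             p_value = p, p_adj = stats::p.adjust(p, method = "BH"),
             direction = ifelse(rateA > rateB, lev[1L],
                                ifelse(rateB > rateA, lev[2L], "none")),
             degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Anchor-change attribution of differential interactions
#'
#' For each significantly differential interaction, tests the two anchors
#' with the same Fisher/BH procedure on an anchor presence matrix and
#' classifies the interaction by how many of its anchors are themselves
#' significantly differential in the same direction: `"both"`,
#' `"one-side"`, or `"neither"`. The three counts partition the
#' differential set.
#'
#' @param diff Result of [differential_interactions()] on the interaction
#'   presence matrix.
#' @param anchor_matrix Binary anchor presence matrix (anchor keys
#'   `"chrom start end"` as rownames, same sample columns).
#' @param groups Group labels as in [differential_interactions()].
#' @param alpha Adjusted-p threshold applied to interactions and anchors
#'   alike (default 0.05).
#' @return List with `counts` (named both/one-side/neither) and the
#'   per-interaction `table`.
#' @export
anchor_change_attribution <- function(diff, anchor_matrix, groups,
                                      alpha = 0.05) {
  pm <- attr(diff, "pairs")
  adiff <- differential_interactions(anchor_matrix, groups)
  sig <- diff[diff$p_adj <= alpha & !diff$degenerate, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(list(counts = c(both = 0L, `one-side` = 0L, neither = 0L),
                table = data.frame()))
  }
  parts <- strsplit(sig$key, ":", fixed = TRUE)
  akey1 <- vapply(parts, function(p) paste(p[1], p[2], p[3]), character(1))
  akey2 <- vapply(parts, function(p) paste(p[4], p[5], p[6]), character(1))
  anchor_sig <- function(akey, direction) {
    i <- match(akey, adiff$key)
    !is.na(i) & adiff$p_adj[i] <= alpha & !adiff$degenerate[i] &
      adiff$direction[i] == direction
  }
  n_sig <- anchor_sig(akey1, sig$direction) + anchor_sig(akey2, sig$direction)
  cls <- c("neither", "one-side", "both")[n_sig + 1L]
  counts <- c(both = sum(cls == "both"), `one-side` = sum(cls == "one-side"),
              neither = sum(cls == "neither"))
  list(counts = counts,
       table = data.frame(key = sig$key, attribution = cls,
                          stringsAsFactors = FALSE))
}

#' Promoter interaction fold change (IFC)
#'
#' Per gene: the number of interactions touching its promoter window is
#' counted in each sample; IFC is the mean count in group A over the mean
#' count in group B. A zero denominator leaves IFC undefined (NA,
#' flagged). Genes whose promoter overlaps no interaction anchor are
#' excluded with a note. When expression classes are supplied, a
#' Kruskal-Wallis test of IFC across classes is reported.
#'
#' @param promoters Interval `data.frame` with a `name` column (gene ids);
#'   typically TSS +/- 2 kb windows.
#' @param matrix A `presence_matrix` (carrying its `pairs` attribute).
#' @param groups Two-level group labels per sample; group A is the first
#'   level in order of appearance.
#' @param expression_classes Optional named vector (gene -> class).
#' @return List with per-gene `table` (counts, `ifc`, `undefined` flag),
#'   `excluded` gene ids, and `kruskal` (htest or NULL).
#' @export
ifc_score <- function(promoters, matrix, groups,
                      expression_classes = NULL) {
  coords <- attr(matrix, "pairs")
  stop_if(is.null(coords), "presence matrix lacks pair coordinates")
  if (!is.null(names(groups))) groups <- groups[colnames(matrix)]
  groups <- as.character(groups)
  lev <- unique(groups)
  stop_if(length(lev) != 2L, "exactly two groups required")
  left <- data.frame(chrom = coords$chrom1, start = coords$start1,
                     end = coords$end1, stringsAsFactors = FALSE)
  right <- data.frame(chrom = coords$chrom2, start = coords$start2,
                      end = coords$end2, stringsAsFactors = FALSE)
  hl <- overlap_hits0(promoters, left)
  hr <- overlap_hits0(promoters, right)
  touch <- unique(rbind(hl, hr))  # promoter row -> interaction row
  genes <- promoters$name
  touched_genes <- unique(genes[touch$query])
  excluded <- setdiff(genes, touched_genes)
  rows <- lapply(touched_genes, function(g) {
    ints <- unique(touch$subject[genes[touch$query] == g])
    counts <- colSums(matrix[ints, , drop = FALSE])
    mA <- mean(counts[groups == lev[1L]])
    mB <- mean(counts[groups == lev[2L]])
    data.frame(gene = g, n_interactions = length(ints),
               mean_A = mA, mean_B = mB,
               ifc = if (mB == 0) NA_real_ else mA / mB,
               undefined = mB == 0, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  kr <- NULL
  if (!is.null(expression_classes) && !is.null(tab) && nrow(tab) > 0L) {
    cls <- expression_classes[tab$gene]
    ok <- !is.na(cls) & !is.na(tab$ifc)
    if (length(unique(cls[ok])) >= 2L) {
      kr <- stats::kruskal.test(tab$ifc[ok], factor(cls[ok]))
    }
  }
  if (length(excluded) > 0L) {
    message(length(excluded), " gene(s) with no overlapping anchor excluded")
  }
  list(table = tab, excluded = excluded, kruskal = kr)
}
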