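# Dataset construction: positive pairs from loop files, distance-matched
# and extended negative tiers by re-pairing positive anchors, candidate
# anchors from open chromatin, exhaustive pair enumeration/labeling, and
# chromosome-holdout splits.

#' Positive pairs from a loop file
#'
#' Drops inter-chromosomal loops, optionally keeps only loops whose two
#' anchors each overlap at least one open chromatin region, collapses
#' duplicated anchor pairs, and labels the survivors positive.
#'
#' @param loops Pair `data.frame` from [read_bedpe()].
#' @param open_regions Optional interval `data.frame` of open chromatin
#'   regions; when given, both anchors must overlap at least one region.
#' @param min_overlap Minimum anchor/region overlap in bp (default 1).
#' @return Pair `data.frame` with `label = "positive"`.
#' @export
extract_positive_pairs <- function(loops, open_regions = NULL, min_overlap = 1L) {
  keep <- !loops$inter_chrom
  pairs <- loops[keep, , drop = FALSE]
  if (!is.null(open_regions) && nrow(pairs) > 0L) {
    left <- data.frame(chrom = pairs$chrom1, start = pairs$start1,
                       end = pairs$end1, stringsAsFactors = FALSE)
    right <- data.frame(chrom = pairs$chrom2, start = pairs$start2,
                        end = pairs$end2, stringsAsFactors = FALSE)
    ok <- count_overlaps0(left, open_regions, min_overlap) > 0L &
      count_overlaps0(right, open_regions, min_overlap) > 0L
    pairs <- pairs[ok, , drop = FALSE]
  }
  pairs <- pairs[!duplicated(pair_key(pairs)), , drop = FALSE]
  if (nrow(pairs) == 0L) warning("no positive pairs after filtering")
  pairs$label <- rep("positive", nrow(pairs))
  rownames(pairs) <- NULL
  pairs
}

# Unique anchors (left and right) of a pair set, with chromosome.
positive_anchor_set <- function(positives) {
  anc <- rbind(
    data.frame(chrom = positives$chrom1, start = positives$start1,
               end = positives$end1, stringsAsFactors = FALSE),
    data.frame(chrom = positives$chrom2, start = positives$start2,
               end = positives$end2, stringsAsFactors = FALSE))
  anc <- anc[!duplicated(paste(anc$chrom, anc$start, anc$end)), , drop = FALSE]
  rownames(anc) <- NULL
  anc
}

# All same-chromosome re-pairings (genomic order) of an anchor set, minus
# any pair identical to a positive. Distances attached.
candidate_repairings <- function(positives) {
  anc <- positive_anchor_set(positives)
  pieces <- lapply(split(seq_len(nrow(anc)), anc$chrom), function(idx) {
    if (length(idx) < 2L) return(NULL)
    a <- anc[idx, , drop = FALSE]
    a <- a[order(a$start, a$end), , drop = FALSE]
    ij <- utils::combn(nrow(a), 2L)
    data.frame(chrom1 = a$chrom[ij[1L, ]], start1 = a$start[ij[1L, ]],
               end1 = a$end[ij[1L, ]], chrom2 = a$chrom[ij[2L, ]],
               start2 = a$start[ij[2L, ]], end2 = a$end[ij[2L, ]],
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, pieces)
  if (is.null(cand) || nrow(cand) == 0L) {
    stop("no candidate re-pairings available", call. = FALSE)
  }
  cand <- anchor_pairs(cand$chrom1, cand$start1, cand$end1,
                       cand$chrom2, cand$start2, cand$end2)
  cand <- cand[!pair_key(cand) %in% pair_key(positives), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Sample distance-matched negatives
#'
#' Candidate negatives are same-chromosome re-pairings of the positive
#' anchor set. Positive distances are binned into `n_bins` log10-spaced
#' bins; each bin contributes `ratio` times its positive count, sampled
#' without replacement from candidates falling in the bin. Bins whose
#' candidates are exhausted have their deficit re-allocated to the nearest
#' remaining candidates (with a warning). Deterministic given `seed`.
#'
#' The target positive-to-negative ratio of 1:5 matches the ratio used for
#' distance-matched loop datasets in practice.
#'
#' @param positives Pair `data.frame` with positive labels.
#' @param ratio Target negatives per positive (default 5).
#' @param n_bins Number of log10-spaced distance bins (default 50).
#' @param seed Integer RNG seed.
#' @return Pair `data.frame` with `label = "negative"`.
#' @export
sample_distance_matched_negatives <- function(positives, ratio = 5L,
                                              n_bins = 50L, seed = 1L) {
  stop_if(nrow(positives) == 0L, "positives must be non-empty")
  stop_if(ratio < 1L, "ratio must be >= 1")
  cand <- candidate_repairings(positives)
  pd <- positives$distance
  rng <- range(pd)
  edges <- 10^seq(log10(max(rng[1L], 1)), log10(rng[2L] + 1),
                  length.out = n_bins + 1L)
  edges[1L] <- min(edges[1L], rng[1L])
  edges[n_bins + 1L] <- max(edges[n_bins + 1L], rng[2L] + 1)
  pos_bin <- findInterval(pd, edges, rightmost.closed = TRUE,
                          all.inside = TRUE)
  cand_bin <- findInterval(cand$distance, edges, rightmost.closed = TRUE,
                           all.inside = TRUE)
  cand_bin[cand$distance < edges[1L] | cand$distance > edges[n_bins + 1L]] <- NA
  quota <- tabulate(pos_bin, nbins = n_bins) * ratio
  with_seed(seed, {
    taken <- logical(nrow(cand))
    deficit_bins <- integer(0)
    deficits <- integer(0)
    for (b in which(quota > 0L)) {
      in_bin <- which(!is.na(cand_bin) & cand_bin == b & !taken)
      k <- min(quota[b], length(in_bin))
      if (k > 0L) taken[in_bin[sample.int(length(in_bin))[seq_len(k)]]] <- TRUE
      if (k < quota[b]) {
        deficit_bins <- c(deficit_bins, b)
        deficits <- c(deficits, quota[b] - k)
      }
    }
    if (length(deficit_bins) > 0L) {
      warning("candidate-poor distance bins; re-allocating ",
              sum(deficits), " negatives to neighboring candidates")
      centers <- sqrt(edges[-1L] * edges[-(n_bins + 1L)])
      for (i in seq_along(deficit_bins)) {
        free <- which(!taken)
        if (length(free) == 0L) break
        d <- abs(log10(pmax(cand$distance[free], 1)) -
                   log10(centers[deficit_bins[i]]))
        ord <- free[order(d, sample.int(length(free)))]
        taken[ord[seq_len(min(deficits[i], length(ord)))]] <- TRUE
      }
    }
    neg <- cand[taken, , drop = FALSE]
  })
  neg$label <- rep("negative", nrow(neg))
  rownames(neg) <- NULL
  neg
}

#' Sample extended negatives
#'
#' Like [sample_distance_matched_negatives()] but with relaxed distance
#' matching: negatives are drawn uniformly over candidate re-pairings whose
#' distance lies within the positive distance range. Extended sets carry
#' more negatives than the distance-matched tier (default 25 per positive).
#'
#' @param positives Pair `data.frame` with positive labels.
#' @param ratio_extended Target negatives per positive (default 25).
#' @param seed Integer RNG seed.
#' @return Pair `data.frame` with `label = "negative"`.
#' @export
build_extended_negatives <- function(positives, ratio_extended = 25L, seed = 1L) {
  stop_if(nrow(positives) == 0L, "positives must be non-empty")
  cand <- candidate_repairings(positives)
  rng <- range(positives$distance)
  cand <- cand[cand$distance >= rng[1L] & cand$distance <= rng[2L], , drop = FALSE]
  want <- ratio_extended * nrow(positives)
  if (nrow(cand) < want) {
    warning("only ", nrow(cand), " candidates for ", want,
            " requested extended negatives")
  }
  with_seed(seed, {
    idx <- sample.int(nrow(cand))[seq_len(min(want, nrow(cand)))]
  })
  neg <- cand[sort(idx), , drop = FALSE]
  neg$label <- rep("negative", nrow(neg))
  rownames(neg) <- NULL
  neg
}

#' Candidate anchors from open chromatin regions
#'
#' Merges open chromatin regions within `merge_distance` bp and extends
#' the merged regions by `extension` bp on each side (clamped to the
#' chromosome). The defaults, 3000 bp merging and 1000 bp extension, are
#' the parameter combination selected for anchor construction on
#' validation data.
#'
#' @param open_regions Interval `data.frame` of peaks.
#' @param merge_distance Merging distance in bp (default 3000).
#' @param extension Extension in bp (default 1000).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return Sorted interval `data.frame` of candidate anchors.
#' @export
build_anchors_from_open_chromatin <- function(open_regions,
                                              merge_distance = 3000L,
                                              extension = 1000L,
                                              chrom_lengths = NULL) {
  merge_and_extend(open_regions, merge_distance, extension, chrom_lengths)
}

#' Enumerate and label all candidate anchor pairs
#'
#' Enumerates every same-chromosome anchor pair with midpoint distance at
#' most `max_span`, and labels a pair positive iff its left anchor overlaps
#' (by at least `min_overlap` bp) one anchor of some known loop and its
#' right anchor overlaps the other anchor of the same loop.
#'
#' @param anchors Sorted interval `data.frame` of candidate anchors.
#' @param known_loops Pair `data.frame` of known interactions.
#' @param max_span Maximum pair distance in bp (default 2 Mb).
#' @param min_overlap Minimum overlap in bp for label transfer (default 1).
#' @return Pair `data.frame` with `label` in `{"positive","negative"}`.
#' @export
enumerate_and_label_pairs <- function(anchors, known_loops,
                                      max_span = 2e6, min_overlap = 1L) {
  stop_if(max_span <= 0, "max_span must be positive")
  pieces <- lapply(split(seq_len(nrow(anchors)), anchors$chrom), function(idx) {
    if (length(idx) < 2L) return(NULL)
    a <- anchors[idx, , drop = FALSE]
    a <- a[order(a$start, a$end), , drop = FALSE]
    mid <- (as.numeric(a$start) + as.numeric(a$end)) %/% 2
    ii <- integer(0); jj <- integer(0)
    hi <- 1L
    for (i in seq_len(nrow(a) - 1L)) {
      js <- which(mid[(i + 1L):nrow(a)] - mid[i] <= max_span) + i
      if (length(js) > 0L) {
        ii <- c(ii, rep.int(i, length(js))); jj <- c(jj, js)
      }
    }
    if (length(ii) == 0L) return(NULL)
    data.frame(chrom1 = a$chrom[ii], start1 = a$start[ii], end1 = a$end[ii],
               chrom2 = a$chrom[jj], start2 = a$start[jj], end2 = a$end[jj],
               stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) {
    out <- anchor_pairs(character(), integer(), integer(),
                        character(), integer(), integer())
    out$label <- character(0)
    return(out)
  }
  cand <- do.call(rbind, pieces)
  cand <- anchor_pairs(cand$chrom1, cand$start1, cand$end1,
                       cand$chrom2, cand$start2, cand$end2)
  cand$label <- rep("negative", nrow(cand))
  if (nrow(known_loops) > 0L) {
    loops <- known_loops[!known_loops$inter_chrom, , drop = FALSE]
    canc <- data.frame(chrom = c(cand$chrom1, cand$chrom2),
                       start = c(cand$start1, cand$start2),
                       end = c(cand$end1, cand$end2),
                       stringsAsFactors = FALSE)
    akey <- paste(canc$chrom, canc$start, canc$end)
    ukey <- unique(akey)
    uanc <- canc[match(ukey, akey), , drop = FALSE]
    la <- data.frame(chrom = loops$chrom1, start = loops$start1,
                     end = loops$end1, stringsAsFactors = FALSE)
    ra <- data.frame(chrom = loops$chrom2, start = loops$start2,
                     end = loops$end2, stringsAsFactors = FALSE)
    h1 <- overlap_hits0(uanc, la, min_overlap)
    h2 <- overlap_hits0(uanc, ra, min_overlap)
    pos_keys <- character(0)
    for (k in seq_len(nrow(loops))) {
      s1 <- ukey[h1$query[h1$subject == k]]
      s2 <- ukey[h2$query[h2$subject == k]]
      if (length(s1) > 0L && length(s2) > 0L) {
        grid <- expand.grid(a = s1, b = s2, stringsAsFactors = FALSE)
        pos_keys <- c(pos_keys,
                      paste(grid$a, grid$b, sep = "|"),
                      paste(grid$b, grid$a, sep = "|"))
      }
    }
    ck <- paste(paste(cand$chrom1, cand$start1, cand$end1),
                paste(cand$chrom2, cand$start2, cand$end2), sep = "|")
    cand$label[ck %in% pos_keys] <- "positive"
  }
  rownames(cand) <- NULL
  cand
}

#' Chromosome-holdout split
#'
#' Partitions labeled pairs into train/validation/test by chromosome, so
#' that no anchor sequence is shared between splits. Random splitting of
#' pairs inflates apparent performance because the two anchors of nearby
#' pairs recur across folds; holding out whole chromosomes avoids that
#' leakage.
#'
#' @param pairs Pair `data.frame`.
#' @param test Chromosomes forming the test set (default `c("chr5","chr14")`).
#' @param validation Chromosomes forming the validation set (default
#'   `"chr4"`; may be empty for a two-way split).
#' @param train Chromosomes forming the training set, or `NULL` (default)
#'   for all remaining chromosomes.
#' @return Named list of three pair `data.frame`s: `train`, `validation`,
#'   `test`.
#' @export
split_by_chromosome <- function(pairs, test = c("chr5", "chr14"),
                                validation = "chr4", train = NULL) {
  sets <- list(test = test, validation = validation)
  stop_if(length(intersect(test, validation)) > 0L,
          "split sets must be disjoint")
  chroms <- pairs$chrom1
  if (is.null(train)) {
    train <- setdiff(unique(chroms), c(test, validation))
  } else {
    stop_if(length(intersect(train, c(test, validation))) > 0L,
            "split sets must be disjoint")
  }
  missing <- setdiff(unique(chroms), c(train, validation, test))
  stop_if(length(missing) > 0L,
          "chromosome(s) not assigned to any split: ",
          paste(missing, collapse = ", "))
  list(train = pairs[chroms %in% train, , drop = FALSE],
       validation = pairs[chroms %in% validation, , drop = FALSE],
       test = pairs[chroms %in% test, , drop = FALSE])
}
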