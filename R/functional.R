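# Functional-genomics baseline features: per-track mean signal or peak
# counts over each anchor, optionally with distance, for the
# gradient-boosted baseline model.

#' Read a bedGraph signal track
#'
#' @param path Path to a 4-column bedGraph file (chrom, start, end, value;
#'   0-based half-open).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric"))
  df
}

#' Write a bedGraph signal track
#'
#' @param track `data.frame` with columns `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Check a track has no overlapping segments within a chromosome.
assert_track_disjoint <- function(track, name = "track") {
  for (ch in unique(track$chrom)) {
    df <- track[track$chrom == ch, , drop = FALSE]
    df <- df[order(df$start), , drop = FALSE]
    if (nrow(df) > 1L && any(df$start[-1L] < df$end[-nrow(df)])) {
      stop("overlapping segments in ", name, " on ", ch, call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Coverage-weighted mean of a track over intervals; uncovered bases count 0.
track_mean_over <- function(intervals, track) {
  out <- numeric(nrow(intervals))
  for (ch in unique(intervals$chrom)) {
    qi <- which(intervals$chrom == ch)
    seg <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(seg) == 0L) next
    hits <- overlap_hits0(intervals[qi, , drop = FALSE], seg)
    if (nrow(hits) == 0L) next
    q <- intervals[qi, , drop = FALSE]
    ov <- pmin(q$end[hits$query], seg$end[hits$subject]) -
      pmax(q$start[hits$query], seg$start[hits$subject])
    contrib <- ov * seg$value[hits$subject]
    sums <- tapply(contrib, hits$query, sum)
    idx <- as.integer(names(sums))
    out[qi[idx]] <- sums / (q$end[idx] - q$start[idx])
  }
  out
}

#' Mean-signal features for anchor pairs
#'
#' For every track and both anchors, the coverage-weighted mean signal
#' over the anchor span: sum of segment value times overlap length,
#' divided by the anchor length; uncovered bases contribute zero. Tracks
#' must be non-overlapping within a chromosome.
#'
#' @param pairs Pair `data.frame`.
#' @param tracks Named list of bedGraph `data.frame`s.
#' @return Numeric matrix with columns `<track>_left`, `<track>_right`
#'   in track order.
#' @export
mean_signal_features <- function(pairs, tracks) {
  stop_if(is.null(names(tracks)) || any(!nzchar(names(tracks))),
          "tracks must be named")
  left <- data.frame(chrom = pairs$chrom1, start = pairs$start1,
                     end = pairs$end1, stringsAsFactors = FALSE)
  right <- data.frame(chrom = pairs$chrom2, start = pairs$start2,
                      end = pairs$end2, stringsAsFactors = FALSE)
  cols <- lapply(names(tracks), function(nm) {
    assert_track_disjoint(tracks[[nm]], nm)
    cbind(track_mean_over(left, tracks[[nm]]),
          track_mean_over(right, tracks[[nm]]))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- as.vector(vapply(names(tracks), function(nm)
    c(paste0(nm, "_left"), paste0(nm, "_right")), character(2)))
  out
}

#' Peak-count features for anchor pairs
#'
#' For every peak set and both anchors, the number of peaks overlapping
#' the anchor by at least 1 bp.
#'
#' @param pairs Pair `data.frame`.
#' @param peak_sets Named list of interval `data.frame`s.
#' @return Integer matrix with columns `<set>_left`, `<set>_right`.
#' @export
peak_count_features <- function(pairs, peak_sets) {
  stop_if(is.null(names(peak_sets)) || any(!nzchar(names(peak_sets))),
          "peak_sets must be named")
  left <- data.frame(chrom = pairs$chrom1, start = pairs$start1,
                     end = pairs$end1, stringsAsFactors = FALSE)
  right <- data.frame(chrom = pairs$chrom2, start = pairs$start2,
                      end = pairs$end2, stringsAsFactors = FALSE)
  cols <- lapply(names(peak_sets), function(nm) {
    cbind(count_overlaps0(left, peak_sets[[nm]]),
          count_overlaps0(right, peak_sets[[nm]]))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- as.vector(vapply(names(peak_sets), function(nm)
    c(paste0(nm, "_left"), paste0(nm, "_right")), character(2)))
  out
}

#' Assemble a functional feature table
#'
#' Builds the classifier input for the functional-genomics baseline from
#' one of three feature sets: all genomics features plus distance,
#' genomics only, or distance only.
#'
#' @param pairs Labeled pair `data.frame`.
#' @param tracks Named list of bedGraph tracks (for `representation =
#'   "signal"`) or interval peak sets (for `"counts"`); ignored for
#'   `feature_mode = "distance_only"`.
#' @param feature_mode One of `"all"`, `"genomics_only"`, `"distance_only"`.
#' @param representation One of `"signal"`, `"counts"`.
#' @return List with `features` (numeric matrix, deterministic column
#'   order) and `labels`.
#' @export
assemble_feature_table <- function(pairs, tracks = NULL,
                                   feature_mode = c("all", "genomics_only",
                                                    "distance_only"),
                                   representation = c("signal", "counts")) {
  feature_mode <- match.arg(feature_mode)
  representation <- match.arg(representation)
  stop_if(is.null(pairs$label), "pairs must be labeled")
  if (feature_mode == "distance_only") {
    if (!is.null(tracks)) {
      warning("distance_only ignores tracks and representation")
    }
    feats <- matrix(as.numeric(pairs$distance), ncol = 1,
                    dimnames = list(NULL, "distance"))
    return(list(features = feats, labels = pairs$label))
  }
  stop_if(is.null(tracks), "tracks required for genomics features")
  gen <- if (representation == "signal") {
    mean_signal_features(pairs, tracks)
  } else {
    peak_count_features(pairs, tracks)
  }
  feats <- if (feature_mode == "all") {
    cbind(gen, distance = as.numeric(pairs$distance))
  } else {
    gen
  }
  list(features = feats, labels = pairs$label)
}
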