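# Genomic intervals are plain data.frames with columns chrom, start, end
# (BED convention: 0-based, half-open) plus optional annotation columns.
# All coordinate arithmetic in the package uses this convention; conversion
# to 1-based closed coordinates happens only at the IRanges boundary.

#' Construct a genomic interval table
#'
#' Intervals use the BED convention throughout: 0-based starts, half-open
#' ends. Invariants (`0 <= start < end`, non-empty chromosome names) are
#' checked on construction.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector of 0-based inclusive start positions.
#' @param end Integer vector of exclusive end positions.
#' @param ... Further equal-length annotation columns (name, score, ...).
#' @return A `data.frame` with columns `chrom`, `start`, `end` and any
#'   annotation columns.
#' @examples
#' genomic_intervals("chr1", 100, 200)
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  stop_if(any(is.na(start)) || any(is.na(end)), "non-integer coordinates")
  stop_if(any(!nzchar(chrom)), "empty chromosome name")
  stop_if(any(start < 0L), "negative start coordinate")
  stop_if(any(start >= end), "start must be < end")
  data.frame(chrom = chrom, start = start, end = end, ...,
             stringsAsFactors = FALSE)
}

#' Read a BED file
#'
#' Parses BED3+ (including narrowPeak) into a 0-based half-open interval
#' table. Columns beyond the first three are kept as annotation columns
#' named `V4`, `V5`, ... (or `name`, `score` for columns 4-5). File order
#' is retained.
#'
#' @param path Path to a tab-separated BED file.
#' @return Interval `data.frame`; see [genomic_intervals()].
#' @export
read_bed <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  stop_if(any(ncol < 3L),
          "BED parse error at line ", which(ncol < 3L)[1L], ": fewer than 3 columns")
  n <- max(ncol)
  mat <- t(vapply(fields, function(f) c(f, rep(NA_character_, n - length(f))),
                  character(n)))
  start <- suppressWarnings(as.integer(mat[, 2L]))
  end <- suppressWarnings(as.integer(mat[, 3L]))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  stop_if(length(bad) > 0L,
          "BED parse error at line ", bad[1L],
          ": invalid coordinates '", mat[bad[1L], 2L], "', '", mat[bad[1L], 3L], "'")
  out <- data.frame(chrom = mat[, 1L], start = start, end = end,
                    stringsAsFactors = FALSE)
  if (n >= 4L) out$name <- mat[, 4L]
  if (n >= 5L) out$score <- suppressWarnings(as.numeric(mat[, 5L]))
  if (n >= 6L) {
    for (j in 6:n) out[[paste0("V", j)]] <- mat[, j]
  }
  out
}

#' Write intervals as BED
#'
#' @param intervals Interval `data.frame`.
#' @param path Output path. Records are tab-separated and newline-terminated.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"),
                    names(intervals))
  extra <- grep("^V[0-9]+$", names(intervals), value = TRUE)
  df <- intervals[, c(cols, extra), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge nearby intervals and extend the result
#'
#' Per chromosome, intervals are sorted by start and any two whose gap
#' (`next start - current end`) is at most `merge_distance` are unioned
#' transitively. Each merged interval is then extended by `extension` bp on
#' both sides and clamped to `[0, chromosome length)`.
#'
#' This is the anchor-construction primitive for building candidate anchors
#' from open chromatin peaks; the defaults used there are a merging
#' distance of 3000 bp and an extension of 1000 bp.
#'
#' @param intervals Interval `data.frame`.
#' @param merge_distance Non-negative gap (bp) at or below which intervals
#'   are merged.
#' @param extension Non-negative extension (bp) applied to each side after
#'   merging.
#' @param chrom_lengths Named integer vector of chromosome lengths used for
#'   clamping. Chromosomes absent from the vector are not clamped on the
#'   right.
#' @return Sorted interval `data.frame` (annotation columns dropped).
#' @export
merge_and_extend <- function(intervals, merge_distance = 0L, extension = 0L,
                             chrom_lengths = NULL) {
  stop_if(merge_distance < 0 || extension < 0,
          "merge_distance and extension must be >= 0")
  if (nrow(intervals) == 0L) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  pieces <- lapply(split(intervals, intervals$chrom), function(df) {
    df <- df[order(df$start, df$end), , drop = FALSE]
    ms <- df$start[1L]
    me <- df$end[1L]
    starts <- integer(0)
    ends <- integer(0)
    if (nrow(df) > 1L) {
      for (i in 2:nrow(df)) {
        if (df$start[i] - me <= merge_distance) {
          me <- max(me, df$end[i])
        } else {
          starts <- c(starts, ms); ends <- c(ends, me)
          ms <- df$start[i]; me <- df$end[i]
        }
      }
    }
    starts <- c(starts, ms); ends <- c(ends, me)
    starts <- pmax(0L, starts - as.integer(extension))
    ends <- ends + as.integer(extension)
    if (!is.null(chrom_lengths) && df$chrom[1L] %in% names(chrom_lengths)) {
      ends <- pmin(ends, as.integer(chrom_lengths[[df$chrom[1L]]]))
    }
    data.frame(chrom = df$chrom[1L], start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Midpoint distance between two anchors
#'
#' Distance between two same-chromosome intervals is defined as the
#' absolute difference of their midpoints, with midpoints rounded down to
#' whole base pairs. Midpoints are stable under symmetric anchor extension,
#' which is why they (rather than gap or edge distances) define pair
#' distance here. Vectorized over rows.
#'
#' @param chrom1,start1,end1 Left anchor coordinates (0-based half-open).
#' @param chrom2,start2,end2 Right anchor coordinates.
#' @return Integer vector of distances in bp.
#' @export
pair_distance <- function(chrom1, start1, end1, chrom2, start2, end2) {
  stop_if(any(chrom1 != chrom2), "pair_distance requires same-chromosome anchors")
  m1 <- (as.numeric(start1) + as.numeric(end1)) %/% 2
  m2 <- (as.numeric(start2) + as.numeric(end2)) %/% 2
  as.integer(abs(m1 - m2))
}

# 0-based half-open -> IRanges (1-based closed)
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

# For each query interval, the number of subject intervals overlapping by
# >= min_overlap bp, computed per chromosome through IRanges.
count_overlaps0 <- function(query, subject, min_overlap = 1L) {
  n <- nrow(query)
  out <- integer(n)
  if (n == 0L || nrow(subject) == 0L) return(out)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (length(si) == 0L) next
    out[qi] <- IRanges::countOverlaps(
      as_iranges0(query$start[qi], query$end[qi]),
      as_iranges0(subject$start[si], subject$end[si]),
      minoverlap = as.integer(min_overlap))
  }
  out
}

# Overlap hit pairs (query index, subject index) with >= min_overlap bp.
overlap_hits0 <- function(query, subject, min_overlap = 1L) {
  qh <- integer(0); sh <- integer(0)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (length(si) == 0L) next
    hits <- IRanges::findOverlaps(
      as_iranges0(query$start[qi], query$end[qi]),
      as_iranges0(subject$start[si], subject$end[si]),
      minoverlap = as.integer(min_overlap))
    qh <- c(qh, qi[S4Vectors_from(hits)])
    sh <- c(sh, si[S4Vectors_to(hits)])
  }
  data.frame(query = qh, subject = sh)
}

S4Vectors_from <- function(hits) methods::slot(hits, "from")
S4Vectors_to <- function(hits) methods::slot(hits, "to")
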