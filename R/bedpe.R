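# Anchor pairs are data.frames with columns chrom1, start1, end1, chrom2,
# start2, end2, and where defined: distance, label, score. Intra-chromosomal
# pairs are normalized so the left anchor has the smaller start.

#' Construct an anchor-pair table
#'
#' Pairs are normalized so that, within a chromosome, the left anchor is
#' the one with the smaller start. The midpoint distance is recomputed for
#' intra-chromosomal pairs; inter-chromosomal pairs get `NA` distance and
#' `inter_chrom = TRUE` (they are retained at the IO layer but excluded
#' from dataset construction).
#'
#' @param chrom1,start1,end1 Left anchor coordinates (0-based half-open).
#' @param chrom2,start2,end2 Right anchor coordinates.
#' @param score Optional numeric score per pair.
#' @param label Optional label per pair (`"positive"`, `"negative"`, `"unknown"`).
#' @return Pair `data.frame` with recomputed `distance` and `inter_chrom`.
#' @export
anchor_pairs <- function(chrom1, start1, end1, chrom2, start2, end2,
                         score = NULL, label = NULL) {
  df <- data.frame(chrom1 = as.character(chrom1), start1 = as.integer(start1),
                   end1 = as.integer(end1), chrom2 = as.character(chrom2),
                   start2 = as.integer(start2), end2 = as.integer(end2),
                   stringsAsFactors = FALSE)
  stop_if(any(df$start1 < 0L | df$start1 >= df$end1 |
                df$start2 < 0L | df$start2 >= df$end2),
          "invalid anchor coordinates")
  swap <- df$chrom1 == df$chrom2 & df$start2 < df$start1
  if (any(swap)) {
    tmp <- df[swap, c("chrom2", "start2", "end2")]
    df[swap, c("chrom2", "start2", "end2")] <-
      df[swap, c("chrom1", "start1", "end1")]
    df[swap, c("chrom1", "start1", "end1")] <- tmp
  }
  df$inter_chrom <- df$chrom1 != df$chrom2
  df$distance <- rep(NA_integer_, nrow(df))
  intra <- !df$inter_chrom
  if (any(intra)) {
    df$distance[intra] <- pair_distance(df$chrom1[intra], df$start1[intra],
                                        df$end1[intra], df$chrom2[intra],
                                        df$start2[intra], df$end2[intra])
  }
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(label)) df$label <- as.character(label)
  df
}

#' Read a BEDPE loop file
#'
#' Requires at least six tab-separated columns (chrom1, start1, end1,
#' chrom2, start2, end2); a seventh column is taken as a name and an eighth
#' as a numeric score (six-plus-score files with a numeric seventh column
#' are also accepted). Pairs are normalized into genomic order.
#' Inter-chromosomal rows are retained but flagged `inter_chrom`.
#'
#' @param path Path to a BEDPE file.
#' @return Pair `data.frame`; see [anchor_pairs()].
#' @export
read_bedpe <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(anchor_pairs(character(), integer(), integer(),
                        character(), integer(), integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  stop_if(any(ncol < 6L),
          "BEDPE parse error at line ", which(ncol < 6L)[1L],
          ": fewer than 6 columns")
  get <- function(j) vapply(fields, `[[`, character(1), j)
  coords <- lapply(c(2L, 3L, 5L, 6L), function(j) {
    suppressWarnings(as.integer(get(j)))
  })
  bad <- which(Reduce(`|`, lapply(coords, is.na)))
  stop_if(length(bad) > 0L,
          "BEDPE parse error at line ", bad[1L], ": non-integer coordinates")
  score <- NULL
  if (min(ncol) >= 8L) {
    score <- suppressWarnings(as.numeric(get(8L)))
  } else if (min(ncol) == 7L) {
    s7 <- suppressWarnings(as.numeric(get(7L)))
    if (!anyNA(s7)) score <- s7
  }
  anchor_pairs(get(1L), coords[[1L]], coords[[2L]],
               get(4L), coords[[3L]], coords[[4L]], score = score)
}

#' Write anchor pairs as BEDPE
#'
#' Emits `chrom1 start1 end1 chrom2 start2 end2 name score` when a score
#' column is present, otherwise the six coordinate columns. Round-tripping
#' through [read_bedpe()] reproduces the pairs up to anchor-order
#' normalization.
#'
#' @param pairs Pair `data.frame`.
#' @param path Output path.
#' @export
write_bedpe <- function(pairs, path) {
  df <- pairs[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2")]
  if (!is.null(pairs$score)) {
    df$name <- sprintf("pair_%d", seq_len(nrow(pairs)))
    df$score <- pairs$score
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Canonical string key of a pair, used for deduplication and presence rows.
pair_key <- function(pairs) {
  paste(pairs$chrom1, pairs$start1, pairs$end1,
        pairs$chrom2, pairs$start2, pairs$end2, sep = ":")
}
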