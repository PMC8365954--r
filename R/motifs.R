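# Interpretation: convolutional kernels -> position weight matrices,
# motif database matching with a column-shuffle null, detection counts
# across models, and the convergent-orientation importance analysis.

#' Construct a position weight matrix
#'
#' @param mat Numeric matrix (width x 4), columns in order A, C, G, T;
#'   rows must be non-negative and sum to 1 (tolerance 1e-6).
#' @param name Motif name.
#' @param source `"kernel"` or `"database"`.
#' @return A `pwm` object.
#' @export
pwm <- function(mat, name = "pwm", source = c("kernel", "database")) {
  source <- match.arg(source)
  mat <- as.matrix(mat)
  stop_if(ncol(mat) != 4L, "PWM must have 4 columns (A,C,G,T)")
  stop_if(any(mat < 0), "PWM entries must be non-negative")
  rs <- rowSums(mat)
  stop_if(any(abs(rs - 1) > 1e-6), "PWM rows must sum to 1")
  colnames(mat) <- c("A", "C", "G", "T")
  structure(list(mat = mat, name = name, source = source), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (%s), width %d, consensus %s\n", x$name, x$source,
              nrow(x$mat), pwm_consensus(x)))
  invisible(x)
}

#' Consensus string of a PWM
#' @param x A `pwm`.
#' @return Character scalar (argmax base per position).
#' @export
pwm_consensus <- function(x) {
  paste(c("A", "C", "G", "T")[max.col(x$mat, ties.method = "first")],
        collapse = "")
}

# Reverse complement of a PWM: reverse positions, swap A<->T and C<->G.
pwm_rc <- function(x) {
  m <- x$mat[rev(seq_len(nrow(x$mat))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(m) <- c("A", "C", "G", "T")
  pwm(m, name = x$name, source = x$source)
}

#' Read motifs in MEME minimal format
#'
#' @param path Path to a MEME minimal motif file.
#' @return Named list of `pwm` objects (source `"database"`).
#' @export
read_meme <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s", lines)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[s])), "\\s+")[[1]][1]
    hdr <- s + which(grepl("letter-probability matrix", lines[(s + 1):length(lines)]))[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- do.call(rbind, lapply(rows, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:4])))
    mat <- mat / rowSums(mat)
    out[[name]] <- pwm(mat, name = name, source = "database")
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param pwms Named list of `pwm` objects.
#' @param path Output path.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(p$mat)), con)
    utils::write.table(format(p$mat, digits = 6), con, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs in JASPAR PFM text format
#'
#' Count matrices (`>ID name` header, then `A [ ... ]` rows) are
#' normalized to probabilities.
#'
#' @param path Path to a JASPAR PFM file.
#' @return Named list of `pwm` objects.
#' @export
read_jaspar <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  starts <- grep("^>", lines)
  out <- list()
  for (s in starts) {
    name <- strsplit(sub("^>", "", lines[s]), "\\s+")[[1]][1]
    rows <- lines[(s + 1):(s + 4)]
    vals <- lapply(rows, function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[?", "", l)
      l <- gsub("\\]", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    mat <- t(do.call(rbind, vals))  # width x 4, rows were A,C,G,T
    mat <- (mat + 1e-9) / rowSums(mat + 1e-9)
    out[[name]] <- pwm(mat, name = name, source = "database")
  }
  out
}

#' Derive PWMs from convolutional kernels
#'
#' DeepBind-style extraction: kernel-width subsequences are scored by the
#' layer's convolution; for each kernel, the windows whose response
#' exceeds `activation_quantile` times that kernel's maximum response
#' (and is positive) are aligned and per-position base counts with
#' pseudocount 1 are normalized to a PWM. Kernels with fewer than
#' `min_count` activating windows are marked inactive (`NULL`).
#'
#' For `layer = "last"`, windows span the kernel's receptive field and
#' responses are the last-layer activations at the single covered
#' position.
#'
#' @param extractor A (typically trained) `loop_extractor`.
#' @param probe_sequences Character vector of probe sequences; windows
#'   are taken at `stride` (at least 10,000 windows recommended).
#' @param layer `"first"` or `"last"` convolutional layer.
#' @param activation_quantile Fraction of the per-kernel maximum response
#'   used as the activation threshold (default 0.5).
#' @param min_count Minimum number of activating windows (default 10).
#' @param stride Window stride in bp (default 1, scanning every
#'   position; larger strides subsample the probe windows).
#' @return List (one element per kernel) of `pwm` objects or `NULL` for
#'   inactive kernels; attribute `n_activating` holds the counts.
#' @export
kernels_to_pwms <- function(extractor, probe_sequences,
                            layer = c("first", "last"),
                            activation_quantile = 0.5, min_count = 10L,
                            stride = 1L) {
  layer <- match.arg(layer)
  cfg <- extractor$config
  if (!extractor$trained) {
    warning("extractor is untrained; derived PWMs will be near-uniform")
  }
  w <- if (layer == "first") cfg$width1 else
    cfg$width2 * cfg$pool + cfg$width1 - 1L
  k <- if (layer == "first") cfg$n_kernels1 else cfg$n_kernels2
  stride <- max(1L, as.integer(stride))
  wins <- character(0)
  for (s in probe_sequences) {
    n <- nchar(s)
    if (n < w) next
    starts <- seq(1L, n - w + 1L, by = stride)
    wins <- c(wins, substring(s, starts, starts + w - 1L))
  }
  wins <- wins[!grepl("N", wins, fixed = TRUE)]
  stop_if(length(wins) == 0L, "no probe windows available")
  codes <- seqs_to_code_matrix(wins, w)
  acts <- if (layer == "first") {
    cpp_conv1_scores(codes, extractor$params, extractor$config)
  } else {
    cfg2 <- cfg
    cfg2$input_length <- w
    cpp_extract_features(codes, extractor$params, cfg2, FALSE)
  }
  base_mat <- t(codes) + 1L  # m x w, values 1..4
  out <- vector("list", k)
  n_act <- integer(k)
  for (r in seq_len(k)) {
    a <- acts[, r]
    pos <- a[a > 0]
    if (length(pos) == 0L) { n_act[r] <- 0L; next }
    thr <- activation_quantile * max(a)
    sel <- which(a > thr & a > 0)
    n_act[r] <- length(sel)
    if (length(sel) < min_count) next
    counts <- matrix(1, nrow = w, ncol = 4)  # pseudocount
    for (b in 1:4) {
      counts[, b] <- counts[, b] + colSums(base_mat[sel, , drop = FALSE] == b)
    }
    out[[r]] <- pwm(counts / rowSums(counts),
                    name = sprintf("%s_kernel_%02d", layer, r),
                    source = "kernel")
  }
  names(out) <- sprintf("kernel_%02d", seq_len(k))
  attr(out, "n_activating") <- n_act
  out
}

# Pearson correlation of aligned PWM columns maximized over offsets with
# at least min_overlap overlapping positions. Offsets are ranked by the
# correlation weighted by the square root of the aligned width, so that
# short alignments against low-complexity stretches (e.g. a run of
# identical columns) cannot outrank a full-width match; the reported
# similarity is the plain correlation at the winning offset.
pwm_similarity_oriented <- function(qmat, tmat, min_overlap = 5L) {
  qw <- nrow(qmat); tw <- nrow(tmat)
  best <- -Inf; best_r <- -Inf; best_off <- 0L
  for (off in seq(-(qw - min_overlap), tw - min_overlap)) {
    qi <- max(1L, 1L - off); qe <- min(qw, tw - off)
    ov <- qe - qi + 1L
    if (ov < min_overlap) next
    q <- as.vector(qmat[qi:qe, , drop = FALSE])
    t <- as.vector(tmat[(qi + off):(qe + off), , drop = FALSE])
    if (stats::sd(q) == 0 || stats::sd(t) == 0) next
    r <- stats::cor(q, t)
    sc <- r * sqrt(ov)
    if (sc > best) { best <- sc; best_r <- r; best_off <- off }
  }
  list(similarity = best_r, offset = best_off, score = best)
}

#' Similarity of two PWMs
#'
#' Maximum Pearson correlation of aligned columns over all offsets (at
#' least `min_overlap` overlapping positions) and both orientations.
#'
#' @param query,target `pwm` objects.
#' @param min_overlap Minimum aligned positions (default 5).
#' @return List with `similarity`, `offset`, `orientation` (`"+"`/`"-"`).
#' @export
pwm_similarity <- function(query, target, min_overlap = 5L) {
  fwd <- pwm_similarity_oriented(query$mat, target$mat, min_overlap)
  rev <- pwm_similarity_oriented(pwm_rc(query)$mat, target$mat, min_overlap)
  if (fwd$score >= rev$score) {
    list(similarity = fwd$similarity, offset = fwd$offset, orientation = "+",
         score = fwd$score)
  } else {
    list(similarity = rev$similarity, offset = rev$offset, orientation = "-",
         score = rev$score)
  }
}

#' Match a PWM against a motif database
#'
#' Tomtom-like matching: candidate alignments over all offsets and both
#' orientations are ranked by Pearson correlation weighted by the square
#' root of the aligned width (so short alignments to low-complexity
#' column runs cannot dominate), and the correlation at the winning
#' alignment is reported as the similarity. Significance is an empirical
#' p-value of that weighted score against `n_shuffles`
#' column(position)-shuffled versions of the query. Matches are sorted by
#' p-value, ties by decreasing similarity.
#'
#' @param query A `pwm` (width at least 5).
#' @param database Named list of `pwm`s (e.g. from [read_meme()] or
#'   [read_jaspar()]).
#' @param n_shuffles Number of shuffled nulls (default 200).
#' @param seed Integer seed for the shuffles.
#' @param min_overlap Minimum aligned positions (default 5).
#' @return `data.frame` with columns `query`, `target`, `offset`,
#'   `orientation`, `similarity`, `p_value`.
#' @export
match_pwm_to_database <- function(query, database, n_shuffles = 200L,
                                  seed = 1L, min_overlap = 5L) {
  stop_if(nrow(query$mat) < 5L, "query PWM width must be >= 5")
  stop_if(length(database) == 0L, "empty motif database")
  obs <- lapply(database, pwm_similarity, query = query,
                min_overlap = min_overlap)
  shuffles <- with_seed(seed, {
    lapply(seq_len(n_shuffles), function(i)
      query$mat[sample.int(nrow(query$mat)), , drop = FALSE])
  })
  pvals <- vapply(seq_along(database), function(j) {
    tmat <- database[[j]]$mat
    o <- obs[[j]]$score
    null_ge <- vapply(shuffles, function(sm) {
      f <- pwm_similarity_oriented(sm, tmat, min_overlap)$score
      smr <- sm[rev(seq_len(nrow(sm))), c(4, 3, 2, 1), drop = FALSE]
      r <- pwm_similarity_oriented(smr, tmat, min_overlap)$score
      max(f, r) >= o
    }, logical(1))
    (1 + sum(null_ge)) / (n_shuffles + 1)
  }, numeric(1))
  out <- data.frame(query = query$name,
                    target = names(database),
                    offset = vapply(obs, `[[`, numeric(1), "offset"),
                    orientation = vapply(obs, `[[`, character(1), "orientation"),
                    similarity = vapply(obs, `[[`, numeric(1), "similarity"),
                    p_value = pvals, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -out$similarity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif detection counts across models
#'
#' For each extractor, derives first-layer kernel PWMs, matches every
#' active kernel against the database, adjusts the kernel-by-motif
#' p-values with Benjamini-Hochberg, and counts how many kernels have
#' each motif as their best match at adjusted p <= `alpha`.
#'
#' @param extractors Named list of trained `loop_extractor`s.
#' @param database Named list of database `pwm`s.
#' @param probe_sequences Probe sequences for [kernels_to_pwms()].
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param n_shuffles,seed Passed to [match_pwm_to_database()].
#' @return Integer matrix, motifs x models.
#' @export
motif_detection_counts <- function(extractors, database, probe_sequences,
                                   alpha = 0.05, n_shuffles = 200L,
                                   seed = 1L) {
  counts <- matrix(0L, nrow = length(database), ncol = length(extractors),
                   dimnames = list(names(database), names(extractors)))
  for (m in seq_along(extractors)) {
    pwms <- kernels_to_pwms(extractors[[m]], probe_sequences, layer = "first")
    active <- which(!vapply(pwms, is.null, logical(1)))
    if (length(active) == 0L) next
    matches <- lapply(active, function(r)
      match_pwm_to_database(pwms[[r]], database, n_shuffles = n_shuffles,
                            seed = seed + r))
    all_p <- unlist(lapply(matches, `[[`, "p_value"))
    adj <- stats::p.adjust(all_p, method = "BH")
    k <- 0L
    for (i in seq_along(matches)) {
      mm <- matches[[i]]
      mm$p_adj <- adj[k + seq_len(nrow(mm))]
      k <- k + nrow(mm)
      best <- mm[1L, ]
      if (best$p_adj <= alpha) {
        counts[best$target, m] <- counts[best$target, m] + 1L
      }
    }
  }
  counts
}

#' Convergent-orientation importance analysis
#'
#' Summarizes a stage-2 importance report into the convergence signature:
#' mean importance per (anchor, orientation) block; Pearson correlations
#' of kernel-matched importance vectors for the four cross-anchor block
#' pairings; a convergence flag that is true iff one convergent block
#' combination (left-F with right-RC, or left-RC with right-F) dominates
#' the opposite combination in mean importance AND its cross-strand
#' correlation exceeds the mean same-strand correlation; and the kernel
#' behind the single most important sequence feature.
#'
#' @param importances Importance report from
#'   [feature_importance_report()] with full block mapping.
#' @return List with `block_means`, `correlations` (named: `LF_RF`,
#'   `LF_RRC`, `LRC_RF`, `LRC_RRC`), `convergent`, `orientation`
#'   (`"LF_RRC"`, `"LRC_RF"` or `NA`), and `top_kernel`.
#' @export
convergence_analysis <- function(importances) {
  stop_if(is.null(importances$block) || is.null(importances$kernel),
          "importance records lack block mapping")
  seqimp <- importances[importances$block %in% BLOCKS, , drop = FALSE]
  stop_if(any(!BLOCKS %in% seqimp$block), "importance records lack block mapping")
  vecs <- lapply(BLOCKS, function(b) {
    df <- seqimp[seqimp$block == b, , drop = FALSE]
    df <- df[order(df$kernel), , drop = FALSE]
    stats::setNames(df$importance, df$kernel)
  })
  names(vecs) <- BLOCKS
  block_means <- vapply(vecs, mean, numeric(1))
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("degenerate importance vector; correlation undefined")
      return(NA_real_)
    }
    stats::cor(a, b)
  }
  correlations <- c(
    LF_RF = safe_cor(vecs$left_F, vecs$right_F),
    LF_RRC = safe_cor(vecs$left_F, vecs$right_RC),
    LRC_RF = safe_cor(vecs$left_RC, vecs$right_F),
    LRC_RRC = safe_cor(vecs$left_RC, vecs$right_RC))
  conv1 <- block_means[["left_F"]] + block_means[["right_RC"]]
  conv2 <- block_means[["left_RC"]] + block_means[["right_F"]]
  same <- mean(correlations[c("LF_RF", "LRC_RRC")], na.rm = TRUE)
  orientation <- NA_character_
  convergent <- FALSE
  if (conv1 > conv2 && is.finite(correlations[["LF_RRC"]]) &&
      !is.nan(same) && correlations[["LF_RRC"]] > same) {
    convergent <- TRUE; orientation <- "LF_RRC"
  } else if (conv2 > conv1 && is.finite(correlations[["LRC_RF"]]) &&
             !is.nan(same) && correlations[["LRC_RF"]] > same) {
    convergent <- TRUE; orientation <- "LRC_RF"
  }
  top <- seqimp[which.max(seqimp$importance), , drop = FALSE]
  list(block_means = block_means, correlations = correlations,
       convergent = convergent, orientation = orientation,
       top_kernel = top$kernel[1L], top_feature = top$feature[1L])
}
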