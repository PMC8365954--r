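# The sequence feature extractor: a small two-layer convolutional network
# applied to both anchors of a pair in both orientations, pretrained with
# a dense head on interaction labels and then frozen as a fixed feature
# map for the boosted classifiers.

BLOCKS <- c("left_F", "left_RC", "right_F", "right_RC")

#' Build a sequence feature extractor
#'
#' Constructs the convolutional feature extractor: conv layer 1 (kernels
#' scanning one-hot DNA), non-overlapping max pooling, ReLU, conv layer 2,
#' ReLU, and global max pooling yielding one feature per last-layer
#' kernel. Two convolutional layers are required so that both first-layer
#' kernels (motif matching) and last-layer kernels (top important
#' features) can be interpreted. Parameter initialization is He-scaled
#' Gaussian and deterministic under `seed`.
#'
#' @param input_length Input window length L in bp, centered on the anchor
#'   midpoint (default 1000).
#' @param n_kernels1,width1 First conv layer: number of kernels and kernel
#'   width in bp (defaults 64 and 19, DeepBind-scale).
#' @param pool Max-pooling width (default 10, non-overlapping).
#' @param n_kernels2,width2 Second conv layer (defaults 32 and 11).
#' @param hidden Width of the dense pretraining head (default 128).
#' @param seed Integer seed for parameter initialization.
#' @return A `loop_extractor` object.
#' @export
build_extractor <- function(input_length = 1000L, n_kernels1 = 64L,
                            width1 = 19L, pool = 10L, n_kernels2 = 32L,
                            width2 = 11L, hidden = 128L, seed = 1L) {
  config <- list(input_length = as.integer(input_length),
                 n_kernels1 = as.integer(n_kernels1),
                 width1 = as.integer(width1), pool = as.integer(pool),
                 n_kernels2 = as.integer(n_kernels2),
                 width2 = as.integer(width2), hidden = as.integer(hidden))
  p1 <- config$input_length - config$width1 + 1L
  q <- p1 %/% config$pool
  p2 <- q - config$width2 + 1L
  stop_if(p1 < 1L || q < 1L || p2 < 1L,
          "extractor config yields a non-positive spatial size")
  k1 <- config$n_kernels1; w1 <- config$width1
  k2 <- config$n_kernels2; w2 <- config$width2; h <- config$hidden
  params <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(k1 * 4 * w1, sd = sqrt(2 / (4 * w1))), k1, 4 * w1),
    b1 = matrix(0, k1, 1),
    W2 = matrix(stats::rnorm(k2 * k1 * w2, sd = sqrt(2 / (k1 * w2))), k2, k1 * w2),
    b2 = matrix(0, k2, 1),
    Wd1 = matrix(stats::rnorm(h * 4 * k2, sd = sqrt(2 / (4 * k2))), h, 4 * k2),
    bd1 = matrix(0, h, 1),
    wd2 = matrix(stats::rnorm(h, sd = sqrt(2 / h)), h, 1),
    bd2 = matrix(0, 1, 1)))
  structure(list(config = config, params = params, seed = as.integer(seed),
                 trained = FALSE, frozen = FALSE, log = NULL,
                 best_epoch = NA_integer_),
            class = "loop_extractor")
}

#' @export
print.loop_extractor <- function(x, ...) {
  cfg <- x$config
  cat("Sequence feature extractor (loop_extractor)\n")
  cat(sprintf("  input length       %d bp\n", cfg$input_length))
  cat(sprintf("  conv layer 1       %d kernels x %d bp\n",
              cfg$n_kernels1, cfg$width1))
  cat(sprintf("  max pooling        width %d\n", cfg$pool))
  cat(sprintf("  conv layer 2       %d kernels x %d bp\n",
              cfg$n_kernels2, cfg$width2))
  cat(sprintf("  pair feature dim   %d (4 blocks x %d kernels)\n",
              4L * cfg$n_kernels2, cfg$n_kernels2))
  cat(sprintf("  trained: %s   frozen: %s\n",
              if (x$trained) sprintf("yes (best epoch %d)", x$best_epoch)
              else "no",
              if (x$frozen) "yes" else "no"))
  invisible(x)
}

# L-bp window centered on each anchor midpoint, clamped to the chromosome;
# returns a codes matrix (L x n).
anchor_code_matrix <- function(genome, chrom, start, end, L) {
  genome_chr <- if (is.character(genome)) genome else as.character(genome)
  lens <- chrom_lengths(genome_chr)
  mid <- (as.numeric(start) + as.numeric(end)) %/% 2
  ws <- pmax(0, mid - L %/% 2)
  we <- pmin(as.numeric(lens[chrom]), ws + L)
  ws <- pmax(0, we - L)
  seqs <- character(length(chrom))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    s <- substring(genome_chr[[ch]], ws[idx] + 1, we[idx])
    s <- toupper(s)
    seqs[idx] <- s
  }
  seqs <- gsub("[^ACGT]", "N", seqs)
  seqs_to_code_matrix(seqs, L)
}

#' Extract pair features from explicit sequences
#'
#' Runs the extractor over the left and right anchor sequences in both
#' orientations and concatenates the four blocks in the fixed order
#' left-F, left-RC, right-F, right-RC. Replacing a sequence by its
#' reverse complement exactly swaps that anchor's F and RC blocks.
#'
#' @param extractor A `loop_extractor`.
#' @param left_seq,right_seq Character vectors of anchor sequences
#'   (centered/padded to the configured input length).
#' @return Numeric matrix (`n x 4K`) with block-annotated column names;
#'   attribute `block_map` maps each feature index to (block, kernel).
#' @export
extract_pair_features <- function(extractor, left_seq, right_seq) {
  L <- extractor$config$input_length
  cl <- seqs_to_code_matrix(left_seq, L)
  cr <- seqs_to_code_matrix(right_seq, L)
  fl <- cpp_extract_features(cl, extractor$params, extractor$config, FALSE)
  flr <- cpp_extract_features(cl, extractor$params, extractor$config, TRUE)
  fr <- cpp_extract_features(cr, extractor$params, extractor$config, FALSE)
  frr <- cpp_extract_features(cr, extractor$params, extractor$config, TRUE)
  out <- cbind(fl, flr, fr, frr)
  colnames(out) <- feature_names(extractor$config$n_kernels2)
  attr(out, "block_map") <- feature_block_map(extractor$config$n_kernels2)
  out
}

feature_names <- function(k2) {
  as.vector(vapply(BLOCKS, function(b)
    sprintf("%s_k%02d", b, seq_len(k2)), character(k2)))
}

feature_block_map <- function(k2) {
  data.frame(feature = feature_names(k2),
             block = rep(BLOCKS, each = k2),
             kernel = rep(seq_len(k2), times = 4L),
             stringsAsFactors = FALSE)
}

#' Featurize anchor pairs from a genome
#'
#' Fetches the input window of every distinct anchor once, runs the
#' extractor in both orientations, and assembles the pair feature matrix
#' (optionally with the raw midpoint distance in bp as a final column).
#'
#' @param extractor A `loop_extractor`.
#' @param pairs Pair `data.frame`.
#' @param genome Named `DNAStringSet` or character vector.
#' @param include_distance Append the `distance` column? (default `FALSE`)
#' @return Numeric feature matrix with `block_map` attribute.
#' @export
featurize_pairs <- function(extractor, pairs, genome,
                            include_distance = FALSE) {
  anc <- rbind(data.frame(chrom = pairs$chrom1, start = pairs$start1,
                          end = pairs$end1, stringsAsFactors = FALSE),
               data.frame(chrom = pairs$chrom2, start = pairs$start2,
                          end = pairs$end2, stringsAsFactors = FALSE))
  key <- paste(anc$chrom, anc$start, anc$end)
  ukey <- unique(key)
  uanc <- anc[match(ukey, key), , drop = FALSE]
  L <- extractor$config$input_length
  codes <- anchor_code_matrix(genome, uanc$chrom, uanc$start, uanc$end, L)
  fF <- cpp_extract_features(codes, extractor$params, extractor$config, FALSE)
  fRC <- cpp_extract_features(codes, extractor$params, extractor$config, TRUE)
  n <- nrow(pairs)
  il <- match(key[seq_len(n)], ukey)
  ir <- match(key[n + seq_len(n)], ukey)
  out <- cbind(fF[il, , drop = FALSE], fRC[il, , drop = FALSE],
               fF[ir, , drop = FALSE], fRC[ir, , drop = FALSE])
  colnames(out) <- feature_names(extractor$config$n_kernels2)
  if (include_distance) {
    out <- cbind(out, distance = as.numeric(pairs$distance))
  }
  attr(out, "block_map") <- feature_block_map(extractor$config$n_kernels2)
  out
}

# Discriminative k-mer seeding of first-layer kernels. Counts k-mers in
# positive vs negative training anchor sequences and seeds each kernel
# with one of the most positively enriched k-mers, centered in the kernel
# (match weight +0.75, mismatch -0.25, so columns are zero-mean), with the
# random initialization retained at low amplitude elsewhere so gradients
# can grow flanking positions. Randomly initialized convolutional kernels
# rarely align with any shared motif, so gradient descent tends to
# memorize individual anchors instead of discovering shared sequence
# features at the sample sizes used here; enriched-k-mer seeding points
# the kernels at discriminative sequence content while leaving all
# refinement to training.
kmer_seed_kernels <- function(extractor, train_pairs, genome, k = 8L,
                              max_anchors = 600L, seed = 1L) {
  w1 <- extractor$config$width1
  k <- min(k, w1)
  y <- as_binary_labels(train_pairs$label)
  with_seed(seed, {
    anchor_seqs <- function(pp, nmax) {
      anc <- positive_anchor_set(pp)
      if (nrow(anc) > nmax) anc <- anc[sample.int(nrow(anc), nmax), ]
      vapply(seq_len(nrow(anc)), function(i)
        fetch_sequence(genome, anc$chrom[i], anc$start[i], anc$end[i]),
        character(1))
    }
    count_kmers <- function(seqs) {
      tabs <- lapply(seqs, function(s) {
        n <- nchar(s)
        if (n < k) return(character(0))
        substring(s, 1:(n - k + 1), k:n)
      })
      kms <- unlist(tabs)
      kms <- kms[!grepl("N", kms, fixed = TRUE)]
      table(kms)
    }
    pos_tab <- count_kmers(anchor_seqs(train_pairs[y == 1L, ], max_anchors))
    neg_tab <- count_kmers(anchor_seqs(train_pairs[y == 0L, ], max_anchors))
    all_kmers <- union(names(pos_tab), names(neg_tab))
    pc <- as.numeric(pos_tab[all_kmers]); pc[is.na(pc)] <- 0
    nc <- as.numeric(neg_tab[all_kmers]); nc[is.na(nc)] <- 0
    # two-proportion z-score of per-window k-mer frequency; favors
    # consistently enriched k-mers over low-count zero-negative flukes
    fp <- pc / (sum(pc) + 1)
    fn <- nc / (sum(nc) + 1)
    fbar <- (pc + nc) / (sum(pc) + sum(nc) + 1)
    score <- (fp - fn) /
      sqrt(fbar * (1 - fbar) * (1 / (sum(pc) + 1) + 1 / (sum(nc) + 1)))
    top <- all_kmers[order(-score)]
    k1 <- extractor$config$n_kernels1
    top <- top[seq_len(min(k1, length(top)))]
    W1 <- 0.05 * extractor$params$W1
    off <- (w1 - k) %/% 2L
    for (r in seq_along(top)) {
      codes <- seq_to_codes(top[r], k)
      for (j in seq_len(k)) {
        cols <- 4L * (off + j - 1L) + (1:4)
        W1[r, cols] <- -0.25
        W1[r, cols[codes[j] + 1L]] <- 0.75
      }
    }
    extractor$params$W1 <- W1
  })
  extractor
}

#' Pretrain the feature extractor (stage 1)
#'
#' Trains extractor plus dense head end-to-end on a distance-matched
#' dataset with a chromosome-holdout validation split, minimizing weighted
#' binary cross-entropy on interaction labels. Class imbalance is handled
#' by down-weighting negatives to an effective 1:1. Early stopping
#' monitors validation auPRC; the returned extractor carries the
#' parameters of the best validation epoch and the per-epoch training log.
#' Training is single-threaded and byte-reproducible under `seed`.
#'
#' @param extractor An untrained, unfrozen `loop_extractor`.
#' @param train_pairs,val_pairs Labeled pair `data.frame`s (both classes
#'   must be present in `train_pairs`).
#' @param genome Named `DNAStringSet` or character vector.
#' @param epochs Maximum epochs (default 30).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Pairs per gradient step (default 128).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param kernel_init `"kmer"` (default) seeds first-layer kernels with
#'   the k-mers most enriched in positive versus negative training
#'   anchors before gradient training (randomly initialized kernels
#'   rarely align with shared motifs and training then memorizes
#'   individual anchors); `"random"` keeps the He initialization.
#' @param seed Integer seed (shuffling order and k-mer seeding;
#'   the He initialization is fixed by [build_extractor()]).
#' @return The trained `loop_extractor` with `log` (epoch, train loss,
#'   validation auPRC) and `best_epoch`.
#' @export
train_stage1 <- function(extractor, train_pairs, val_pairs, genome,
                         epochs = 30L, learning_rate = 1e-3,
                         batch_size = 128L, patience = 5L,
                         kernel_init = c("kmer", "random"), seed = 1L) {
  kernel_init <- match.arg(kernel_init)
  stop_if(extractor$frozen, "extractor is frozen; training is not allowed")
  y <- as_binary_labels(train_pairs$label)
  stop_if(length(unique(y)) < 2L, "training set must contain both classes")
  stop_if(nrow(val_pairs) == 0L, "validation set is empty")
  if (kernel_init == "kmer") {
    extractor <- kmer_seed_kernels(extractor, train_pairs, genome,
                                   seed = seed + 1L)
  }
  L <- extractor$config$input_length
  seqL <- anchor_code_matrix(genome, train_pairs$chrom1, train_pairs$start1,
                             train_pairs$end1, L)
  seqR <- anchor_code_matrix(genome, train_pairs$chrom2, train_pairs$start2,
                             train_pairs$end2, L)
  vL <- anchor_code_matrix(genome, val_pairs$chrom1, val_pairs$start1,
                           val_pairs$end1, L)
  vR <- anchor_code_matrix(genome, val_pairs$chrom2, val_pairs$start2,
                           val_pairs$end2, L)
  vy <- as_binary_labels(val_pairs$label)
  n <- length(y)
  w <- ifelse(y == 1L, 1, sum(y == 1L) / max(1L, sum(y == 0L)))
  perms <- with_seed(seed, {
    t(vapply(seq_len(epochs), function(e) sample.int(n), integer(n)))
  })
  fit <- cpp_train_stage1(seqL, seqR, as.numeric(y), as.numeric(w),
                          vL, vR, as.numeric(vy), extractor$params,
                          extractor$config,
                          list(learning_rate = learning_rate,
                               batch_size = as.integer(batch_size),
                               max_epochs = as.integer(epochs),
                               patience = as.integer(patience)),
                          perms)
  extractor$params <- fit$params
  extractor$log <- as.data.frame(fit$log)
  extractor$trained <- TRUE
  extractor$best_epoch <- fit$best_epoch
  extractor
}

#' Freeze a trained extractor
#'
#' After stage-1 pretraining the extractor is frozen: its parameters
#' become immutable and any attempt to train it again is an explicit
#' error, so later classifier stages leave it bit-identical.
#'
#' @param extractor A trained `loop_extractor`.
#' @return The extractor with `frozen = TRUE`.
#' @export
freeze <- function(extractor) {
  extractor$frozen <- TRUE
  extractor
}

#' Score pairs with the stage-1 head
#'
#' Predicted interaction probability from extractor + dense pretraining
#' head (used for stage-1 monitoring; later stages replace the head with
#' gradient-boosted trees).
#'
#' @param extractor A trained `loop_extractor`.
#' @param pairs Pair `data.frame`.
#' @param genome Named `DNAStringSet` or character vector.
#' @return Numeric vector of probabilities.
#' @export
predict_stage1 <- function(extractor, pairs, genome) {
  L <- extractor$config$input_length
  seqL <- anchor_code_matrix(genome, pairs$chrom1, pairs$start1,
                             pairs$end1, L)
  seqR <- anchor_code_matrix(genome, pairs$chrom2, pairs$start2,
                             pairs$end2, L)
  cpp_predict_head(seqL, seqR, extractor$params, extractor$config)
}

#' Save / load an extractor checkpoint
#'
#' The checkpoint is self-describing JSON: architecture config, channel
#' order, all parameters at full precision, the training log and flags.
#'
#' @param extractor A `loop_extractor`.
#' @param path Checkpoint path.
#' @return `save_extractor` returns `path`; `load_extractor` returns the
#'   restored `loop_extractor`.
#' @export
save_extractor <- function(extractor, path) {
  # parameters stored as %.17g strings so the binary doubles round-trip
  # exactly (JSON number formatting is lossy at the last bits)
  params <- lapply(extractor$params, function(m)
    list(nrow = nrow(m), ncol = ncol(m),
         data = sprintf("%.17g", as.vector(m))))
  obj <- list(format = "seqloop_extractor", channel_order = c("A", "C", "G", "T"),
              config = extractor$config, seed = extractor$seed,
              trained = extractor$trained, frozen = extractor$frozen,
              best_epoch = extractor$best_epoch,
              log = extractor$log,
              params = params)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_extractor
#' @export
load_extractor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stop_if(!identical(obj$format, "seqloop_extractor"),
          "not an extractor checkpoint: ", path)
  params <- lapply(obj$params, function(p)
    matrix(as.numeric(p$data), nrow = p$nrow, ncol = p$ncol))
  structure(list(config = lapply(obj$config, as.integer),
                 params = params, seed = obj$seed,
                 trained = isTRUE(obj$trained), frozen = isTRUE(obj$frozen),
                 log = if (is.null(obj$log)) NULL else as.data.frame(obj$log),
                 best_epoch = obj$best_epoch %||% NA_integer_),
            class = "loop_extractor")
}
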