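# Synthetic data with planted convergent motifs. The generator emulates
# every input the pipeline consumes: a random genome, open chromatin
# regions, positive loops whose anchors carry a planted motif in
# convergent orientation (forward instance in the left anchor,
# reverse-complement instance in the right), distance-matched and
# extended negative tiers drawn from the remaining open regions by the
# same distance-sampling procedure as the positives, signal tracks
# enriched at positive anchors, and cohort fixtures with group-dependent
# interaction presence. Everything is deterministic under the config
# seed.

#' Default planted motif
#'
#' A sharp, non-palindromic 19-position PWM (dominant base probability
#' 0.85) whose consensus is asymmetric, so orientation effects are
#' detectable. Deliberately not any real transcription factor's PWM.
#'
#' @param dominant Probability of the consensus base (default 0.85).
#' @return A `pwm` object.
#' @export
planted_motif_pwm <- function(dominant = 0.85) {
  consensus <- "TGGCCACCAGGGGGCGCTA"
  idx <- seq_to_codes(consensus, nchar(consensus)) + 1L
  mat <- matrix((1 - dominant) / 3, nrow = nchar(consensus), ncol = 4)
  mat[cbind(seq_along(idx), idx)] <- dominant
  pwm(mat, name = "planted", source = "database")
}

#' Simulation configuration
#'
#' Bundles the study conditions for the synthetic generator. Defaults:
#' eight 8-Mb chromosomes at GC 0.5; 12,000 open regions of 500 bp;
#' 2,000 positive loops with log-normal distances (median 100 kb,
#' sdlog 1); planted-motif embedding probability 0.9 per positive anchor
#' in convergent orientation and background motif rate 0.1 per non-anchor
#' region in random orientation; negative tiers at 1:5 (distance-matched)
#' and 1:25 (extended); signal enrichment fold 4 at positive anchors; and
#' a six-sample cohort (2 uCLL-like vs 4 mCLL-like).
#'
#' @param chroms Named integer vector of chromosome lengths.
#' @param gc GC content of the background sequence.
#' @param n_regions Total open chromatin regions.
#' @param region_width Region width in bp.
#' @param n_positives Number of positive loops.
#' @param motif Planted `pwm`.
#' @param embed_prob Embedding probability per positive anchor.
#' @param background_rate Motif rate per non-anchor region.
#' @param convergent Plant convergent orientations? (forward left,
#'   reverse-complement right; if `FALSE`, random orientation).
#' @param dist_meanlog,dist_sdlog Log-normal pair-distance parameters.
#' @param ratio,ratio_extended Negative:positive ratios of the two tiers.
#' @param n_tracks,signal_baseline,signal_fold Signal-track parameters.
#' @param n_samples,groups Cohort size and group labels.
#' @param frac_differential Fraction of loops planted as differential.
#' @param presence_common,presence_high,presence_low Per-sample presence
#'   probabilities (shared loops; differential loops in their high/low
#'   group).
#' @param seed Integer master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chroms = stats::setNames(rep(8e6, 8), paste0("chr", 1:8)),
                       gc = 0.5, n_regions = 12000L, region_width = 500L,
                       n_positives = 2000L, motif = planted_motif_pwm(),
                       embed_prob = 0.9, background_rate = 0.1,
                       convergent = TRUE,
                       dist_meanlog = log(1e5), dist_sdlog = 1,
                       ratio = 5L, ratio_extended = 25L,
                       n_tracks = 3L, signal_baseline = 1, signal_fold = 4,
                       n_samples = 6L,
                       groups = c("uCLL", "uCLL", "mCLL", "mCLL", "mCLL", "mCLL"),
                       frac_differential = 0.2,
                       presence_common = 0.7, presence_high = 0.9,
                       presence_low = 0.1, seed = 13L) {
  stop_if(gc < 0 || gc > 1 || embed_prob < 0 || embed_prob > 1 ||
            background_rate < 0 || background_rate > 1,
          "probabilities must lie in [0, 1]")
  stop_if(any(chroms <= 0) || region_width <= 0 || n_positives <= 0,
          "lengths and counts must be positive")
  stop_if(length(groups) != n_samples, "one group label per sample required")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a genome and open chromatin regions
#'
#' Bases are i.i.d. at the configured GC content (order-0 background);
#' open regions are placed uniformly without overlap on each chromosome
#' (region counts proportional to chromosome length).
#'
#' @param config A `sim_config`.
#' @return List with `genome` (named character vector), `regions`
#'   (interval `data.frame`) and `chrom_lengths`.
#' @export
simulate_genome_and_regions <- function(config) {
  with_seed(config$seed, {
    probs <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
               (1 - config$gc) / 2)
    base_codes <- utf8ToInt("ACGT")
    genome <- vapply(config$chroms, function(len) {
      intToUtf8(sample(base_codes, len, replace = TRUE, prob = probs))
    }, character(1))
    n_per <- round(config$n_regions * config$chroms / sum(config$chroms))
    w <- config$region_width
    regions <- do.call(rbind, lapply(names(config$chroms), function(ch) {
      n <- n_per[[ch]]
      if (n == 0L) return(NULL)
      len <- config$chroms[[ch]]
      slack <- len - n * w
      stop_if(slack < 0, "open regions cannot fit on ", ch)
      starts <- sort(sample.int(slack + 1L, n)) - 1L + (seq_len(n) - 1L) * w
      data.frame(chrom = ch, start = as.integer(starts),
                 end = as.integer(starts + w), stringsAsFactors = FALSE)
    }))
    rownames(regions) <- NULL
    list(genome = genome, regions = regions, chrom_lengths = config$chroms)
  })
}

# Sample one base string from a PWM.
sample_motif_instance <- function(mat) {
  bases <- c("A", "C", "G", "T")
  paste(vapply(seq_len(nrow(mat)), function(i)
    sample(bases, 1L, prob = mat[i, ]), character(1)), collapse = "")
}

# Draw `n` region pairs on one chromosome by the distance-targeting
# procedure: left region uniform from `pool`, target distance log-normal,
# partner = free region with midpoint closest to the target, accepted if
# within 25% of the target. Used identically for positives and both
# negative tiers so realized distance distributions match.
draw_pairs <- function(mids, pool, n, rlog_fun, consume, forbidden_keys,
                       max_tries = 30L) {
  picked_l <- integer(0); picked_r <- integer(0)
  free <- pool
  keys <- character(0)
  tries <- 0L
  while (length(picked_l) < n && tries < max_tries * n) {
    tries <- tries + 1L
    if (length(free) < 2L) break
    li <- free[sample.int(length(free), 1L)]
    d <- rlog_fun()
    target <- mids[li] + sample(c(-1, 1), 1L) * d
    cand <- setdiff(free, li)
    ri <- cand[which.min(abs(mids[cand] - target))]
    realized <- abs(mids[ri] - mids[li])
    if (abs(realized - d) > 0.25 * d) next
    a <- min(li, ri); b <- max(li, ri)
    key <- paste(a, b)
    if (key %in% keys || key %in% forbidden_keys) next
    picked_l <- c(picked_l, a); picked_r <- c(picked_r, b)
    keys <- c(keys, key)
    if (consume) free <- setdiff(free, c(a, b))
  }
  list(left = picked_l, right = picked_r, keys = keys)
}

#' Simulate interactions with planted convergent motifs
#'
#' Positive pairs are drawn with log-normal distances over the open
#' regions; each positive left anchor receives a forward-strand motif
#' instance sampled from the planted PWM and each right anchor its
#' reverse complement (convergent), independently with the configured
#' embedding probability. Distance-matched (1:`ratio`) and extended
#' (1:`ratio_extended`) negative tiers are drawn from the regions not
#' used as positive anchors by the same distance procedure, so negative
#' distances match the positive distribution. Non-anchor regions carry
#' background motif instances in random orientation at the background
#' rate. The manifest records every planted instance.
#'
#' @param config A `sim_config`.
#' @param genome Named character vector from
#'   [simulate_genome_and_regions()].
#' @param regions Open-region interval `data.frame`.
#' @return List with `pairs` (all tiers, columns `label` and `tier`),
#'   `positives`, `genome` (with motifs written in), and `manifest`.
#' @export
simulate_interactions_with_convergent_motifs <- function(config, genome,
                                                         regions) {
  w <- config$region_width
  mw <- nrow(config$motif$mat)
  stop_if(w < mw, "anchor width shorter than the planted motif")
  with_seed(config$seed + 1L, {
    mids <- (regions$start + regions$end) %/% 2
    by_chrom <- split(seq_len(nrow(regions)), regions$chrom)
    n_per <- round(config$n_positives * lengths(by_chrom) / nrow(regions))
    rlog <- function() stats::rlnorm(1, config$dist_meanlog, config$dist_sdlog)
    pos_l <- integer(0); pos_r <- integer(0)
    neg_l <- integer(0); neg_r <- integer(0); neg_tier <- character(0)
    for (ch in names(by_chrom)) {
      idx <- by_chrom[[ch]]
      pp <- draw_pairs(mids, idx, n_per[[ch]], rlog, consume = TRUE,
                       forbidden_keys = character(0))
      pos_l <- c(pos_l, pp$left); pos_r <- c(pos_r, pp$right)
      pool <- setdiff(idx, c(pp$left, pp$right))
      nn <- draw_pairs(mids, pool, config$ratio * length(pp$left), rlog,
                       consume = FALSE, forbidden_keys = pp$keys)
      neg_l <- c(neg_l, nn$left); neg_r <- c(neg_r, nn$right)
      neg_tier <- c(neg_tier, rep("matched", length(nn$left)))
      # the extended tier is the matched tier plus extra negatives from
      # the same pool, totalling ratio_extended per positive
      ee <- draw_pairs(mids, pool,
                       (config$ratio_extended - config$ratio) * length(pp$left),
                       rlog, consume = FALSE,
                       forbidden_keys = c(pp$keys, nn$keys))
      neg_l <- c(neg_l, ee$left); neg_r <- c(neg_r, ee$right)
      neg_tier <- c(neg_tier, rep("extended_extra", length(ee$left)))
    }
    mk_pairs <- function(l, r, label) {
      p <- anchor_pairs(regions$chrom[l], regions$start[l], regions$end[l],
                        regions$chrom[r], regions$start[r], regions$end[r])
      p$label <- rep(label, nrow(p))
      p
    }
    positives <- mk_pairs(pos_l, pos_r, "positive")
    positives$tier <- "positive"
    negatives <- mk_pairs(neg_l, neg_r, "negative")
    negatives$tier <- neg_tier
    # plant motifs: genome held as integer code vectors during editing
    gcodes <- lapply(genome, utf8ToInt)
    manifest <- list()
    plant <- function(region_i, seq_str, strand, role) {
      ch <- regions$chrom[region_i]
      off <- sample.int(w - mw + 1L, 1L) - 1L
      pos0 <- regions$start[region_i] + off
      gcodes[[ch]][(pos0 + 1L):(pos0 + mw)] <<- utf8ToInt(seq_str)
      manifest[[length(manifest) + 1L]] <<- data.frame(
        chrom = ch, region_start = regions$start[region_i],
        region_end = regions$end[region_i], motif_start = pos0,
        motif_end = pos0 + mw, strand = strand, instance = seq_str,
        role = role, stringsAsFactors = FALSE)
    }
    for (i in seq_along(pos_l)) {
      if (stats::runif(1) <= config$embed_prob) {
        inst <- sample_motif_instance(config$motif$mat)
        if (config$convergent) {
          plant(pos_l[i], inst, "+", "positive_left")
        } else {
          s <- sample(c("+", "-"), 1L)
          plant(pos_l[i], if (s == "+") inst else reverse_complement(inst),
                s, "positive_left")
        }
      }
      if (stats::runif(1) <= config$embed_prob) {
        inst <- sample_motif_instance(config$motif$mat)
        if (config$convergent) {
          plant(pos_r[i], reverse_complement(inst), "-", "positive_right")
        } else {
          s <- sample(c("+", "-"), 1L)
          plant(pos_r[i], if (s == "+") inst else reverse_complement(inst),
                s, "positive_right")
        }
      }
    }
    non_anchor <- setdiff(seq_len(nrow(regions)), c(pos_l, pos_r))
    for (i in non_anchor) {
      if (stats::runif(1) <= config$background_rate) {
        inst <- sample_motif_instance(config$motif$mat)
        s <- sample(c("+", "-"), 1L)
        plant(i, if (s == "+") inst else reverse_complement(inst),
              s, "background")
      }
    }
    genome <- vapply(gcodes, intToUtf8, character(1))
    manifest <- if (length(manifest) > 0L) do.call(rbind, manifest)
    else data.frame()
    pairs <- rbind(positives, negatives)
    rownames(pairs) <- NULL
    list(pairs = pairs, positives = positives, genome = genome,
         manifest = manifest)
  })
}

#' Simulate signal tracks and cohort fixtures
#'
#' Signal tracks: per track, every open region gets a log-normal
#' perturbation of the baseline value; regions that are positive-loop
#' anchors are multiplied by the enrichment fold. Cohort fixtures: each
#' positive loop is present in each sample with a group-dependent
#' probability -- a planted differential subset uses high/low
#' probabilities by group (direction alternating), the rest a common
#' probability -- yielding per-sample loop subsets, per-sample open
#' region (ATAC-like) BED tables, and the ground-truth presence matrix.
#'
#' @param config A `sim_config`.
#' @param regions Open-region interval `data.frame`.
#' @param loops Positive pair `data.frame`.
#' @return List with `tracks` (named bedGraph list), `presence`
#'   (loops x samples 0/1 matrix), `samples` (per-sample pair subsets),
#'   `atac` (per-sample region BEDs), `groups`, and `differential`
#'   (logical ground truth per loop).
#' @export
simulate_signal_tracks <- function(config, regions, loops) {
  with_seed(config$seed + 2L, {
    anchor_keys <- unique(c(paste(loops$chrom1, loops$start1, loops$end1),
                            paste(loops$chrom2, loops$start2, loops$end2)))
    rkey <- paste(regions$chrom, regions$start, regions$end)
    is_anchor <- rkey %in% anchor_keys
    ord <- order(regions$chrom, regions$start)
    tracks <- lapply(seq_len(config$n_tracks), function(t) {
      v <- config$signal_baseline * exp(stats::rnorm(nrow(regions), 0, 0.2))
      v[is_anchor] <- v[is_anchor] * config$signal_fold
      data.frame(chrom = regions$chrom[ord], start = regions$start[ord],
                 end = regions$end[ord], value = v[ord],
                 stringsAsFactors = FALSE)
    })
    names(tracks) <- sprintf("track%02d", seq_len(config$n_tracks))
    n <- nrow(loops)
    ns <- config$n_samples
    lev <- unique(config$groups)
    differential <- stats::runif(n) < config$frac_differential
    up_group <- sample(lev, n, replace = TRUE)
    prob <- matrix(config$presence_common, nrow = n, ncol = ns)
    for (j in seq_len(ns)) {
      hi <- differential & up_group == config$groups[j]
      lo <- differential & up_group != config$groups[j]
      prob[hi, j] <- config$presence_high
      prob[lo, j] <- config$presence_low
    }
    presence <- matrix(as.integer(stats::runif(n * ns) < prob), n, ns)
    colnames(presence) <- sprintf("sample%02d", seq_len(ns))
    rownames(presence) <- pair_key(loops)
    samples <- lapply(seq_len(ns), function(j)
      loops[presence[, j] == 1L, , drop = FALSE])
    names(samples) <- colnames(presence)
    atac <- lapply(seq_len(ns), function(j) {
      present_anchor <- rkey %in%
        c(paste(samples[[j]]$chrom1, samples[[j]]$start1, samples[[j]]$end1),
          paste(samples[[j]]$chrom2, samples[[j]]$start2, samples[[j]]$end2))
      keep <- present_anchor | stats::runif(nrow(regions)) < 0.8
      regions[keep, , drop = FALSE]
    })
    names(atac) <- colnames(presence)
    list(tracks = tracks, presence = presence, samples = samples,
         atac = atac, groups = stats::setNames(config$groups,
                                               colnames(presence)),
         differential = differential)
  })
}

#' Select a dataset tier from simulated pairs
#'
#' @param pairs The `pairs` element of a simulated study.
#' @param tier `"matched"` (positives + distance-matched negatives) or
#'   `"extended"` (positives + all negatives).
#' @return Labeled pair `data.frame`.
#' @export
dataset_tier <- function(pairs, tier = c("matched", "extended")) {
  tier <- match.arg(tier)
  keep <- if (tier == "matched") {
    pairs$tier %in% c("positive", "matched")
  } else {
    rep(TRUE, nrow(pairs))
  }
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full synthetic study generator
#'
#' Chains [simulate_genome_and_regions()],
#' [simulate_interactions_with_convergent_motifs()] and
#' [simulate_signal_tracks()] under one config.
#'
#' @param config A `sim_config`.
#' @return List with `genome`, `regions`, `chrom_lengths`, `pairs`,
#'   `positives`, `manifest`, `tracks`, and the cohort elements of
#'   [simulate_signal_tracks()].
#' @export
simulate_loop_study <- function(config = sim_config()) {
  gr <- simulate_genome_and_regions(config)
  si <- simulate_interactions_with_convergent_motifs(config, gr$genome,
                                                     gr$regions)
  st <- simulate_signal_tracks(config, gr$regions, si$positives)
  c(list(genome = si$genome, regions = gr$regions,
         chrom_lengths = gr$chrom_lengths, pairs = si$pairs,
         positives = si$positives, manifest = si$manifest), st)
}

#' Write simulated fixtures to standard formats
#'
#' Emits FASTA (genome), BED (open regions), BEDPE (positive loops and
#' labeled pairs TSV), bedGraph tracks, per-sample ATAC BEDs and loop
#' BEDPEs, and a JSON manifest of planted motif instances.
#'
#' @param study Result of [simulate_loop_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(study$genome, file.path(dir, "genome.fa"))
  write_bed(study$regions, file.path(dir, "open_regions.bed"))
  write_bedpe(study$positives, file.path(dir, "positive_loops.bedpe"))
  utils::write.table(study$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(study$tracks)) {
    write_bedgraph(study$tracks[[nm]], file.path(dir, paste0(nm, ".bedGraph")))
  }
  for (nm in names(study$samples)) {
    write_bedpe(study$samples[[nm]], file.path(dir, paste0(nm, "_loops.bedpe")))
    write_bed(study$atac[[nm]], file.path(dir, paste0(nm, "_atac.bed")))
  }
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       digits = NA)
  invisible(dir)
}
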