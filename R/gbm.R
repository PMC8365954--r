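# Stages 2-3: gradient-boosted-tree classifiers on frozen-extractor
# sequence features (optionally with distance), probability scoring,
# gain-based feature importances, and the end-to-end from-open-chromatin
# genome-wide predictor. Trees are invariant to monotone transforms, so
# distance is passed raw in bp.

#' Train a gradient-boosted-tree classifier
#'
#' Wraps gradient tree boosting (xgboost) with the package defaults:
#' 500 trees, depth 6, learning rate 0.05, subsample 0.8, and early
#' stopping on validation auPRC (50 rounds) when a validation set is
#' supplied. Training is deterministic given `seed` in the single-threaded
#' mode used here; multi-threaded boosting may break tie-break
#' determinism, so `nthread` defaults to 1.
#'
#' @param features Numeric feature matrix with column names (the feature
#'   manifest); an optional `block_map` attribute (see
#'   [featurize_pairs()]) is stored for importance mapping.
#' @param labels Binary labels.
#' @param val_features,val_labels Optional validation data for early
#'   stopping.
#' @param stage One of `"extended"`, `"from_open"`, `"functional"`;
#'   recorded as the model identifier.
#' @param nrounds,max_depth,eta,subsample,early_stopping_rounds,nthread
#'   Boosting hyperparameters.
#' @param seed Integer seed.
#' @return A `loop_gb` model.
#' @export
train_gb <- function(features, labels, val_features = NULL,
                     val_labels = NULL,
                     stage = c("extended", "from_open", "functional"),
                     nrounds = 500L, max_depth = 6L, eta = 0.05,
                     subsample = 0.8, early_stopping_rounds = 50L,
                     nthread = 1L, seed = 1L) {
  stage <- match.arg(stage)
  y <- as_binary_labels(labels)
  stop_if(length(unique(y)) < 2L, "training labels contain a single class")
  bad <- which(vapply(seq_len(ncol(features)),
                      function(j) any(!is.finite(features[, j])), logical(1)))
  stop_if(length(bad) > 0L, "non-finite feature values in column: ",
          paste(colnames(features)[bad], collapse = ", "))
  stop_if(is.null(colnames(features)), "features must carry column names")
  dtrain <- xgboost::xgb.DMatrix(features, label = y)
  evals <- list(train = dtrain)
  esr <- NULL
  if (!is.null(val_features)) {
    evals <- list(val = xgboost::xgb.DMatrix(val_features,
                                             label = as_binary_labels(val_labels)))
    esr <- as.integer(early_stopping_rounds)
  }
  params <- list(objective = "binary:logistic", eval_metric = "aucpr",
                 max_depth = as.integer(max_depth), eta = eta,
                 subsample = subsample, nthread = as.integer(nthread),
                 seed = as.integer(seed))
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = as.integer(nrounds),
                                evals = evals,
                                early_stopping_rounds = esr,
                                maximize = TRUE, verbose = 0)
  structure(list(booster = booster,
                 feature_names = colnames(features),
                 block_map = attr(features, "block_map"),
                 stage = stage,
                 eval_log = as.data.frame(attributes(booster)$evaluation_log)),
            class = "loop_gb")
}

#' @export
print.loop_gb <- function(x, ...) {
  cat("Gradient-boosted interaction classifier (loop_gb)\n")
  cat(sprintf("  stage      %s\n", x$stage))
  cat(sprintf("  features   %d (%s...)\n", length(x$feature_names),
              paste(utils::head(x$feature_names, 3), collapse = ", ")))
  bi <- xgboost::xgb.attr(x$booster, "best_iteration")
  if (!is.null(bi)) cat(sprintf("  best round %s\n", bi))
  invisible(x)
}

#' @export
predict.loop_gb <- function(object, newdata, ...) {
  stop_if(is.null(colnames(newdata)) ||
            !identical(colnames(newdata), object$feature_names),
          "feature manifest mismatch: model expects [",
          paste(utils::head(object$feature_names, 4), collapse = ", "),
          ", ...]")
  as.numeric(stats::predict(object$booster, newdata))
}

#' Score anchor pairs with a frozen extractor and GB classifier
#'
#' Featurizes pairs through the frozen extractor (each distinct anchor is
#' encoded once, so scores are invariant to input batching/order) and
#' scores them with the boosted classifier.
#'
#' @param model A `loop_gb` trained on matching features.
#' @param extractor The frozen `loop_extractor`.
#' @param pairs Pair `data.frame`.
#' @param genome Named `DNAStringSet` or character vector.
#' @param include_distance Must match the model's feature manifest.
#' @param threshold Optional decision threshold; adds a `predicted` flag.
#' @return `pairs` with a `score` column (and `predicted` if thresholded).
#' @export
predict_pairs <- function(model, extractor, pairs, genome,
                          include_distance = FALSE, threshold = NULL) {
  feats <- featurize_pairs(extractor, pairs, genome,
                           include_distance = include_distance)
  pairs$score <- predict(model, feats)
  if (!is.null(threshold)) pairs$predicted <- pairs$score >= threshold
  pairs
}

#' Feature importance report
#'
#' Gain-based importances of a boosted model, with every feature of the
#' manifest reported exactly once (features never used by a split get
#' importance 0). Sequence features are mapped through the pair-feature
#' block boundaries to (anchor side, orientation, kernel); distance is
#' reported as its own record.
#'
#' @param model A `loop_gb`.
#' @return `data.frame` with columns `feature`, `block`, `kernel`,
#'   `importance`.
#' @export
feature_importance_report <- function(model) {
  # gain summed per feature over all split nodes, normalized to sum 1
  tree <- xgboost::xgb.model.dt.tree(model = model$booster)
  tree <- as.data.frame(tree)
  splits <- tree[tree$Feature != "Leaf", , drop = FALSE]
  gain <- stats::setNames(rep(0, length(model$feature_names)),
                          model$feature_names)
  if (nrow(splits) > 0L) {
    sums <- tapply(splits$Gain, splits$Feature, sum)
    gain[names(sums)] <- sums / sum(sums)
  }
  bm <- model$block_map
  if (is.null(bm)) {
    bm <- data.frame(feature = model$feature_names,
                     block = ifelse(model$feature_names == "distance",
                                    "distance", "unmapped"),
                     kernel = NA_integer_, stringsAsFactors = FALSE)
  }
  out <- data.frame(feature = model$feature_names, stringsAsFactors = FALSE)
  m <- match(out$feature, bm$feature)
  out$block <- ifelse(out$feature == "distance", "distance", bm$block[m])
  out$kernel <- ifelse(out$feature == "distance", NA_integer_, bm$kernel[m])
  out$importance <- as.numeric(gain)
  out
}

#' Genome-wide prediction from open chromatin regions
#'
#' The final from-open-chromatin pipeline: candidate anchors are built by
#' merging open chromatin peaks (3000 bp) and extending (1000 bp), all
#' same-chromosome anchor pairs within `max_span` are enumerated,
#' featurized through the frozen extractor and scored by the
#' from-open-stage classifier. All pairs are returned with their scores;
#' `predicted` flags pairs at or above `threshold` (typically chosen by
#' [f_score_threshold_scan()]).
#'
#' @param peaks Interval `data.frame` of open chromatin regions.
#' @param genome Named `DNAStringSet` or character vector.
#' @param extractor Frozen `loop_extractor`.
#' @param model `loop_gb` trained at the from-open stage.
#' @param merge_distance,extension Anchor-construction parameters
#'   (defaults 3000 and 1000 bp).
#' @param max_span Maximum pair span in bp (default 2 Mb).
#' @param threshold Decision threshold on the probability score.
#' @param include_distance Must match the model's feature manifest.
#' @return Pair `data.frame` (BEDPE-ready, see [write_bedpe()]) with
#'   `score` and `predicted` columns.
#' @export
predict_from_open_chromatin <- function(peaks, genome, extractor, model,
                                        merge_distance = 3000L,
                                        extension = 1000L, max_span = 2e6,
                                        threshold = 0.5,
                                        include_distance = FALSE) {
  if (nrow(peaks) == 0L) {
    out <- anchor_pairs(character(), integer(), integer(),
                        character(), integer(), integer())
    out$score <- numeric(0)
    out$predicted <- logical(0)
    return(out)
  }
  anchors <- build_anchors_from_open_chromatin(
    peaks, merge_distance, extension, chrom_lengths(genome))
  no_loops <- anchor_pairs(character(), integer(), integer(),
                           character(), integer(), integer())
  cand <- enumerate_and_label_pairs(anchors, known_loops = no_loops,
                                    max_span = max_span)
  cand$label <- NULL
  predict_pairs(model, extractor, cand, genome,
                include_distance = include_distance, threshold = threshold)
}

#' Save / load a boosted classifier
#'
#' Stores the booster (base64-encoded) together with its feature manifest
#' and stage in a single JSON file.
#'
#' @param model A `loop_gb`.
#' @param path Model file path.
#' @return `save_gb_model` returns `path`; `load_gb_model` the restored
#'   `loop_gb`.
#' @export
save_gb_model <- function(model, path) {
  obj <- list(format = "seqloop_gb", stage = model$stage,
              feature_names = model$feature_names,
              block_map = model$block_map,
              booster_raw = jsonlite::base64_enc(
                xgboost::xgb.save.raw(model$booster)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_gb_model
#' @export
load_gb_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stop_if(!identical(obj$format, "seqloop_gb"), "not a model file: ", path)
  structure(list(booster = xgboost::xgb.load.raw(
    jsonlite::base64_dec(obj$booster_raw)),
    feature_names = obj$feature_names,
    block_map = obj$block_map, stage = obj$stage,
    eval_log = NULL), class = "loop_gb")
}
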