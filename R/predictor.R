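#' Build a training set of windows for binding prediction
#'
#' Draws a seeded uniform sample of windows, without replacement, from the
#' windows that are unmasked and have defined features and target, and
#' pairs the selected feature columns with the target value of each window.
#'
#' @param features Feature table from [sequence_features()].
#' @param target Signal track of per-window enrichment on the same grid
#'   (any continuous per-window enrichment works; the package's own SES
#'   enrichment is the default pipeline choice).
#' @param mask Optional mask track or logical vector.
#' @param n Number of training windows (default 10000).
#' @param seed Integer seed; the same seed reproduces the same window list.
#' @param feature_cols Character vector of feature columns; default uses
#'   `f_GC` (the single independent mononucleotide feature: base
#'   frequencies sum to 1 and strand symmetry equates A with T and C with
#'   G) plus any reverse-complement-collapsed k-mer class columns `kc_*`,
#'   dropping the mononucleotide classes themselves.
#' @return An object of class `training_set`: `ids` (row indices of the
#'   grid), `x` (feature tibble), `y` (target vector), `seed`,
#'   `feature_cols`.
#' @export
build_training_set <- function(features, target, mask = NULL, n = 10000,
                               seed = 1, feature_cols = NULL) {
  check_same_grid(features, target)
  if (is.null(feature_cols)) {
    kc <- setdiff(grep("^kc_", names(features), value = TRUE),
                  c("kc_A", "kc_C"))
    feature_cols <- c("f_GC", kc)
  }
  stopifnot(all(feature_cols %in% names(features)))
  ok <- features$defined & !is.na(target$value) &
    !mask_values(mask, nrow(features)) &
    stats::complete.cases(features[, feature_cols])
  eligible <- which(ok)
  if (length(eligible) < n) {
    stop("only ", length(eligible), " eligible windows; need ", n)
  }
  ids <- withr::with_seed(seed, sort(sample(eligible, n)))
  structure(list(ids = ids,
                 x = features[ids, feature_cols],
                 y = target$value[ids],
                 seed = seed, feature_cols = feature_cols),
            class = "training_set")
}

#' Train a random-forest regressor of binding on sequence features
#'
#' Fits a 100-tree random forest (CART-style trees via ranger) regressing
#' window enrichment on the k-mer features of a training set. The fit is
#' deterministic given the seed (single thread).
#'
#' @param ts Training set from [build_training_set()].
#' @param n_trees Number of trees (default 100).
#' @param max_depth Maximum tree depth, in 3..8 (the range over which the
#'   predictions are expected to be robust).
#' @param seed Integer seed for the forest.
#' @return Object of class `binding_rf`: the ranger fit plus metadata.
#'   `glance()` reports the training-set predicted-vs-actual Pearson r.
#' @export
train_regressor <- function(ts, n_trees = 100, max_depth = 6, seed = 1) {
  stopifnot(inherits(ts, "training_set"))
  if (!(max_depth %in% 3:8)) stop("max_depth must be between 3 and 8")
  if (stats::sd(ts$y) == 0) stop("constant target; nothing to learn")
  d <- data.frame(ts$x, .y = ts$y)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = d,
    num.trees = n_trees, max.depth = max_depth,
    mtry = length(ts$feature_cols),  # consider every feature at each split
    importance = "impurity", seed = seed, num.threads = 1)
  pred <- stats::predict(fit, data.frame(ts$x), num.threads = 1)$predictions
  structure(list(fit = fit, feature_cols = ts$feature_cols,
                 train_ids = ts$ids, n_trees = n_trees,
                 max_depth = max_depth, seed = seed,
                 r_train = stats::cor(pred, ts$y)),
            class = "binding_rf")
}

#' @export
print.binding_rf <- function(x, ...) {
  cat("Random-forest binding regressor:", x$n_trees, "trees, depth <=",
      x$max_depth, "\n  features:", length(x$feature_cols),
      "\n  training r(pred, actual):", round(x$r_train, 3), "\n")
  invisible(x)
}

#' @rdname train_regressor
#' @param x A `binding_rf`.
#' @param ... Unused.
#' @method glance binding_rf
#' @export
glance.binding_rf <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, max_depth = x$max_depth,
                 n_features = length(x$feature_cols),
                 n_train = length(x$train_ids), r_train = x$r_train)
}

#' Predict enrichment for all windows of a feature table
#' @param model A `binding_rf`.
#' @param features Feature table (same columns as at training).
#' @return Numeric vector of predictions (NA where features are undefined).
#' @export
predict_enrichment <- function(model, features) {
  out <- rep(NA_real_, nrow(features))
  ok <- stats::complete.cases(features[, model$feature_cols])
  out[ok] <- stats::predict(model$fit,
                            data.frame(features[ok, model$feature_cols]),
                            num.threads = 1)$predictions
  out
}

#' Classify windows as bound and evaluate by ROC
#'
#' Windows are labelled positive when they overlap any peak by at least
#' `overlap_min` bp. The predicted enrichment is swept over thresholds to
#' produce the ROC curve; AUC is computed by the trapezoid rule, and the
#' equal-error-rate (EER) point is the threshold where the false-positive
#' and false-negative rates cross (linearly interpolated). The EER accuracy
#' is 1 - FPR at that point.
#'
#' @param model A `binding_rf`.
#' @param features Feature table for the evaluation windows.
#' @param peaks Tibble of peak intervals (`chrom`, `start`, `end`).
#' @param overlap_min Minimum overlap in bp to call a window positive.
#' @param mask Optional mask track or logical vector.
#' @param exclude_training Drop the model's training windows from the
#'   evaluation set (default TRUE).
#' @return Object of class `roc_result`: tibble (`threshold`, `fpr`,
#'   `tpr`) with attributes `auc`, `eer_threshold`, `eer_accuracy`,
#'   `n_pos`, `n_neg`; `glance()` returns them as a row.
#' @export
classify_and_roc <- function(model, features, peaks, overlap_min = 50,
                             mask = NULL, exclude_training = TRUE) {
  pred <- predict_enrichment(model, features)
  keep <- !is.na(pred) & !mask_values(mask, nrow(features))
  if (exclude_training) keep[model$train_ids] <- FALSE
  labels <- window_peak_overlap(features, peaks) >= overlap_min
  pred <- pred[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("need both positive and negative windows (pos = ", n_pos,
         ", neg = ", n_neg, ")")
  }
  o <- order(pred, decreasing = TRUE)
  tp <- cumsum(labels[o]); fp <- cumsum(!labels[o])
  # collapse tied thresholds to their last (most permissive) point
  last <- c(pred[o][-1] != pred[o][-length(pred)], TRUE)
  tpr <- c(0, tp[last] / n_pos); fpr <- c(0, fp[last] / n_neg)
  thr <- c(Inf, pred[o][last])
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  # EER: fpr - fnr = fpr - (1 - tpr) crosses 0 along the curve
  d <- fpr - (1 - tpr)
  k <- which(d >= 0)[1]
  if (is.na(k)) k <- length(d)
  if (k == 1 || d[k] == 0) {
    eer_fpr <- fpr[k]; eer_thr <- thr[k]
  } else {
    w <- d[k - 1] / (d[k - 1] - d[k])  # interpolate between k-1 and k
    eer_fpr <- fpr[k - 1] + w * (fpr[k] - fpr[k - 1])
    eer_thr <- thr[k - 1] + w * (thr[k] - thr[k - 1])
  }
  out <- tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)
  structure(out, class = c("roc_result", class(out)),
            auc = auc, eer_threshold = eer_thr,
            eer_accuracy = 1 - eer_fpr, n_pos = n_pos, n_neg = n_neg)
}

#' @keywords internal
window_peak_overlap <- function(grid, peaks) {
  out <- numeric(nrow(grid))
  for (ch in unique(peaks$chrom)) {
    pk <- peaks[peaks$chrom == ch, ]
    sel <- which(grid$chrom == ch)
    if (length(sel) == 0) next
    win <- IRanges::IRanges(grid$start[sel] + 1, grid$end[sel])
    pir <- IRanges::reduce(IRanges::IRanges(pk$start + 1, pk$end))
    ov <- IRanges::findOverlaps(win, pir)
    if (length(ov) == 0) next
    w <- IRanges::width(IRanges::pintersect(
      win[S4Vectors::queryHits(ov)], pir[S4Vectors::subjectHits(ov)]))
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    out[sel[as.integer(names(agg))]] <- as.numeric(agg)
  }
  out
}

#' @rdname classify_and_roc
#' @param x A `roc_result`.
#' @param ... Unused.
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"),
                 eer_threshold = attr(x, "eer_threshold"),
                 eer_accuracy = attr(x, "eer_accuracy"),
                 n_pos = attr(x, "n_pos"), n_neg = attr(x, "n_neg"))
}

#' @rdname classify_and_roc
#' @param object A `roc_result`.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f, EER accuracy = %.3f",
                                  attr(object, "auc"),
                                  attr(object, "eer_accuracy"))) +
    ggplot2::theme_minimal()
}

#' Feature importance of a binding regressor
#'
#' Two importance measures are available. `"depth"` follows the idea that
#' features used near the root of a tree influence more of the prediction:
#' each split of feature f contributes 1 minus its relative depth (node
#' depth divided by tree height), summed over all trees; features never
#' used score 0. `"impurity"` is the standard variance-reduction importance
#' reported by the forest. Both are normalized to sum to 1.
#'
#' @param model A `binding_rf`.
#' @param method `"depth"` or `"impurity"`.
#' @return Tibble (`feature`, `importance`, `method`) sorted decreasingly.
#' @export
feature_importance <- function(model, method = c("depth", "impurity")) {
  method <- match.arg(method)
  feats <- model$feature_cols
  if (method == "impurity") {
    imp <- ranger::importance(model$fit)
    imp <- pmax(imp[feats], 0)
  } else {
    score <- stats::setNames(numeric(length(feats)), feats)
    for (t in seq_len(model$fit$num.trees)) {
      ti <- ranger::treeInfo(model$fit, t)
      depth <- rep(NA_real_, nrow(ti))
      depth[ti$nodeID == 0] <- 0
      ord <- order(ti$nodeID)
      for (i in ord) {  # children always have larger nodeID than parent
        if (ti$terminal[i]) next
        d <- depth[match(ti$nodeID[i], ti$nodeID)] + 1
        depth[match(ti$leftChild[i], ti$nodeID)] <- d
        depth[match(ti$rightChild[i], ti$nodeID)] <- d
      }
      height <- max(depth, na.rm = TRUE)
      if (height == 0) next
      splits <- !ti$terminal
      contrib <- tapply(1 - depth[splits] / height,
                        ti$splitvarName[splits], sum)
      score[names(contrib)] <- score[names(contrib)] + as.numeric(contrib)
    }
    imp <- score
  }
  total <- sum(imp)
  if (total == 0) stop("no splits recorded; cannot compute importance")
  tibble::tibble(feature = names(imp), importance = as.numeric(imp) / total,
                 method = method) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}
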