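#' Confusion counts
#'
#' Dependent ambulation is the positive class: a correctly classified
#' dependent patient is a true positive, a correctly classified independent
#' patient a true negative.
#'
#' @param pred,truth Equal-length vectors of `"dependent"` / `"independent"`.
#' @return An object of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  pred <- as.character(pred); truth <- as.character(truth)
  ok <- c("dependent", "independent")
  if (!all(pred %in% ok) || !all(truth %in% ok))
    stop("labels must be 'dependent' or 'independent'")
  structure(list(
    TP = sum(pred == "dependent" & truth == "dependent"),
    TN = sum(pred == "independent" & truth == "independent"),
    FP = sum(pred == "dependent" & truth == "independent"),
    FN = sum(pred == "independent" & truth == "dependent")),
    class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' F1 `2TP/(2TP+FP+FN)` (the harmonic mean of precision and recall).
#' Zero-denominator convention: precision and recall are 0 when undefined,
#' and F1 is 0 when precision + recall is 0.
#'
#' @param c A `confusion_counts` object.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
metric_set <- function(c) {
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) stop("empty confusion table")
  precision <- if (c$TP + c$FP > 0) c$TP / (c$TP + c$FP) else 0
  recall <- if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else 0
  f1 <- if (2 * c$TP + c$FP + c$FN > 0) 2 * c$TP / (2 * c$TP + c$FP + c$FN) else 0
  c(accuracy = (c$TP + c$TN) / total, precision = precision,
    recall = recall, f1 = f1)
}

#' k-fold cross-validation split
#'
#' Test folds are disjoint, cover every item exactly once, and differ in
#' size by at most one (168 items into 5 folds gives test sizes 34, 34, 34,
#' 33, 33 — i.e. roughly 80/20 train/test). With `groups`, all items of a
#' group share a fold (leakage-safe patient-level splitting); group folds
#' are balanced greedily and may then differ by more than one item.
#'
#' @param n Number of items.
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @param groups Optional length-`n` grouping vector.
#' @return List of `k` lists with `train` and `test` index vectors.
#' @export
kfold_split <- function(n, k = 5, seed = 1, groups = NULL) {
  if (k > n) stop("k must not exceed n")
  if (is.null(groups)) {
    idx <- with_seed(seed, sample(n))
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    folds <- lapply(seq_len(k), function(i) sort(idx[starts[i]:ends[i]]))
  } else {
    stopifnot(length(groups) == n)
    gs <- split(seq_len(n), groups)
    ord <- with_seed(seed, sample(length(gs)))
    ## largest-first greedy balancing onto the currently smallest fold
    ord <- ord[order(-vapply(gs[ord], length, 1L))]
    fold_of <- integer(length(gs))
    load <- integer(k)
    for (g in ord) {
      f <- which.min(load)
      fold_of[g] <- f
      load[f] <- load[f] + length(gs[[g]])
    }
    folds <- lapply(seq_len(k), function(f)
      sort(unlist(gs[fold_of == f], use.names = FALSE)))
  }
  lapply(seq_len(k), function(i)
    list(train = sort(setdiff(seq_len(n), folds[[i]])), test = folds[[i]]))
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores with trapezoidal area, reported for
#' both class orientations (dependent as positive scored by `p`, independent
#' as positive scored by `1 - p`).
#'
#' @param scores Numeric scores (probability of dependent).
#' @param truth Labels `"dependent"` / `"independent"`.
#' @return List with per-orientation `points` (fpr/tpr data.frame) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.character(truth)
  if (length(unique(truth)) < 2) stop("both classes must be present")
  one <- function(sc, pos) {
    is_pos <- truth == pos
    thr <- sort(unique(sc), decreasing = TRUE)
    tpr <- vapply(thr, function(t) mean(sc[is_pos] >= t), 1.0)
    fpr <- vapply(thr, function(t) mean(sc[!is_pos] >= t), 1.0)
    fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
    auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
  }
  list(dependent = one(scores, "dependent"),
       independent = one(1 - scores, "independent"))
}

#' Fivefold cross-validated evaluation of the full pipeline
#'
#' Per fold: the classifier is trained from scratch on the training clips,
#' applied to the held-out clips, and evaluated twice — network-only
#' (threshold at 0.5) and fused with swing-time asymmetry over the
#' uncertainty band. Reports per-fold accuracy/precision/recall/F1, their
#' mean and standard deviation over folds, and pooled ROC/AUC for both class
#' orientations.
#'
#' @param dataset A dataset from [make_dataset()] (each record carries
#'   `tensor`, `label`, `asym`).
#' @param k Number of folds.
#' @param seed Split seed (also offsets the per-fold model seeds).
#' @param model_cfg,train_cfg,fusion_cfg Component configurations.
#' @param groups Optional grouping for leakage-safe splits.
#' @return An object of class `cv_report`.
#' @export
cross_validate <- function(dataset, k = 5, seed = 1,
                           model_cfg = model_config(),
                           train_cfg = train_config(),
                           fusion_cfg = fusion_config(),
                           groups = NULL) {
  n <- length(dataset)
  labels <- vapply(dataset, function(r) r$label, "")
  tensors <- lapply(dataset, function(r) r$tensor)
  asyms <- lapply(dataset, function(r) r$asym)
  folds <- kfold_split(n, k, seed, groups)
  per_fold <- list()
  pooled_p <- numeric(0); pooled_truth <- character(0)
  for (i in seq_along(folds)) {
    tr <- folds[[i]]$train; te <- folds[[i]]$test
    if (length(unique(labels[tr])) < 2) {
      warning("fold ", i, " skipped: single-class training split")
      next
    }
    mcfg <- model_cfg; mcfg$seed <- model_cfg$seed + i
    tcfg <- train_cfg; tcfg$seed <- train_cfg$seed + i
    fit <- train_cnn3d(build_model(mcfg), tensors[tr], labels[tr], tcfg)
    p <- predict_cnn3d(fit$model, tensors[te])
    cnn_lab <- ifelse(p >= 0.5, "dependent", "independent")
    fused_lab <- fuse_all(p, asyms[te], fusion_cfg)
    per_fold[[length(per_fold) + 1]] <- list(
      fold = i, n_test = length(te),
      cnn = metric_set(confusion(cnn_lab, labels[te])),
      fused = metric_set(confusion(as.character(fused_lab), labels[te])),
      final_loss = tail(fit$log$loss, 1))
    pooled_p <- c(pooled_p, p)
    pooled_truth <- c(pooled_truth, labels[te])
  }
  if (length(per_fold) == 0) stop("no usable folds")
  agg <- function(variant) {
    m <- t(vapply(per_fold, function(f) f[[variant]], numeric(4)))
    list(per_fold = m, mean = colMeans(m), sd = apply(m, 2, sd))
  }
  structure(list(k = k, n = n, folds = per_fold,
                 cnn = agg("cnn"), fused = agg("fused"),
                 roc = roc_auc(pooled_p, pooled_truth)),
            class = "cv_report")
}

fmt_pm <- function(mean, sd) sprintf("%.3f ± %.3f", mean, sd)

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds over %d clips\n", length(x$folds), x$n))
  for (variant in c("cnn", "fused")) {
    v <- x[[variant]]
    cat(sprintf("  %-5s accuracy %s  precision %s  recall %s  F1 %s\n",
                variant, fmt_pm(v$mean[1], v$sd[1]), fmt_pm(v$mean[2], v$sd[2]),
                fmt_pm(v$mean[3], v$sd[3]), fmt_pm(v$mean[4], v$sd[4])))
  }
  cat(sprintf("  AUC (dependent) %.3f, (independent) %.3f\n",
              x$roc$dependent$auc, x$roc$independent$auc))
  invisible(x)
}
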