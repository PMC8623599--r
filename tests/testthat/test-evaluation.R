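test_that("confusion counts use the dependent-positive orientation", {
  truth <- c("dependent", "dependent", "dependent", "independent")
  pred <- c("dependent", "dependent", "independent", "dependent")
  cc <- confusion(pred, truth)
  expect_equal(unlist(cc[c("TP", "FN", "FP", "TN")]), c(TP = 2, FN = 1, FP = 1, TN = 0))
  perfect <- confusion(truth, truth)
  expect_equal(perfect$FP + perfect$FN, 0)
  flipped <- ifelse(truth == "dependent", "independent", "dependent")
  cc2 <- confusion(flipped, truth)
  expect_equal(cc2$TP + cc2$TN, 0)
  expect_error(confusion(pred[1:2], truth), "lengths")
  expect_error(confusion(c("dep", "ind"), truth[1:2]), "labels")
})

test_that("metrics match their formulas including degenerate conventions", {
  m <- metric_set(confusion(c("dependent", "dependent", "dependent", "dependent",
                              "independent"),
                            c("dependent", "dependent", "dependent", "independent",
                              "independent")))
  expect_equal(unname(m), c(0.8, 0.75, 1, 6 / 7))
  perfect <- metric_set(structure(list(TP = 5, TN = 5, FP = 0, FN = 0),
                                  class = "confusion_counts"))
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  degen <- metric_set(structure(list(TP = 0, TN = 3, FP = 0, FN = 2),
                                class = "confusion_counts"))
  expect_equal(unname(degen[c("precision", "recall", "f1")]), c(0, 0, 0))
  expect_error(metric_set(structure(list(TP = 0, TN = 0, FP = 0, FN = 0),
                                    class = "confusion_counts")), "empty")
})

test_that("metrics agree with a brute-force oracle on random confusion tables", {
  with_seed <- get("with_seed", envir = asNamespace("ambustride"))
  tables <- with_seed(77, matrix(sample(0:40, 4000, replace = TRUE), ncol = 4))
  for (i in seq_len(nrow(tables))) {
    tp <- tables[i, 1]; tn <- tables[i, 2]; fp <- tables[i, 3]; fn <- tables[i, 4]
    if (tp + tn + fp + fn == 0) next
    got <- metric_set(structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
                                class = "confusion_counts"))
    ## oracle: rebuild label vectors and count directly
    truth <- rep(c("dependent", "independent", "independent", "dependent"),
                 c(tp, tn, fp, fn))
    pred <- rep(c("dependent", "independent", "dependent", "independent"),
                c(tp, tn, fp, fn))
    acc <- mean(pred == truth)
    prec <- if (sum(pred == "dependent") > 0)
      mean(truth[pred == "dependent"] == "dependent") else 0
    rec <- if (sum(truth == "dependent") > 0)
      mean(pred[truth == "dependent"] == "dependent") else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    expect_equal(unname(got), c(acc, prec, rec, f1), tolerance = 1e-12)
  }
})

test_that("f1 equals the harmonic mean of precision and recall when defined", {
  with_seed <- get("with_seed", envir = asNamespace("ambustride"))
  tables <- with_seed(3, matrix(sample(1:30, 400, replace = TRUE), ncol = 4))
  for (i in seq_len(nrow(tables))) {
    m <- metric_set(structure(list(TP = tables[i, 1], TN = tables[i, 2],
                                   FP = tables[i, 3], FN = tables[i, 4]),
                              class = "confusion_counts"))
    expect_equal(m[["f1"]],
                 2 / (1 / m[["precision"]] + 1 / m[["recall"]]),
                 tolerance = 1e-12)
  }
})

test_that("kfold splits partition the data with balanced sizes", {
  ks <- kfold_split(168, 5, seed = 1)
  sizes <- vapply(ks, function(f) length(f$test), 1L)
  expect_equal(sort(sizes, decreasing = TRUE), c(34, 34, 34, 33, 33))
  expect_equal(length(ks[[1]]$train), 134)
  ## exact cover
  expect_equal(sort(unlist(lapply(ks, `[[`, "test"))), 1:168)
  for (f in ks) expect_equal(sort(c(f$train, f$test)), 1:168)

  ks2 <- kfold_split(10, 5, seed = 2)
  expect_true(all(vapply(ks2, function(f) length(f$test), 1L) == 2))
  expect_error(kfold_split(3, 5), "exceed")
})

test_that("grouped kfold splits never separate a group", {
  with_seed <- get("with_seed", envir = asNamespace("ambustride"))
  for (s in 1:5) {
    groups <- with_seed(s, sample(letters[1:8], 40, replace = TRUE))
    ks <- kfold_split(40, 5, seed = s, groups = groups)
    expect_equal(sort(unlist(lapply(ks, `[[`, "test"))), 1:40)
    for (f in ks) {
      g_test <- unique(groups[f$test])
      g_train <- unique(groups[f$train])
      expect_length(intersect(g_test, g_train), 0)
    }
  }
})

test_that("roc_auc has the separation, symmetry, and chance properties", {
  truth <- rep(c("dependent", "independent"), each = 20)
  perfect <- c(runif(20, 0.6, 1), runif(20, 0, 0.4))
  r <- roc_auc(perfect, truth)
  expect_equal(r$dependent$auc, 1)
  expect_equal(r$independent$auc, 1)

  with_seed <- get("with_seed", envir = asNamespace("ambustride"))
  sc <- with_seed(5, runif(2000))
  truth_big <- rep(c("dependent", "independent"), 1000)
  r2 <- roc_auc(sc, truth_big)
  expect_lt(abs(r2$dependent$auc - 0.5), 0.05)

  ## reversing the labels maps AUC to 1 - AUC
  some <- with_seed(6, runif(60))
  t3 <- rep(c("dependent", "independent"), 30)
  t3r <- ifelse(t3 == "dependent", "independent", "dependent")
  expect_equal(roc_auc(some, t3)$dependent$auc,
               1 - roc_auc(some, t3r)$dependent$auc, tolerance = 1e-12)

  ## invariant under strictly monotone transforms of the scores
  expect_equal(roc_auc(plogis(5 * some - 2), t3)$dependent$auc,
               roc_auc(some, t3)$dependent$auc, tolerance = 1e-12)
  expect_error(roc_auc(some, rep("dependent", 60)), "both classes")
})

test_that("roc_auc agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  with_seed <- get("with_seed", envir = asNamespace("ambustride"))
  sc <- with_seed(8, runif(80))
  truth <- with_seed(9, sample(c("dependent", "independent"), 80,
                               replace = TRUE, prob = c(0.6, 0.4)))
  sc[truth == "dependent"] <- sc[truth == "dependent"] + 0.3
  want <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = sc, levels = c("independent", "dependent"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(sc, truth)$dependent$auc, want, tolerance = 1e-10)
})

test_that("cross-validation reports per-fold metrics for both variants", {
  ## tiny pipeline run: keypoint-only records with synthetic predictions are
  ## not enough here, so run a scaled-down true CV on toy tensors
  with_seed <- get("with_seed", envir = asNamespace("ambustride"))
  ds <- lapply(1:12, function(i) {
    lab <- if (i <= 6) "dependent" else "independent"
    asym <- structure(list(ratio = if (lab == "dependent") 1.24 else 1.02,
                           valid = TRUE, n_cycles_paretic = 3L,
                           n_cycles_nonparetic = 3L, paretic_side = "left"),
                      class = "asymmetry_result")
    list(tensor = toy_tensor(as.integer(lab == "dependent"), i),
         label = lab, asym = asym)
  })
  rep <- cross_validate(ds, k = 3, seed = 1,
                        model_cfg = tiny_model_config(),
                        train_cfg = train_config(cycle_epochs = c(5, 10),
                                                 batch_size = 4))
  expect_s3_class(rep, "cv_report")
  expect_length(rep$folds, 3)
  expect_true(all(is.finite(rep$cnn$mean)) && all(is.finite(rep$fused$mean)))
  expect_true(all(rep$fused$per_fold >= 0 & rep$fused$per_fold <= 1))
  ## the printed summary uses the mean ± SD convention
  expect_match(paste(capture.output(print(rep)), collapse = "\n"),
               "\\d\\.\\d{3} ± \\d\\.\\d{3}")
})
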