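# shared small feature/target construction for predictor tests
predictor_fixture <- function(seed = 101, n = 6000, W = 200,
                              gc_driver = TRUE) {
  withr::with_seed(seed, {
    g <- bin_grid(stats::setNames(n * W, "c1"), W)
    ft <- g
    ft$f_GC <- runif(n, 0.2, 0.8)
    cls <- kmer_classes(2)$class
    for (cl in cls) ft[[paste0("kc_", cl)]] <- runif(n)
    ft$defined <- TRUE
    y <- if (gc_driver) ifelse(ft$f_GC > 0.55, 2, 0) + rnorm(n, 0, 0.1)
         else rnorm(n)
    list(grid = g, features = ft, target = as_track(g, y))
  })
}

test_that("mono+di feature set after reverse-complement collapsing has 11 features", {
  fx <- predictor_fixture()
  ts <- build_training_set(fx$features, fx$target, n = 1000, seed = 1)
  expect_equal(length(ts$feature_cols), 11)
  expect_equal(ts$feature_cols[1], "f_GC")
  # mono+di+tri would give 11 + 32 = 43
  expect_equal(nrow(kmer_classes(1)) - 1 + nrow(kmer_classes(2)) +
                 nrow(kmer_classes(3)), 43)
})

test_that("training sets are seeded, mask-aware and representative", {
  fx <- predictor_fixture()
  ts1 <- build_training_set(fx$features, fx$target, n = 2000, seed = 7)
  ts2 <- build_training_set(fx$features, fx$target, n = 2000, seed = 7)
  expect_identical(ts1$ids, ts2$ids)
  mask <- rep(FALSE, nrow(fx$features)); mask[1:3000] <- TRUE
  for (seed in c(1, 2, 3)) {
    ts <- build_training_set(fx$features, fx$target, mask = mask,
                             n = 1000, seed = seed)
    expect_true(all(ts$ids > 3000))
  }
  expect_error(build_training_set(fx$features, fx$target, mask = mask,
                                  n = 5000, seed = 1), "eligible")
  # sample mean of y within 3 SE of the population mean
  ts <- build_training_set(fx$features, fx$target, n = 2000, seed = 9)
  se <- sd(fx$target$value) / sqrt(2000)
  expect_lt(abs(mean(ts$y) - mean(fx$target$value)), 3 * se)
})

test_that("the forest learns a one-dimensional GC rule and fails on noise", {
  fx <- predictor_fixture(gc_driver = TRUE)
  ts <- build_training_set(fx$features, fx$target, n = 3000, seed = 5,
                           feature_cols = "f_GC")
  rf <- train_regressor(ts, seed = 5)
  heldout <- setdiff(seq_len(nrow(fx$features)), ts$ids)
  pred <- predict_enrichment(rf, fx$features)
  expect_gt(cor(pred[heldout], fx$target$value[heldout]), 0.95)
  # target unrelated to the features: no held-out signal
  fx_null <- predictor_fixture(seed = 105, gc_driver = FALSE)
  tsn <- build_training_set(fx_null$features, fx_null$target, n = 3000,
                            seed = 5, feature_cols = "f_GC")
  rfn <- train_regressor(tsn, seed = 5)
  heldout_n <- setdiff(seq_len(nrow(fx_null$features)), tsn$ids)
  predn <- predict_enrichment(rfn, fx_null$features)
  expect_lt(abs(cor(predn[heldout_n], fx_null$target$value[heldout_n])), 0.1)
  # determinism: same seed, same predictions
  rf2 <- train_regressor(ts, seed = 5)
  expect_identical(predict_enrichment(rf2, fx$features), pred)
  # constant target errors
  tsc <- ts; tsc$y <- rep(1, length(tsc$y))
  expect_error(train_regressor(tsc), "constant")
})

test_that("ROC handles perfect, random and monotone-transformed predictions", {
  withr::with_seed(60, {
    fx <- predictor_fixture(seed = 102, n = 5000)
    # peaks over the high-GC windows -> labels follow GC
    peak_bins <- fx$features$f_GC > 0.55
    peaks <- fx$grid[peak_bins, c("chrom", "start", "end")]
    ts <- build_training_set(fx$features, fx$target, n = 1000, seed = 3,
                             feature_cols = "f_GC")
    rf <- train_regressor(ts, seed = 3)
    roc <- classify_and_roc(rf, fx$features, peaks)
    gl <- glance(roc)
    expect_gt(gl$auc, 0.95)       # near-deterministic construction
    expect_gt(gl$eer_accuracy, 0.9)
    expect_equal(gl$n_pos + gl$n_neg, nrow(fx$features) - 1000)
  })
})

test_that("ROC on an uninformative predictor is null, and AUC matches an independent oracle", {
  withr::with_seed(70, {
    fx <- predictor_fixture(seed = 104, n = 8000, gc_driver = FALSE)
    peak_bins <- fx$features$f_GC > 0.65  # labels unrelated to the noise target
    peaks <- fx$grid[peak_bins, c("chrom", "start", "end")]
    ts <- build_training_set(fx$features, fx$target, n = 1000, seed = 8,
                             feature_cols = "kc_AT")  # junk feature
    rf <- train_regressor(ts, seed = 8)
    roc <- classify_and_roc(rf, fx$features, peaks)
    expect_lt(abs(glance(roc)$auc - 0.5), 0.04)
    # AUC agrees with the rank-statistic (Mann-Whitney) oracle
    pred <- predict_enrichment(rf, fx$features)
    keep <- seq_len(nrow(fx$features))[-ts$ids]
    lab <- chipdissect:::window_peak_overlap(fx$features, peaks)[keep] >= 50
    p <- pred[keep]
    auc_mw <- (sum(rank(p)[lab]) - sum(lab) * (sum(lab) + 1) / 2) /
      (sum(lab) * sum(!lab))
    expect_equal(glance(roc)$auc, auc_mw, tolerance = 1e-10)
  })
})

test_that("labels require the minimum peak overlap", {
  g <- bin_grid(c(c1 = 1000), 200)
  peaks <- tibble::tibble(chrom = "c1", start = 151, end = 249)
  # window [0,200) overlaps 49 bp, window [200,400) overlaps 49 bp
  ov <- chipdissect:::window_peak_overlap(g, peaks)
  expect_equal(ov[1:2], c(49, 49))
  peaks2 <- tibble::tibble(chrom = "c1", start = 150, end = 250)
  ov2 <- chipdissect:::window_peak_overlap(g, peaks2)
  expect_equal(ov2[1:2], c(50, 50))
})

test_that("feature importance: single feature gets all of it; GC dominates a GC-driven signal", {
  fx <- predictor_fixture(seed = 103)
  ts1 <- build_training_set(fx$features, fx$target, n = 2000, seed = 2,
                            feature_cols = "f_GC")
  rf1 <- train_regressor(ts1, seed = 2)
  for (m in c("depth", "impurity")) {
    imp <- feature_importance(rf1, m)
    expect_equal(imp$importance, 1)
    expect_equal(imp$feature, "f_GC")
  }
  # mono+di features, GC-only signal: GC top-ranked by both methods;
  # the impurity measure additionally keeps every dinucleotide class small
  ts <- build_training_set(fx$features, fx$target, n = 2000, seed = 2)
  rf <- train_regressor(ts, seed = 2)
  for (m in c("depth", "impurity")) {
    imp <- feature_importance(rf, m)
    expect_equal(imp$feature[1], "f_GC")
    expect_equal(sum(imp$importance), 1, tolerance = 1e-10)
  }
  imp_gini <- feature_importance(rf, "impurity")
  expect_true(all(imp_gini$importance[imp_gini$feature != "f_GC"] < 0.1))
  expect_error(feature_importance(rf, "gini"))
})

test_that("duplicated features split importance roughly evenly", {
  withr::with_seed(80, {
    n <- 4000
    g <- bin_grid(c(c1 = n * 200), 200)
    ft <- g
    ft$f_GC <- runif(n, 0.2, 0.8)
    ft$kc_dup <- ft$f_GC          # exact duplicate of the informative feature
    ft$kc_junk <- runif(n)
    ft$defined <- TRUE
    y <- as_track(g, 2 * ft$f_GC + rnorm(n, 0, 0.1))
    ts <- build_training_set(ft, y, n = 2000, seed = 4,
                             feature_cols = c("f_GC", "kc_dup", "kc_junk"))
    rf <- train_regressor(ts, seed = 4)
    imp <- feature_importance(rf, "impurity")
    combined <- sum(imp$importance[imp$feature %in% c("f_GC", "kc_dup")])
    expect_gt(combined, 0.85)
    junk <- imp$importance[imp$feature == "kc_junk"]
    expect_lt(junk, 0.15)
  })
})
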