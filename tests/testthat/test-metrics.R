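test_that("confusion matrices tally calls against truth", {
  cm <- confusion_matrix(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(2L, 0L, 0L, 1L))
  cm <- confusion_matrix(c(TRUE, FALSE), c(FALSE, TRUE))
  expect_equal(c(cm$tp, cm$tn), c(0L, 0L))
  expect_error(confusion_matrix(TRUE, c(TRUE, FALSE)), "same length")
  expect_error(confusion_matrix(logical(), logical()), "empty")
  # element-wise tally oracle on random inputs
  for (seed in 1:5) {
    set.seed(seed)
    pred <- runif(50) < 0.5
    truth <- runif(50) < 0.7
    cm <- confusion_matrix(pred, truth)
    tally <- c(0, 0, 0, 0)
    for (i in 1:50) {
      cell <- if (pred[i] && truth[i]) 1 else if (pred[i]) 2 else if (truth[i]) 3 else 4
      tally[cell] <- tally[cell] + 1
    }
    expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), as.integer(tally))
  }
})

test_that("scalar metrics follow their defining ratios", {
  cm <- confusion_counts(tp = 184, fp = 3, fn = 32, tn = 4)
  expect_equal(accuracy(cm), 188 / 223)
  expect_equal(precision(cm), 184 / 187)
  expect_equal(recall(cm), 184 / 216)
  expect_equal(specificity(cm), 4 / 7)
  expect_equal(mcc(cm), 640 / sqrt(187 * 216 * 7 * 36))
  expect_equal(printed_recall_variant(cm), 184 / 188)
  expect_equal(recall(confusion_counts(0, 2, 5, 1)), 0)
  expect_equal(printed_recall_variant(confusion_counts(3, 1, 1, 0)), 1)
})

test_that("zero denominators raise typed undefined-metric conditions", {
  expect_error(precision(confusion_counts(0, 0, 5, 5)), class = "undefined_metric")
  expect_error(recall(confusion_counts(0, 5, 0, 5)), class = "undefined_metric")
  expect_error(specificity(confusion_counts(5, 0, 5, 0)), class = "undefined_metric")
  expect_error(mcc(confusion_counts(5, 0, 5, 0)), class = "undefined_metric")
  expect_error(auc_single_point(confusion_counts(0, 5, 0, 5)), class = "undefined_metric")
  expect_error(
    printed_recall_variant(confusion_counts(0, 5, 5, 0)),
    class = "undefined_metric"
  )
  expect_error(f_beta(confusion_counts(0, 5, 5, 0), 1), class = "undefined_metric")
})

test_that("F-beta reduces to F1 at beta = 1 and weights precision below it", {
  cm <- confusion_counts(tp = 202, fp = 3, fn = 14, tn = 4)
  expect_equal(f_beta(cm, 1), 404 / 421)
  expect_equal(f_beta(cm, 0.5), 0.9749034, tolerance = 1e-6)
  perfect <- confusion_counts(10, 0, 0, 5)
  for (b in c(0.25, 0.5, 1, 2)) expect_equal(f_beta(perfect, b), 1)
  expect_error(f_beta(cm, 0), "positive")
  # strictly increasing in recall (fn down) and precision (fp down)
  expect_gt(f_beta(confusion_counts(50, 5, 5, 5)), f_beta(confusion_counts(50, 5, 10, 5)))
  expect_gt(f_beta(confusion_counts(50, 2, 5, 5)), f_beta(confusion_counts(50, 5, 5, 5)))
})

test_that("single-point AUC is the balanced accuracy and respects the chance line", {
  cm <- confusion_counts(tp = 202, fp = 3, fn = 14, tn = 4)
  expect_equal(auc_single_point(cm), (202 / 216 + 4 / 7) / 2)
  # sensitivity = 1 - specificity lands on the chance diagonal
  expect_equal(auc_single_point(confusion_counts(30, 30, 10, 10)), 0.5)
  expect_equal(auc_single_point(confusion_counts(10, 0, 0, 10)), 1)
})

test_that("MCC and AUC match their brute-force oracles on random matrices", {
  set.seed(42)
  for (i in 1:60) {
    counts <- rmultinom(1, sample(8:120, 1), prob = runif(4, 0.05, 1))[, 1]
    tp <- counts[1]; fp <- counts[2]; fn <- counts[3]; tn <- counts[4]
    cm <- confusion_counts(tp, fp, fn, tn)
    if (all(c(tp + fp, tp + fn, tn + fp, tn + fn) > 0)) {
      expect_equal(mcc(cm), mcc_cor_oracle(tp, fp, fn, tn), tolerance = 1e-12)
    }
    if (tp + fn > 0 && tn + fp > 0) {
      expect_equal(auc_single_point(cm), mw_auc_oracle(tp, fp, fn, tn),
        tolerance = 1e-12
      )
    }
  }
})

test_that("the panel agrees with the individually called metrics", {
  cm <- confusion_counts(tp = 292, fp = 8, fn = 19, tn = 9)
  p <- metric_panel(cm)
  expect_equal(p$accuracy, accuracy(cm))
  expect_equal(p$recall, recall(cm))
  expect_equal(p$precision, precision(cm))
  expect_equal(p$f1, f_beta(cm, 1))
  expect_equal(p$f_weighted, f_beta(cm, 0.5))
  expect_equal(p$mcc, mcc(cm))
  expect_equal(p$auc, auc_single_point(cm))
  expect_equal(p$printed_recall_variant, printed_recall_variant(cm))
  expect_length(p$undefined, 0)
  # frozen spot values for this matrix
  expect_equal(p$accuracy, 0.9176829, tolerance = 1e-6)
  expect_equal(p$f1, 0.9558101, tolerance = 1e-6)
  expect_equal(p$mcc, 0.3715406, tolerance = 1e-6)
  expect_equal(p$auc, 0.7341593, tolerance = 1e-6)
})

test_that("undefined panel fields are NA and named, not fatal", {
  p <- metric_panel(confusion_counts(tp = 0, fp = 0, fn = 3, tn = 7))
  expect_true(is.na(p$precision))
  expect_true("precision" %in% p$undefined)
  expect_equal(p$accuracy, 0.7)
  all_correct <- metric_panel(confusion_counts(7, 0, 0, 3))
  expect_equal(all_correct$accuracy, 1)
  expect_equal(all_correct$f1, 1)
  expect_equal(all_correct$auc, 1)
  expect_equal(all_correct$mcc, 1)
})

test_that("Hanley-McNeil interval brackets the AUC and stays in [0, 1]", {
  ci <- auc_ci_hanley_mcneil(confusion_counts(202, 3, 14, 4))
  expect_true(ci$lower <= ci$auc && ci$auc <= ci$upper)
  expect_gte(ci$lower, 0)
  expect_lte(ci$upper, 1)
  expect_gt(ci$se, 0)
})
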