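# Builders and independent oracles shared across the suite. Oracles here
# deliberately take the dumb route (element-wise tallies, O(n^2) pair
# counts, expansion to indicator vectors) so they share no code with the
# implementation they check.

make_cohort_df <- function(gvr_type = "I", size_mm = 10, dl_score = 10,
                           suspicious_features = FALSE, truth = "neoplastic",
                           split = "training", n = NULL) {
  n <- if (is.null(n)) {
    max(
      length(gvr_type), length(size_mm), length(dl_score),
      length(suspicious_features), length(truth), length(split)
    )
  } else {
    n
  }
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    nodule_id = sprintf("N%03d", seq_len(n)),
    gvr_type = rep_len(gvr_type, n),
    size_mm = rep_len(size_mm, n),
    dl_score = rep_len(dl_score, n),
    suspicious_features = rep_len(suspicious_features, n),
    truth = rep_len(truth, n),
    split = rep_len(split, n),
    stringsAsFactors = FALSE
  )
}

random_cohort_df <- function(n, seed) {
  set.seed(seed)
  make_cohort_df(
    gvr_type = sample(c("I", "II", "III", "IV"), n, replace = TRUE),
    size_mm = round(runif(n, 0.5, 45), 2),
    dl_score = round(runif(n, 0, 100), 2),
    suspicious_features = runif(n) < 0.2,
    truth = sample(c("neoplastic", "non-neoplastic"), n, replace = TRUE),
    split = sample(c("training", "validation"), n, replace = TRUE),
    n = n
  )
}

# expand a confusion matrix into parallel 0/1 prediction/truth vectors
expand_cm <- function(tp, fp, fn, tn) {
  list(
    pred = c(rep(1, tp), rep(1, fp), rep(0, fn), rep(0, tn)),
    truth = c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
  )
}

# Pearson correlation of the expanded indicator vectors
mcc_cor_oracle <- function(tp, fp, fn, tn) {
  v <- expand_cm(tp, fp, fn, tn)
  suppressWarnings(stats::cor(v$pred, v$truth))
}

# brute-force Mann-Whitney probability over all positive-negative pairs,
# ties counted half, using the binary call as the score
mw_auc_oracle <- function(tp, fp, fn, tn) {
  v <- expand_cm(tp, fp, fn, tn)
  s_pos <- v$pred[v$truth == 1]
  s_neg <- v$pred[v$truth == 0]
  cmp <- outer(s_pos, s_neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# all (tp, fp, fn, tn) with the given total
cm_compositions <- function(total) {
  g <- expand.grid(tp = 0:total, fp = 0:total, fn = 0:total)
  g <- g[g$tp + g$fp + g$fn <= total, , drop = FALSE]
  g$tn <- total - g$tp - g$fp - g$fn
  g
}
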