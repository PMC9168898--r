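test_that("the default configuration carries the calibrated cohort structure", {
  cfg <- default_config()
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$prevalence, 527 / 551)
  expect_equal(cfg$size_mean_mm, 13.96)
  expect_equal(cfg$size_sd_mm, 6.58)
  expect_equal(cfg$nodules_per_patient, c(467, 33, 6) / 506)
  expect_equal(sum(cfg$gvr_probs_pos), 1, tolerance = 1e-12)
  expect_equal(sum(cfg$gvr_probs_neg), 1, tolerance = 1e-12)
  # score calibration hits its configured bin-mass targets
  tail_of <- function(s) {
    m <- s$mean / 100
    1 - pbeta(0.5, m * s$concentration, (1 - m) * s$concentration)
  }
  expect_equal(tail_of(cfg$dl_score_pos), 294 / 311, tolerance = 1e-8)
  expect_equal(1 - tail_of(cfg$dl_score_neg), 3 / 17, tolerance = 1e-8)
})

test_that("configuration invariants are enforced", {
  expect_error(default_config(n_patients = 0), "n_patients")
  cfg <- unclass(default_config())
  cfg$gvr_probs_pos <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(do.call(simulation_config, cfg), "sum to 1")
  cfg <- unclass(default_config())
  cfg$prevalence <- 1.2
  expect_error(do.call(simulation_config, cfg), "\\[0, 1\\]")
  cfg <- unclass(default_config())
  cfg$dl_score_pos$mean <- 150
  expect_error(do.call(simulation_config, cfg), "mean")
})

test_that("generation is deterministic given the seed and sensitive to it", {
  cfg <- default_config(n_patients = 300, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # byte-identical on disk too
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, pa)
  write_cohort(b, pb)
  expect_identical(readLines(pa), readLines(pb))
  other <- generate_cohort(default_config(n_patients = 300, seed = 6))
  expect_false(identical(as.data.frame(a), as.data.frame(other)))
  # the caller's RNG stream is not consumed
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_cohort(cfg))
  expect_identical(runif(1), before)
})

test_that("degenerate prevalence produces single-class cohorts", {
  cfg <- unclass(default_config(n_patients = 100, seed = 2))
  cfg$prevalence <- 0
  coh <- generate_cohort(do.call(simulation_config, cfg))
  expect_true(all(coh$truth == "non-neoplastic"))
  cfg$prevalence <- 1
  coh <- generate_cohort(do.call(simulation_config, cfg))
  expect_true(all(coh$truth == "neoplastic"))
})

test_that("generated cohorts satisfy the cohort invariants", {
  for (seed in c(3, 4)) {
    coh <- generate_cohort(default_config(n_patients = 150, seed = seed))
    expect_s3_class(coh, "ggn_cohort") # constructor re-validates everything
    expect_true(all(coh$size_mm > 0))
    expect_true(all(coh$dl_score >= 0 & coh$dl_score <= 100))
    expect_false(any(duplicated(paste(coh$patient_id, coh$nodule_id))))
    # split is constant within patient
    expect_true(all(tapply(as.character(coh$split), coh$patient_id, function(s) {
      length(unique(s)) == 1
    })))
    expect_equal(provenance(coh)$seed, seed)
  }
})

test_that("large-sample frequencies match the configured parameters", {
  cfg <- default_config(n_patients = 9200, seed = 31) # ~10,000 nodules
  coh <- generate_cohort(cfg)
  n <- nrow(coh)
  expect_gt(n, 9200)
  p <- cfg$prevalence
  expect_lt(
    abs(mean(coh$truth == "neoplastic") - p),
    3 * sqrt(p * (1 - p) / n)
  )
  s <- summarize_cohort(coh)
  overall <- s[s$split == "overall", ]
  expect_lt(
    abs(overall$size_mean_mm - cfg$size_mean_mm),
    3 * overall$size_sd_mm / sqrt(n)
  )
})

test_that("the closed-form oracle is exact on point-mass configurations", {
  base <- unclass(default_config(n_patients = 10))
  base$suspicious_prob_pos <- 0
  # all mass on type IV with a high score: every strategy calls positive
  hi <- base
  hi$gvr_probs_pos <- c(0, 0, 0, 1)
  hi$dl_score_pos <- list(mean = 90, concentration = 1e6)
  em <- expected_metrics(do.call(simulation_config, hi))
  expect_equal(em$sensitivity, c(1, 1, 1), tolerance = 1e-9)
  # all mass on type I, 10 mm, low score: every strategy calls negative
  lo <- base
  lo$gvr_probs_pos <- c(1, 0, 0, 0)
  lo$size_mean_mm <- 10
  lo$size_sd_mm <- 0.5
  lo$dl_score_pos <- list(mean = 10, concentration = 1e6)
  em <- expected_metrics(do.call(simulation_config, lo))
  expect_equal(em$sensitivity, c(0, 0, 0), tolerance = 1e-9)
})

test_that("pipeline metrics converge to the closed-form oracle", {
  cfg <- default_config(n_patients = 9200, seed = 17)
  coh <- generate_cohort(cfg)
  m <- evaluate_predictions(stratify_cohort(coh))
  em <- expected_metrics(cfg)
  pooled <- stats::aggregate(cbind(tp, fp, fn, tn) ~ strategy, as.data.frame(m), sum)
  for (i in seq_len(nrow(pooled))) {
    row <- pooled[i, ]
    exp_row <- em[em$strategy == row$strategy, ]
    n_pos <- row$tp + row$fn
    n_neg <- row$tn + row$fp
    sens <- row$tp / n_pos
    spec <- row$tn / n_neg
    se_sens <- sqrt(exp_row$sensitivity * (1 - exp_row$sensitivity) / n_pos)
    se_spec <- sqrt(exp_row$specificity * (1 - exp_row$specificity) / n_neg)
    expect_lt(abs(sens - exp_row$sensitivity), 3 * se_sens)
    expect_lt(abs(spec - exp_row$specificity), 3 * se_spec)
    expect_lt(
      abs((sens + spec) / 2 - exp_row$auc),
      3 * 0.5 * sqrt(se_sens^2 + se_spec^2)
    )
  }
})
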