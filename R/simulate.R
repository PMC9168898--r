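# Synthetic screening-cohort generator. The generative model draws, per
# nodule, a truth label, then GVR type, suspicious flag and malignancy
# score conditional on truth, and a truth-independent truncated-normal
# size. Because every stratification rule is a deterministic function of
# these features, the operating characteristics of all three strategies
# have closed forms (expected_metrics), which the Monte-Carlo pipeline is
# tested against.

#' Build a simulation configuration
#'
#' All knobs of the generative model. Probability vectors must sum to 1
#' (tolerance 1e-9). Score distributions are Beta laws rescaled to
#' `[0, 100]`, parameterised by `mean` (percent scale) and `concentration`
#' (the sum of the two Beta shapes); bounded support matches the percent
#' scale and two parameters suffice to place the bin masses.
#'
#' @param n_patients number of patients to simulate.
#' @param nodules_per_patient probability vector over 1, 2, 3 nodules.
#' @param prevalence probability that a nodule is neoplastic.
#' @param gvr_probs_pos,gvr_probs_neg probability 4-vectors over GVR types
#'   I..IV conditional on truth.
#' @param size_mean_mm,size_sd_mm target mean and parent-normal SD of the
#'   nodule diameter; sizes follow a normal truncated at `size_lower_mm`
#'   whose location is solved so the realized mean equals `size_mean_mm`.
#' @param size_lower_mm lower truncation bound (default 0.1 mm).
#' @param dl_score_pos,dl_score_neg lists `list(mean =, concentration =)`
#'   for the class-conditional score Beta laws (mean on the percent scale).
#' @param suspicious_prob_pos,suspicious_prob_neg probability of the
#'   radiologist suspicious-findings flag conditional on truth.
#' @param split_fraction_training probability that a *patient* (all of
#'   their nodules) is assigned to the training split.
#' @param seed integer seed; generation is deterministic given the config.
#' @return A validated `simulation_config` list.
#' @seealso [default_config()] for the calibrated defaults,
#'   [generate_cohort()], [expected_metrics()].
#' @export
simulation_config <- function(n_patients,
                              nodules_per_patient = c(467, 33, 6) / 506,
                              prevalence = 527 / 551,
                              gvr_probs_pos,
                              gvr_probs_neg,
                              size_mean_mm = 13.96,
                              size_sd_mm = 6.58,
                              size_lower_mm = 0.1,
                              dl_score_pos,
                              dl_score_neg,
                              suspicious_prob_pos = 0.05,
                              suspicious_prob_neg = 0,
                              split_fraction_training = 205 / 506,
                              seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    nodules_per_patient = as.numeric(nodules_per_patient),
    prevalence = as.numeric(prevalence),
    gvr_probs_pos = as.numeric(gvr_probs_pos),
    gvr_probs_neg = as.numeric(gvr_probs_neg),
    size_mean_mm = as.numeric(size_mean_mm),
    size_sd_mm = as.numeric(size_sd_mm),
    size_lower_mm = as.numeric(size_lower_mm),
    dl_score_pos = lapply(dl_score_pos, as.numeric),
    dl_score_neg = lapply(dl_score_neg, as.numeric),
    suspicious_prob_pos = as.numeric(suspicious_prob_pos),
    suspicious_prob_neg = as.numeric(suspicious_prob_neg),
    split_fraction_training = as.numeric(split_fraction_training),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  fail <- function(msg) stop(sprintf("invalid simulation config: %s", msg), call. = FALSE)
  prob1 <- function(p, what, len) {
    if (length(p) != len || anyNA(p) || any(p < 0) || any(p > 1)) {
      fail(sprintf("%s must be %d probabilities in [0, 1]", what, len))
    }
    if (abs(sum(p) - 1) > 1e-9) fail(sprintf("%s must sum to 1", what))
  }
  if (is.na(cfg$n_patients) || cfg$n_patients < 1) fail("n_patients must be >= 1")
  prob1(cfg$nodules_per_patient, "nodules_per_patient", 3)
  prob1(cfg$gvr_probs_pos, "gvr_probs_pos", 4)
  prob1(cfg$gvr_probs_neg, "gvr_probs_neg", 4)
  for (p in c(
    cfg$prevalence, cfg$suspicious_prob_pos, cfg$suspicious_prob_neg,
    cfg$split_fraction_training
  )) {
    if (is.na(p) || p < 0 || p > 1) fail("probabilities must lie in [0, 1]")
  }
  if (cfg$size_sd_mm <= 0 || cfg$size_mean_mm <= cfg$size_lower_mm) {
    fail("size_mean_mm must exceed size_lower_mm and size_sd_mm must be > 0")
  }
  for (side in c("dl_score_pos", "dl_score_neg")) {
    s <- cfg[[side]]
    if (is.null(s$mean) || is.null(s$concentration) ||
      s$mean <= 0 || s$mean >= 100 || s$concentration <= 0) {
      fail(sprintf("%s needs mean in (0, 100) and concentration > 0", side))
    }
  }
  invisible(cfg)
}

# location mu of a normal(mu, sd) truncated below at `lower` whose mean is
# `target`; solved by uniroot (monotone in mu)
trunc_normal_location <- function(target, sd, lower) {
  trunc_mean <- function(mu) {
    a <- (lower - mu) / sd
    # inverse Mills ratio on the log scale; stable for extreme a
    mu + sd * exp(stats::dnorm(a, log = TRUE) -
      stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
  }
  stats::uniroot(
    function(mu) trunc_mean(mu) - target,
    lower = lower - 10 * sd, upper = target + sd,
    tol = 1e-10
  )$root
}

# P(X >= cut) for the truncated normal above
trunc_normal_upper_tail <- function(cut, mu, sd, lower) {
  (1 - stats::pnorm((cut - mu) / sd)) / (1 - stats::pnorm((lower - mu) / sd))
}

# Beta mean (0..1) with given concentration whose upper tail above
# `threshold` equals `target`; monotone in the mean
beta_mean_for_tail <- function(target, concentration, threshold = 0.5) {
  tail_prob <- function(m) {
    1 - stats::pbeta(threshold, m * concentration, (1 - m) * concentration)
  }
  stats::uniroot(
    function(m) tail_prob(m) - target,
    lower = 1e-6, upper = 1 - 1e-6, tol = 1e-12
  )$root
}

# Class-conditional GVR probabilities from pooled counts. With pooled
# counts c_k over N = sum(c) nodules, N_neg expected non-neoplastic nodules
# split as q (probabilities), the neoplastic-class probabilities follow in
# closed form from the mixture identity: p_k = (c_k - N_neg * q_k) / N_pos.
gvr_class_conditionals <- function(pooled_counts = c(47, 58, 64, 381),
                                   neg_expected = c(6.5, 6.5, 4, 7)) {
  n_neg <- sum(neg_expected)
  n_pos <- sum(pooled_counts) - n_neg
  q <- neg_expected / n_neg
  p <- (pooled_counts - n_neg * q) / n_pos
  if (any(p < 0)) stop("infeasible GVR calibration", call. = FALSE)
  list(pos = p, neg = q)
}

#' Default calibrated simulation configuration
#'
#' The defaults emulate a high-prevalence GGN screening cohort:
#'
#' * prevalence 527/551; nodules per patient distributed (467, 33, 6)/506;
#'   training fraction 205/506 of patients;
#' * pooled GVR-type frequencies (47, 58, 64, 381)/551, split between the
#'   truth classes in closed form with the non-neoplastic class skewed
#'   toward types I/II (expected non-neoplastic counts 6.5/6.5/4/7), so the
#'   rule-only strategy's sensitivity and specificity land near the
#'   reference operating characteristics;
#' * nodule size: normal truncated at 0.1 mm, location solved so the mean
#'   is 13.96 mm at parent SD 6.58 mm, truth-independent;
#' * malignancy scores: Beta laws on `[0, 100]` whose means are solved so
#'   that P(score >= 50 | neoplastic) = 294/311 and
#'   P(score < 50 | non-neoplastic) = 3/17, at concentrations 6 and 4;
#' * suspicious-findings flag: probability 0.05 for neoplastic nodules,
#'   0 for non-neoplastic.
#'
#' @param n_patients number of patients (default 506).
#' @param seed integer seed stored in the config (default 1).
#' @return A `simulation_config`.
#' @export
default_config <- function(n_patients = 506, seed = 1L) {
  gvr <- gvr_class_conditionals()
  simulation_config(
    n_patients = n_patients,
    gvr_probs_pos = gvr$pos,
    gvr_probs_neg = gvr$neg,
    dl_score_pos = list(
      mean = 100 * beta_mean_for_tail(294 / 311, 6), concentration = 6
    ),
    dl_score_neg = list(
      mean = 100 * beta_mean_for_tail(14 / 17, 4), concentration = 4
    ),
    seed = seed
  )
}

#' Generate a synthetic GGN cohort
#'
#' Draws a cohort from the generative model in `config`, deterministically
#' given `config$seed` (a private RNG stream is used; the caller's
#' `.Random.seed` is untouched). Sizes and scores are rounded to two
#' decimals, matching how such measurements are reported. The provenance
#' attribute records the seed and the full configuration.
#'
#' @param config a [simulation_config()].
#' @return A [ggn_cohort()].
#' @examples
#' coh <- generate_cohort(default_config(n_patients = 50, seed = 7))
#' summarize_cohort(coh)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, unclass(config))
  }
  validate_config(config)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(config$seed)

  n_pat <- config$n_patients
  k <- sample.int(3L, n_pat, replace = TRUE, prob = config$nodules_per_patient)
  split_pat <- ifelse(
    stats::runif(n_pat) < config$split_fraction_training, "training", "validation"
  )
  n <- sum(k)
  pid <- rep(sprintf("P%0*d", max(4L, nchar(n_pat)), seq_len(n_pat)), k)
  nid <- paste0(pid, "-N", sequence(k))
  split <- rep(split_pat, k)

  pos <- stats::runif(n) < config$prevalence
  gvr <- character(n)
  if (any(pos)) {
    gvr[pos] <- sample(GVR_LEVELS, sum(pos), replace = TRUE, prob = config$gvr_probs_pos)
  }
  if (any(!pos)) {
    gvr[!pos] <- sample(GVR_LEVELS, sum(!pos), replace = TRUE, prob = config$gvr_probs_neg)
  }

  mu <- trunc_normal_location(config$size_mean_mm, config$size_sd_mm, config$size_lower_mm)
  a0 <- stats::pnorm((config$size_lower_mm - mu) / config$size_sd_mm)
  size <- mu + config$size_sd_mm *
    stats::qnorm(a0 + stats::runif(n) * (1 - a0))

  score <- numeric(n)
  draw_score <- function(m, spec) {
    mean01 <- spec$mean / 100
    100 * stats::rbeta(m, mean01 * spec$concentration, (1 - mean01) * spec$concentration)
  }
  if (any(pos)) score[pos] <- draw_score(sum(pos), config$dl_score_pos)
  if (any(!pos)) score[!pos] <- draw_score(sum(!pos), config$dl_score_neg)

  flag_prob <- ifelse(pos, config$suspicious_prob_pos, config$suspicious_prob_neg)
  flag <- stats::runif(n) < flag_prob

  ggn_cohort(
    data.frame(
      patient_id = pid,
      nodule_id = nid,
      gvr_type = gvr,
      size_mm = pmax(round(size, 2), config$size_lower_mm),
      dl_score = pmin(pmax(round(score, 2), 0), 100),
      suspicious_features = flag,
      truth = ifelse(pos, "neoplastic", "non-neoplastic"),
      split = split,
      stringsAsFactors = FALSE
    ),
    provenance = list(
      source = "synthetic", seed = config$seed, config = unclass(config)
    )
  )
}

#' Closed-form expected operating characteristics
#'
#' Because the three strategies are deterministic functions of the
#' generated features, their expected sensitivity, specificity and
#' single-point AUC follow exactly from the configuration by enumerating
#' the discrete cells (GVR type, suspicious flag) and integrating the size
#' and score densities over each rule region:
#'
#' * rule-only positive: type III/IV, or the suspicious flag on a
#'   category-3 nodule (type II, or type I with size >= 30 mm);
#' * score-only positive: score >= 50 (medium/high bin);
#' * combined positive: type III/IV, or a category-3 nodule that is either
#'   flagged (4X) or upgraded by a medium/high score bin.
#'
#' This is the independent oracle the Monte-Carlo pipeline is validated
#' against; it shares no sampling code with [generate_cohort()].
#'
#' @param config a [simulation_config()].
#' @return Data frame with one row per strategy (`clung_rads`, `dl_only`,
#'   `dl_based_clung_rads`) and columns `sensitivity`, `specificity`,
#'   `auc`.
#' @export
expected_metrics <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, unclass(config))
  }
  validate_config(config)
  mu <- trunc_normal_location(config$size_mean_mm, config$size_sd_mm, config$size_lower_mm)
  s30 <- trunc_normal_upper_tail(30, mu, config$size_sd_mm, config$size_lower_mm)

  class_positive <- function(g, f, score_spec) {
    m <- score_spec$mean / 100
    p_medhigh <- 1 - stats::pbeta(
      0.5, m * score_spec$concentration, (1 - m) * score_spec$concentration
    )
    cat3 <- g[2] + g[1] * s30 # type II any size, type I >= 30 mm
    c(
      clung_rads = g[3] + g[4] + f * cat3,
      dl_only = p_medhigh,
      dl_based_clung_rads = g[3] + g[4] + cat3 * (f + (1 - f) * p_medhigh)
    )
  }
  p_pos <- class_positive(config$gvr_probs_pos, config$suspicious_prob_pos, config$dl_score_pos)
  p_neg <- class_positive(config$gvr_probs_neg, config$suspicious_prob_neg, config$dl_score_neg)

  sens <- p_pos
  spec <- 1 - p_neg
  data.frame(
    strategy = names(sens),
    sensitivity = unname(sens),
    specificity = unname(spec),
    auc = unname((sens + spec) / 2),
    stringsAsFactors = FALSE
  )
}
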