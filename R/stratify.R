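# The deterministic rule engine. Three strategies are derived for every
# nodule: the rule-only category (complementary Lung-RADS 1.1), the
# score-only call, and the combined model that upgrades rule categories by
# one step on a medium/high score bin.

#' Assign the complementary Lung-RADS 1.1 category
#'
#' Categorises a pure GGN from its GGN-vessel-relationship (GVR) type, its
#' mean diameter, and the radiologist's suspicious-findings flag:
#'
#' * category 2 — type I with size < 30 mm;
#' * category 3 — type I with size >= 30 mm, or type II (any size);
#' * category 4A — type III, any size;
#' * category 4B — type IV, any size;
#' * category 4X — a nodule whose category so far is 3, 4A or 4B and that
#'   carries additional features or imaging findings increasing the
#'   suspicion of malignancy. Category 2 is never escalated by the flag.
#'
#' Exactly one rule fires for every valid input, so the function is total
#' and single-valued. Vectorised; scalar arguments are recycled.
#'
#' @param gvr_type GVR type, `"I"`..`"IV"` (character or factor).
#' @param size_mm mean axial diameter in millimetres, > 0.
#' @param suspicious_features logical flag (default `FALSE`).
#' @return Ordered factor of risk categories (see [rads_categories()]).
#' @examples
#' classify_clung_rads("I", 15, FALSE) # 2
#' classify_clung_rads("IV", 8, FALSE) # 4B
#' classify_clung_rads("II", 12, TRUE) # 4X
#' @export
classify_clung_rads <- function(gvr_type, size_mm, suspicious_features = FALSE) {
  g <- gvr_factor(gvr_type)
  size_mm <- as.numeric(size_mm)
  if (anyNA(g) || anyNA(size_mm) || anyNA(suspicious_features)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  if (any(size_mm <= 0)) stop("size_mm must be > 0", call. = FALSE)
  n <- max(length(g), length(size_mm), length(suspicious_features))
  g <- rep_len(g, n)
  size_mm <- rep_len(size_mm, n)
  flag <- rep_len(as.logical(suspicious_features), n)

  base <- character(n)
  base[g == "I" & size_mm < 30] <- "2"
  base[(g == "I" & size_mm >= 30) | g == "II"] <- "3"
  base[g == "III"] <- "4A"
  base[g == "IV"] <- "4B"
  base[flag & base %in% c("3", "4A", "4B")] <- "4X"
  rads_factor(base)
}

#' Bin a malignancy-risk score
#'
#' Maps a percent-scale score to the three risk bins: low on `[0, 50)`,
#' medium on `[50, 70)`, high on `[70, 100]`. Intervals are half-open and
#' lower-inclusive, so a score of exactly 50 is medium and exactly 70 is
#' high.
#'
#' @param dl_score numeric vector in `[0, 100]`.
#' @return Ordered factor low < medium < high.
#' @examples
#' bin_dl_score(c(30, 50, 70, 100)) # low, medium, high, high
#' @export
bin_dl_score <- function(dl_score) {
  dl_score <- as.numeric(dl_score)
  if (anyNA(dl_score)) stop("missing values are not allowed", call. = FALSE)
  if (any(dl_score < 0 | dl_score > 100)) {
    stop("dl_score must lie in [0, 100]", call. = FALSE)
  }
  bin_factor(ifelse(dl_score < 50, "low", ifelse(dl_score < 70, "medium", "high")))
}

#' Upgrade a rule category with the score bin
#'
#' The combined model's one-step upgrade: categories 2 and 4X are fixed
#' points (managed on the initial classification whatever the score); for
#' categories 3, 4A and 4B a low bin keeps the category and a medium or
#' high bin upgrades exactly one step (3 to 4A, 4A to 4B, 4B to 4X). The
#' result is never below the input category.
#'
#' @param initial initial risk category (character or factor).
#' @param dl_bin risk bin (character or factor; see [bin_dl_score()]).
#' @return Ordered factor of final categories.
#' @examples
#' combine_categories("3", "high") # 4A
#' combine_categories("4B", "medium") # 4X
#' combine_categories("2", "high") # 2
#' @export
combine_categories <- function(initial, dl_bin) {
  i <- rads_factor(initial)
  b <- bin_factor(dl_bin)
  if (anyNA(i) || anyNA(b)) stop("missing values are not allowed", call. = FALSE)
  n <- max(length(i), length(b))
  i <- rep_len(as.character(i), n)
  b <- rep_len(as.character(b), n)
  step_up <- c("2" = "2", "3" = "4A", "4A" = "4B", "4B" = "4X", "4X" = "4X")
  rads_factor(ifelse(b == "low", i, unname(step_up[i])))
}

#' Binarize a risk category at the neoplasm point
#'
#' A final category of 4A or above predicts a neoplastic lesion.
#'
#' @param category risk category (character or factor).
#' @return Logical vector: `TRUE` for categories 4A, 4B, 4X.
#' @export
binarize_category <- function(category) {
  r <- rads_rank(rads_factor(category))
  if (anyNA(r)) stop("missing values are not allowed", call. = FALSE)
  r >= match("4A", RADS_LEVELS)
}

#' Score-only positivity rule
#'
#' A nodule with a medium or high malignancy-risk bin is called positive by
#' the score-only strategy.
#'
#' @param dl_bin risk bin (character or factor).
#' @return Logical vector.
#' @export
dl_only_positive <- function(dl_bin) {
  b <- bin_factor(dl_bin)
  if (anyNA(b)) stop("missing values are not allowed", call. = FALSE)
  as.character(b) %in% c("medium", "high")
}

#' Stratify every nodule in a cohort under all three strategies
#'
#' Applies the rule engine to a cohort and returns one row per nodule with
#' the rule-only category, the score bin, the combined (upgraded) category,
#' and the binary call of each strategy at the category-4A neoplasm point
#' (the score-only strategy is positive on a medium/high bin).
#'
#' @param cohort a [ggn_cohort()].
#' @return A `ggn_predictions` data.frame with columns `patient_id`,
#'   `nodule_id`, `truth`, `split`, `clung_category`, `dl_bin`,
#'   `combined_category`, `clung_positive`, `dl_positive`,
#'   `combined_positive`.
#' @examples
#' coh <- ggn_cohort(data.frame(
#'   patient_id = "P1", nodule_id = "N1", gvr_type = "III", size_mm = 10,
#'   dl_score = 80, suspicious_features = FALSE, truth = "neoplastic",
#'   split = "training"
#' ))
#' stratify_cohort(coh) # rule 4A, bin high, combined 4B; all calls positive
#' @export
stratify_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "ggn_cohort"))
  if (nrow(cohort) == 0) stop("cannot stratify an empty cohort", call. = FALSE)
  clung <- classify_clung_rads(
    cohort$gvr_type, cohort$size_mm, cohort$suspicious_features
  )
  bin <- bin_dl_score(cohort$dl_score)
  combined <- combine_categories(clung, bin)
  out <- data.frame(
    patient_id = cohort$patient_id,
    nodule_id = cohort$nodule_id,
    truth = cohort$truth,
    split = cohort$split,
    clung_category = clung,
    dl_bin = bin,
    combined_category = combined,
    clung_positive = binarize_category(clung),
    dl_positive = dl_only_positive(bin),
    combined_positive = binarize_category(combined),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("ggn_predictions", "data.frame"))
}
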