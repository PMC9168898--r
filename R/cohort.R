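# Cohort container and CSV I/O. A cohort is a validated data.frame with one
# row per nodule; validation collects every offending row before failing so
# bad files are reported in one pass.

COHORT_COLUMNS <- c(
  "patient_id", "nodule_id", "gvr_type", "size_mm", "dl_score",
  "suspicious_features", "truth", "split"
)

#' Construct a validated GGN cohort
#'
#' Builds a `ggn_cohort` (a `data.frame` subclass) from per-nodule records.
#' Columns: `patient_id`, `nodule_id` (opaque identifiers, unique as a
#' pair), `gvr_type` (`"I"`..`"IV"`), `size_mm` (mean axial diameter,
#' millimetres, > 0), `dl_score` (malignancy risk on the percent scale,
#' `[0, 100]`), `suspicious_features` (logical; radiologist-flagged
#' additional findings), `truth` (`"neoplastic"` / `"non-neoplastic"`), and
#' `split` (`"training"` / `"validation"`).
#'
#' Scores are stored on the percent scale. A table whose scores all lie in
#' `[0, 1]` is rejected as almost certainly fraction-scaled; rescaling is
#' the caller's responsibility, never silent.
#'
#' Validation is all-or-nothing: every offending row is listed in the error
#' (condition class `"cohort_validation_error"`, with the problem table in
#' its `problems` field). Missing values are errors, not imputed, so the
#' rule engine is total on any cohort that constructs.
#'
#' @param records data.frame with the columns above (extra columns are
#'   dropped; tokens are parsed strictly).
#' @param provenance named list of free-text metadata (source, seed,
#'   generator configuration); stored as an attribute.
#' @return A `ggn_cohort`.
#' @seealso [read_cohort()], [write_cohort()], [summarize_cohort()]
#' @export
ggn_cohort <- function(records, provenance = list(source = "user")) {
  records <- as.data.frame(records)
  missing <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing) > 0) {
    stop(sprintf("missing cohort column(s): %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  d <- data.frame(
    patient_id = as.character(records$patient_id),
    nodule_id = as.character(records$nodule_id),
    gvr_type = factor(toupper(as.character(records$gvr_type)),
      levels = GVR_LEVELS, ordered = TRUE
    ),
    size_mm = suppressWarnings(as.numeric(records$size_mm)),
    dl_score = suppressWarnings(as.numeric(records$dl_score)),
    suspicious_features = parse_bool(records$suspicious_features),
    truth = factor(tolower(as.character(records$truth)), levels = TRUTH_LEVELS),
    split = factor(tolower(as.character(records$split)), levels = SPLIT_LEVELS),
    stringsAsFactors = FALSE
  )
  problems <- cohort_problems(d, records)
  if (nrow(problems) > 0) {
    shown <- utils::head(problems, 10)
    stop(errorCondition(
      paste0(
        sprintf("invalid cohort: %d problem(s)\n", nrow(problems)),
        paste(sprintf(
          "  row %d [%s]: %s", shown$row, shown$field, shown$problem
        ), collapse = "\n"),
        if (nrow(problems) > 10) sprintf("\n  ... and %d more", nrow(problems) - 10) else ""
      ),
      class = c("cohort_validation_error", "ggnrads_error"),
      problems = problems
    ))
  }
  structure(d, provenance = provenance, class = c("ggn_cohort", "data.frame"))
}

# one row per problem: (row, field, problem)
cohort_problems <- function(d, raw) {
  probs <- list()
  note <- function(rows, field, msg) {
    if (length(rows) > 0) {
      probs[[length(probs) + 1]] <<- data.frame(
        row = rows, field = field, problem = msg, stringsAsFactors = FALSE
      )
    }
  }
  note(which(is.na(d$patient_id) | d$patient_id == ""), "patient_id", "missing identifier")
  note(which(is.na(d$nodule_id) | d$nodule_id == ""), "nodule_id", "missing identifier")
  note(which(is.na(d$gvr_type)), "gvr_type", sprintf(
    "unparseable GVR token (admissible: %s)", paste(GVR_LEVELS, collapse = ", ")
  ))
  note(which(is.na(d$size_mm)), "size_mm", "not a number")
  note(which(!is.na(d$size_mm) & d$size_mm <= 0), "size_mm", "must be > 0")
  note(which(is.na(d$dl_score)), "dl_score", "not a number")
  note(
    which(!is.na(d$dl_score) & (d$dl_score < 0 | d$dl_score > 100)),
    "dl_score", "outside [0, 100]"
  )
  note(which(is.na(d$suspicious_features)), "suspicious_features", "not true/false")
  note(which(is.na(d$truth)), "truth", "not neoplastic/non-neoplastic")
  note(which(is.na(d$split)), "split", "not training/validation")
  key <- paste(d$patient_id, d$nodule_id, sep = "\r")
  note(which(duplicated(key)), "nodule_id", "duplicate (patient_id, nodule_id)")
  if (nrow(d) >= 2 && !anyNA(d$dl_score) && all(d$dl_score <= 1)) {
    note(
      seq_len(nrow(d)), "dl_score",
      "all scores lie in [0, 1]; scores must be on the percent scale [0, 100]"
    )
  }
  if (length(probs) == 0) {
    return(data.frame(row = integer(), field = character(), problem = character()))
  }
  out <- do.call(rbind, probs)
  out[order(out$row), , drop = FALSE]
}

parse_bool <- function(x) {
  if (is.logical(x)) {
    return(x)
  }
  tok <- tolower(as.character(x))
  out <- rep(NA, length(tok))
  out[tok %in% c("true", "t", "1")] <- TRUE
  out[tok %in% c("false", "f", "0")] <- FALSE
  out
}

#' Provenance metadata of a cohort
#'
#' @param cohort a `ggn_cohort`.
#' @return The provenance list attached at construction (source, seed,
#'   generator configuration, ...).
#' @export
provenance <- function(cohort) attr(cohort, "provenance")

#' @export
print.ggn_cohort <- function(x, ...) {
  p <- provenance(x)
  cat(sprintf(
    "GGN cohort: %d nodules, %d patients (source: %s)\n",
    nrow(x), length(unique(x$patient_id)),
    if (is.null(p$source)) "unknown" else p$source
  ))
  if (nrow(x) > 0) {
    print(utils::head(as.data.frame(x), 6))
    if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  }
  invisible(x)
}

#' Read a nodule cohort from CSV
#'
#' Reads a comma-separated, UTF-8, header-first cohort table and validates
#' it into a [ggn_cohort()]. The expected columns are the canonical schema
#' (`patient_id, nodule_id, gvr_type, size_mm, dl_score,
#' suspicious_features, truth, split`); `schema` remaps differently named
#' files onto it. Every malformed row is reported with its row number and
#' reason in a single validation error.
#'
#' @param path file path to a CSV.
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(size_mm = "diameter")`; unmapped columns are taken by their
#'   canonical name.
#' @return A validated `ggn_cohort` with the file path recorded as
#'   provenance.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- utils::read.csv(path,
    colClasses = "character", check.names = FALSE,
    stringsAsFactors = FALSE
  )
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), COHORT_COLUMNS)
    if (length(bad) > 0) {
      stop(sprintf("schema maps unknown column(s): %s", paste(bad, collapse = ", ")),
        call. = FALSE
      )
    }
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw)) {
        stop(sprintf("schema column '%s' not present in %s", src, path), call. = FALSE)
      }
      raw[[canon]] <- raw[[src]]
    }
  }
  missing <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s: missing column(s): %s", path, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  ggn_cohort(raw, provenance = list(source = path))
}

#' Write a cohort to CSV
#'
#' Serialises with a deterministic dialect: canonical column order, header
#' row, comma separator, booleans as `"true"`/`"false"`, categories by
#' their labels, numerics at up to 15 significant digits. The dialect
#' round-trips: `read_cohort()` on the written file recovers the data model
#' field-for-field.
#'
#' @param cohort a `ggn_cohort`.
#' @param path destination file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ggn_cohort"))
  ids <- c(cohort$patient_id, cohort$nodule_id)
  if (any(grepl('[",\n\r]', ids))) {
    stop("identifiers may not contain commas, quotes or newlines", call. = FALSE)
  }
  out <- data.frame(
    patient_id = cohort$patient_id,
    nodule_id = cohort$nodule_id,
    gvr_type = as.character(cohort$gvr_type),
    size_mm = as.character(cohort$size_mm),
    dl_score = as.character(cohort$dl_score),
    suspicious_features = ifelse(cohort$suspicious_features, "true", "false"),
    truth = as.character(cohort$truth),
    split = as.character(cohort$split),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path,
    sep = ",", quote = FALSE, row.names = FALSE,
    col.names = TRUE, fileEncoding = "UTF-8", eol = "\n"
  )
  invisible(path)
}

#' Summarise a cohort the way screening-study baseline tables do
#'
#' Per split and overall: nodule and patient counts, neoplastic count and
#' prevalence, nodule size mean and SD (sample SD, n-1 denominator), and
#' GVR-type frequencies.
#'
#' @param cohort a non-empty `ggn_cohort`.
#' @return A `cohort_summary` data.frame with one row per split plus an
#'   `"overall"` row.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "ggn_cohort"))
  if (nrow(cohort) == 0) stop("cannot summarise an empty cohort", call. = FALSE)
  one <- function(d, label) {
    gvr <- table(d$gvr_type)
    data.frame(
      split = label,
      n_nodules = nrow(d),
      n_patients = length(unique(d$patient_id)),
      n_neoplastic = sum(d$truth == "neoplastic"),
      prevalence = mean(d$truth == "neoplastic"),
      size_mean_mm = mean(d$size_mm),
      size_sd_mm = stats::sd(d$size_mm),
      gvr_I = as.integer(gvr[["I"]]),
      gvr_II = as.integer(gvr[["II"]]),
      gvr_III = as.integer(gvr[["III"]]),
      gvr_IV = as.integer(gvr[["IV"]]),
      stringsAsFactors = FALSE
    )
  }
  splits <- intersect(SPLIT_LEVELS, unique(as.character(cohort$split)))
  rows <- lapply(splits, function(s) one(cohort[cohort$split == s, , drop = FALSE], s))
  out <- do.call(rbind, c(rows, list(one(cohort, "overall"))))
  rownames(out) <- NULL
  structure(out, class = c("cohort_summary", "data.frame"))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    cat(sprintf(
      "  %-10s %5d nodules / %5d patients | neoplastic %d (%.1f%%) | size %.2f +/- %.2f mm | GVR I/II/III/IV = %d/%d/%d/%d\n",
      r$split, r$n_nodules, r$n_patients, r$n_neoplastic, 100 * r$prevalence,
      r$size_mean_mm, r$size_sd_mm, r$gvr_I, r$gvr_II, r$gvr_III, r$gvr_IV
    ))
  }
  invisible(x)
}
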