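#' @name cohort
#' @title Cohort objects
#'
#' @description A `cohort` bundles one study site's per-subject records:
#' demographics (age, sex, education, APOE e4 carrier status), clinical
#' diagnosis, CSF analytes (Abeta42, t-Tau, p-Tau181, complement C3, factor
#' H), optional longitudinal cognitive visits, and the cognitively normal
#' reference subjects used to harmonize C3 across assay platforms.
#'
#' Diagnosis takes one of four values: `NORMAL` (cognitively normal),
#' `MCI_OTHER` (mild cognitive impairment with CSF t-Tau/Abeta42 below the
#' inclusion threshold), `MCI_AD` (MCI with ratio >= 0.39, taken as
#' early-stage Alzheimer's disease) and `AD` (mild AD dementia).
NULL

DIAGNOSIS_LEVELS <- c("NORMAL", "MCI_OTHER", "MCI_AD", "AD")
SEX_LEVELS <- c("MALE", "FEMALE")
ANALYTES <- c("abeta42", "ttau", "ptau181", "c3_raw", "fh")

# canonical per-subject columns, in on-disk order
SUBJECT_COLUMNS <- c(
  "subject_id", "diagnosis", "age", "sex", "education", "apoe4_carrier",
  "abeta42", "ttau", "ptau181", "c3_raw", "fh", "c3_z"
)
VISIT_COLUMNS <- c("subject_id", "months_from_baseline", "executive_z", "memory_z")

#' Construct a cohort
#'
#' @param subjects data.frame with (at least) columns `subject_id`,
#'   `diagnosis`, `age`, `sex`, `education`, `apoe4_carrier`, `abeta42`,
#'   `ttau`, `ptau181`, `c3_raw`, `fh`; a `c3_z` column is added (all `NA`)
#'   if absent -- it is only populated by [normalize_c3()].
#' @param cohort_id short string identifying the cohort (e.g. a site name).
#' @param visits optional long-format data.frame of longitudinal cognitive
#'   visits with columns `subject_id`, `months_from_baseline`,
#'   `executive_z`, `memory_z`; months must be strictly increasing within
#'   subject.
#' @param normal_reference optional data.frame of cognitively normal
#'   subjects (same columns as `subjects`) used as the z-scoring reference
#'   for log C3. Defaults to the `NORMAL` rows of `subjects`. May be a
#'   disjoint set.
#' @param metadata optional named list of assay metadata (detection limits,
#'   inter-plate CVs); carried along, never used in computation.
#' @return an object of class `cohort`.
#' @export
new_cohort <- function(subjects, cohort_id = "cohort", visits = NULL,
                       normal_reference = NULL, metadata = list()) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  if (!"c3_z" %in% names(subjects)) subjects$c3_z <- NA_real_
  missing_cols <- setdiff(SUBJECT_COLUMNS, names(subjects))
  if (length(missing_cols)) {
    stop("cohort subjects table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  subjects <- subjects[SUBJECT_COLUMNS]
  if (is.null(visits)) {
    visits <- data.frame(subject_id = character(), months_from_baseline = numeric(),
                         executive_z = numeric(), memory_z = numeric(),
                         stringsAsFactors = FALSE)
  }
  visits <- as.data.frame(visits, stringsAsFactors = FALSE)[VISIT_COLUMNS]
  if (is.null(normal_reference)) {
    normal_reference <- subjects[subjects$diagnosis == "NORMAL", , drop = FALSE]
  } else {
    normal_reference <- as.data.frame(normal_reference, stringsAsFactors = FALSE)
    if (!"c3_z" %in% names(normal_reference)) normal_reference$c3_z <- NA_real_
    normal_reference <- normal_reference[SUBJECT_COLUMNS]
  }
  x <- structure(
    list(cohort_id = as.character(cohort_id), subjects = subjects,
         visits = visits, normal_reference = normal_reference,
         metadata = metadata, c3_normalized = FALSE),
    class = "cohort"
  )
  validate_cohort(x)
  x
}

#' Validate a cohort's structural invariants
#'
#' Checks subject-id uniqueness, diagnosis and sex levels, analyte
#' positivity, the MCI-AD inclusion rule (t-Tau/Abeta42 >= 0.39), and the
#' strict ordering of visit times within subject. Called by [new_cohort()];
#' exported for use after manual edits.
#'
#' @param x a `cohort`.
#' @param ratio_threshold inclusion threshold for the MCI-AD rule
#'   (default 0.39).
#' @return `x`, invisibly; errors describe the offending rows/subjects.
#' @export
validate_cohort <- function(x, ratio_threshold = 0.39) {
  stopifnot(inherits(x, "cohort"))
  s <- x$subjects
  if (anyDuplicated(s$subject_id)) {
    stop("duplicate subject_id in cohort '", x$cohort_id, "': ",
         paste(unique(s$subject_id[duplicated(s$subject_id)]), collapse = ", "))
  }
  bad_dx <- !s$diagnosis %in% DIAGNOSIS_LEVELS
  if (any(bad_dx)) {
    stop("unknown diagnosis value(s): ", paste(unique(s$diagnosis[bad_dx]), collapse = ", "))
  }
  bad_sex <- !is.na(s$sex) & !s$sex %in% SEX_LEVELS
  if (any(bad_sex)) {
    stop("unknown sex value(s): ", paste(unique(s$sex[bad_sex]), collapse = ", "))
  }
  for (a in ANALYTES) {
    bad <- !is.na(s[[a]]) & s[[a]] <= 0
    if (any(bad)) {
      stop("non-positive ", a, " for subject(s): ",
           paste(s$subject_id[bad], collapse = ", "))
    }
  }
  bad_age <- !is.na(s$age) & s$age <= 0
  if (any(bad_age)) {
    stop("non-positive age for subject(s): ", paste(s$subject_id[bad_age], collapse = ", "))
  }
  mci <- s$diagnosis == "MCI_AD" & !is.na(s$ttau) & !is.na(s$abeta42)
  if (any(mci)) {
    viol <- mci & (s$ttau / s$abeta42 < ratio_threshold)
    if (any(viol)) {
      stop("MCI_AD subject(s) violate t-Tau/Abeta42 >= ", ratio_threshold, ": ",
           paste(s$subject_id[viol], collapse = ", "))
    }
  }
  v <- x$visits
  if (nrow(v)) {
    if (any(v$months_from_baseline < 0, na.rm = TRUE)) {
      stop("negative months_from_baseline in visits")
    }
    by_subj <- split(v$months_from_baseline, v$subject_id)
    nondec <- vapply(by_subj, function(m) any(diff(m) <= 0), logical(1))
    if (any(nondec)) {
      stop("visit months not strictly increasing for subject(s): ",
           paste(names(by_subj)[nondec], collapse = ", "))
    }
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", x$cohort_id, ": ", nrow(x$subjects), " subjects (",
      paste(vapply(DIAGNOSIS_LEVELS, function(d) {
        sprintf("%s=%d", d, sum(x$subjects$diagnosis == d))
      }, character(1)), collapse = ", "),
      "), ", nrow(x$visits), " visits, ",
      nrow(x$normal_reference), " normal-reference subjects",
      if (isTRUE(x$c3_normalized)) ", C3 z-scored" else "", "\n", sep = "")
  invisible(x)
}

# sniff delimiter from extension; default comma
read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Read a cohort from a subjects CSV/TSV (plus optional visits file)
#'
#' @param path path to a delimited file with one row per subject, header
#'   required, `.` decimal separator. `.tsv`/`.txt` extensions are read as
#'   tab-separated, anything else as comma-separated.
#' @param schema optional named character vector mapping canonical column
#'   names (see [new_cohort()]) to the file's column names, e.g.
#'   `c(abeta42 = "AB42", ttau = "TAU")`. Unmapped canonical names are
#'   looked up verbatim.
#' @param visits_path optional path to a long-format visits file with
#'   columns `subject_id`, `months_from_baseline`, `executive_z`,
#'   `memory_z`.
#' @param cohort_id cohort identifier; defaults to the file stem.
#' @param normal_reference passed to [new_cohort()].
#' @return a `cohort`. Rows failing type/positivity checks abort with the
#'   offending row numbers and subject ids.
#' @export
read_cohort <- function(path, schema = NULL, visits_path = NULL,
                        cohort_id = NULL, normal_reference = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- read_delim_auto(path)
  cohort_id <- cohort_id %||% sub("\\.[^.]+$", "", basename(path))

  resolve <- function(canonical) {
    src <- if (!is.null(schema) && canonical %in% names(schema)) schema[[canonical]] else canonical
    src
  }
  required <- setdiff(SUBJECT_COLUMNS, c("education", "c3_z"))
  for (col in required) {
    if (!resolve(col) %in% names(raw)) {
      stop("schema error: required column '", resolve(col),
           "' (canonical '", col, "') not found in ", path)
    }
  }
  get_col <- function(canonical) {
    src <- resolve(canonical)
    if (src %in% names(raw)) raw[[src]] else rep(NA, nrow(raw))
  }
  num_col <- function(canonical) {
    v <- get_col(canonical)
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      stop("validation error in ", path, ": non-numeric '", canonical,
           "' at row(s) ", paste(bad, collapse = ", "))
    }
    out
  }
  bool_col <- function(canonical) {
    v <- get_col(canonical)
    if (is.logical(v)) return(v)
    up <- toupper(trimws(as.character(v)))
    out <- rep(NA, length(v))
    out[up %in% c("TRUE", "T", "1", "YES", "Y")] <- TRUE
    out[up %in% c("FALSE", "F", "0", "NO", "N")] <- FALSE
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      stop("validation error in ", path, ": unparseable '", canonical,
           "' at row(s) ", paste(bad, collapse = ", "))
    }
    out
  }
  subjects <- data.frame(
    subject_id = as.character(get_col("subject_id")),
    diagnosis = toupper(trimws(as.character(get_col("diagnosis")))),
    age = num_col("age"),
    sex = toupper(trimws(as.character(get_col("sex")))),
    education = num_col("education"),
    apoe4_carrier = bool_col("apoe4_carrier"),
    abeta42 = num_col("abeta42"),
    ttau = num_col("ttau"),
    ptau181 = num_col("ptau181"),
    c3_raw = num_col("c3_raw"),
    fh = num_col("fh"),
    c3_z = num_col("c3_z"),
    stringsAsFactors = FALSE
  )
  for (a in c(ANALYTES, "age")) {
    bad <- which(!is.na(subjects[[a]]) & subjects[[a]] <= 0)
    if (length(bad)) {
      stop("validation error in ", path, ": non-positive ", a, " at row(s) ",
           paste(bad, collapse = ", "), " (subject ",
           paste(subjects$subject_id[bad], collapse = ", "), ")")
    }
  }
  visits <- NULL
  if (!is.null(visits_path)) {
    if (!file.exists(visits_path)) stop("visits file not found: ", visits_path)
    vraw <- read_delim_auto(visits_path)
    miss <- setdiff(VISIT_COLUMNS, names(vraw))
    if (length(miss)) {
      stop("schema error: visits file missing column(s): ", paste(miss, collapse = ", "))
    }
    visits <- data.frame(
      subject_id = as.character(vraw$subject_id),
      months_from_baseline = as.numeric(vraw$months_from_baseline),
      executive_z = as.numeric(vraw$executive_z),
      memory_z = as.numeric(vraw$memory_z),
      stringsAsFactors = FALSE
    )
  }
  cohort <- new_cohort(subjects, cohort_id = cohort_id, visits = visits,
                       normal_reference = normal_reference)
  if (any(!is.na(subjects$c3_z))) cohort$c3_normalized <- TRUE
  cohort
}

# format doubles at full precision so write -> read is the identity
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a cohort to canonical CSV
#'
#' Subjects go to `path` with canonical column names; if the cohort has
#' longitudinal visits they go to a companion long-format file keyed by
#' `subject_id` (default: `<path stem>_visits.csv`). Numeric values are
#' written at full precision so that [read_cohort()] after `write_cohort()`
#' reproduces every field exactly.
#'
#' @param cohort a `cohort`.
#' @param path output CSV path for the subjects table.
#' @param visits_path output CSV path for the visits table; only written
#'   when the cohort has visits.
#' @return invisibly, the path(s) written.
#' @export
write_cohort <- function(cohort, path,
                         visits_path = sub("(\\.[^.]+)?$", "_visits.csv",
                                           path)[1]) {
  stopifnot(inherits(cohort, "cohort"))
  s <- cohort$subjects
  out <- s
  for (col in c("age", "education", ANALYTES, "c3_z")) {
    out[[col]] <- format_full(s[[col]])
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  written <- path
  if (nrow(cohort$visits)) {
    v <- cohort$visits
    vo <- v
    for (col in c("months_from_baseline", "executive_z", "memory_z")) {
      vo[[col]] <- format_full(v[[col]])
    }
    write.csv(vo, visits_path, row.names = FALSE, quote = TRUE, na = "NA")
    written <- c(written, visits_path)
  }
  invisible(written)
}

#' MCI-due-to-AD inclusion rule
#'
#' A subject with mild cognitive impairment is classified as MCI due to AD
#' when the CSF t-Tau/Abeta42 ratio is at least 0.39 (inclusive boundary).
#'
#' @param ttau t-Tau, pg/mL (vectorized).
#' @param abeta42 Abeta42, pg/mL (vectorized; must be positive).
#' @param threshold ratio threshold, default 0.39.
#' @return logical vector: `TRUE` where `ttau / abeta42 >= threshold`.
#' @export
#' @examples
#' apply_ad_filter(39, 100)   # boundary ratio 0.39 -> TRUE
#' apply_ad_filter(38.9, 100) # just below -> FALSE
apply_ad_filter <- function(ttau, abeta42, threshold = 0.39) {
  if (any(is.na(ttau)) || any(is.na(abeta42))) {
    stop("undefined ratio: ttau/abeta42 missing")
  }
  if (any(abeta42 <= 0)) stop("undefined ratio: abeta42 must be positive")
  if (any(ttau <= 0)) stop("undefined ratio: ttau must be positive")
  ttau / abeta42 >= threshold
}

#' Harmonize C3 by z-scoring log levels against the cognitively normal reference
#'
#' C3 concentrations are right-skewed and assay-dependent, so raw levels are
#' log-transformed and standardized per cohort against that cohort's own
#' cognitively normal reference subjects: `c3_z = (ln(c3_raw) - m) / s`,
#' where `m` and `s` are the sample mean and sample SD (n-1 denominator) of
#' `ln(c3_raw)` over the cohort's `normal_reference`. Normalization is
#' strictly per cohort and never pooled: a cohort-level multiplicative assay
#' shift only translates `ln(c3_raw)` and is removed by the subtraction,
#' which is what allows cohorts measured on different platforms to be
#' compared.
#'
#' @param cohort a `cohort` with a non-empty `normal_reference` (>= 2
#'   subjects with positive `c3_raw`).
#' @return the cohort with `c3_z` populated on subjects and on the reference
#'   itself, and `c3_normalized` set.
#' @export
normalize_c3 <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  ref <- cohort$normal_reference
  ref_c3 <- ref$c3_raw[!is.na(ref$c3_raw)]
  if (length(ref_c3) < 2) {
    stop("insufficient reference: need >= 2 cognitively normal subjects with C3, got ",
         length(ref_c3))
  }
  if (any(ref_c3 <= 0)) stop("reference c3_raw must be positive")
  logc3 <- log(ref_c3)
  m <- mean(logc3)
  s <- sd(logc3)
  if (s == 0) {
    stop("degenerate reference: zero variance in log C3 over the normal reference")
  }
  zscore <- function(x) (log(x) - m) / s
  cohort$subjects$c3_z <- ifelse(is.na(cohort$subjects$c3_raw), NA_real_,
                                 zscore(cohort$subjects$c3_raw))
  cohort$normal_reference$c3_z <- ifelse(is.na(ref$c3_raw), NA_real_,
                                         zscore(ref$c3_raw))
  cohort$c3_normalized <- TRUE
  cohort$c3_reference <- list(mean_log = m, sd_log = s, n = length(ref_c3))
  cohort
}
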