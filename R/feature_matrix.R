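EXPERIMENTS <- c("EXP1", "EXP2")
EXP1_FEATURES <- c("age", "sex_male01", "apoe4_01", "abeta42", "ttau", "ptau181")
EXP2_FEATURES <- c(EXP1_FEATURES, "c3_z", "fh")

experiment_features <- function(experiment) {
  switch(match.arg(experiment, EXPERIMENTS),
         EXP1 = EXP1_FEATURES,
         EXP2 = EXP2_FEATURES)
}

#' Build the per-experiment design matrix for stage classification
#'
#' Restricts the cohort to the two AD stages (`MCI_AD`, labeled 0, and `AD`,
#' labeled 1) and assembles the numeric feature matrix for one of the two
#' feature-set experiments:
#' \describe{
#'   \item{EXP1}{6 features: age, sex (male = 1), APOE e4 carrier (1/0),
#'     CSF Abeta42, t-Tau, p-Tau181.}
#'   \item{EXP2}{EXP1 plus harmonized C3 (`c3_z`, see [normalize_c3()]) and
#'     factor H (untransformed).}
#' }
#' Subjects with any missing required feature are excluded (complete-case);
#' their ids are recorded in the result and reported via the verbose log.
#'
#' @param cohort a `cohort`; must have been through [normalize_c3()] when
#'   `experiment = "EXP2"`.
#' @param experiment `"EXP1"` or `"EXP2"`.
#' @param subject_ids optional subset of subject ids to consider (used
#'   internally to align experiments on a common complete-case set).
#' @return an object of class `feature_matrix`: list with `x` (numeric
#'   matrix), `y` (0 = MCI_AD, 1 = AD), `feature_names`, `experiment`,
#'   `subject_ids`, `dropped_ids`.
#' @export
build_feature_matrix <- function(cohort, experiment = c("EXP1", "EXP2"),
                                 subject_ids = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  experiment <- match.arg(experiment)
  if (experiment == "EXP2" && !isTRUE(cohort$c3_normalized)) {
    stop("normalize_c3() must be applied to the cohort before building EXP2 features")
  }
  s <- cohort$subjects
  s <- s[s$diagnosis %in% c("MCI_AD", "AD"), , drop = FALSE]
  if (!is.null(subject_ids)) s <- s[s$subject_id %in% subject_ids, , drop = FALSE]
  if (!nrow(s)) stop("empty matrix: no MCI_AD or AD subjects in cohort '",
                     cohort$cohort_id, "'")
  raw <- data.frame(
    age = s$age,
    sex_male01 = as.numeric(s$sex == "MALE"),
    apoe4_01 = as.numeric(s$apoe4_carrier),
    abeta42 = s$abeta42,
    ttau = s$ttau,
    ptau181 = s$ptau181,
    c3_z = s$c3_z,
    fh = s$fh
  )
  feats <- experiment_features(experiment)
  x <- as.matrix(raw[feats])
  complete <- stats::complete.cases(x)
  dropped <- s$subject_id[!complete]
  if (length(dropped)) {
    xmittn_log("build_feature_matrix(", experiment, "): dropped ",
               length(dropped), " incomplete subject(s): ",
               paste(dropped, collapse = ", "))
  }
  x <- x[complete, , drop = FALSE]
  s <- s[complete, , drop = FALSE]
  if (!nrow(x)) stop("empty matrix: no complete-case subjects for ", experiment)
  rownames(x) <- s$subject_id
  structure(
    list(x = x, y = as.integer(s$diagnosis == "AD"),
         feature_names = feats, experiment = experiment,
         subject_ids = s$subject_id, dropped_ids = dropped),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", x$experiment, ": ", nrow(x$x), " x ", ncol(x$x),
      " (", sum(x$y == 0), " MCI_AD, ", sum(x$y == 1), " AD; ",
      length(x$dropped_ids), " dropped)\n", sep = "")
  invisible(x)
}

# ids complete for every requested experiment, so all experiments share rows
complete_case_ids <- function(cohort, experiments) {
  ids <- NULL
  for (e in experiments) {
    fm <- build_feature_matrix(cohort, e)
    ids <- if (is.null(ids)) fm$subject_ids else intersect(ids, fm$subject_ids)
  }
  ids
}
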