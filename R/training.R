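#' Stages One-Three: repeated-CV Gini distributions for every
#' algorithm x experiment cell
#'
#' For every fold of the split plan, every requested algorithm is fit on
#' the fold's train rows under every requested feature-set experiment and
#' scored on the fold's CV rows; the CV Gini index is recorded. The same
#' splits are shared by every algorithm x experiment cell, so cells differ
#' only in learner and feature set, never in data. The per-cell empirical
#' p-value is the fraction of fold Gini values at or below 0
#' ([stage3_pvalue()]).
#'
#' To keep the splits shared, only subjects with complete features for
#' *all* requested experiments are used. Folds whose CV set ends up
#' single-class (possible in unstratified mode) are recorded as missing and
#' excluded from the p-value denominator; their count is kept in the
#' result.
#'
#' @param cohort training `cohort` ([normalize_c3()] must have been applied
#'   when `"EXP2"` is among the experiments).
#' @param plan optional [make_splits()] plan; built from `n_folds`,
#'   `train_size`, `cv_size`, `master_seed`, `stratified` when `NULL`.
#' @param algorithms character vector of algorithm names (default all
#'   nine); hyperparameter overrides via `hyperparameters`, a named list of
#'   per-algorithm lists.
#' @param experiments feature-set experiments (default both).
#' @param n_folds,train_size,cv_size,stratified used only when
#'   `plan = NULL`; defaults 1000/180/50/stratified.
#' @param master_seed master seed; per-fold fit seeds are derived from
#'   `(master_seed, fold, algorithm)`.
#' @param hyperparameters named list: `list(SVM = list(cost = 2), ...)`.
#' @return an object of class `xmittn_training`: list with `gini` (3-d
#'   array algorithm x experiment x fold), `p_values` (matrix
#'   algorithm x experiment), `dropped_folds` (per-cell count of missing
#'   folds), the plan, and bookkeeping.
#' @export
run_training_stage <- function(cohort, plan = NULL,
                               algorithms = xmittn_algorithms(),
                               experiments = c("EXP1", "EXP2"),
                               n_folds = 1000L, train_size = 180L,
                               cv_size = 50L, master_seed = 1L,
                               stratified = TRUE,
                               hyperparameters = list()) {
  stopifnot(inherits(cohort, "cohort"))
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)
  experiments <- match.arg(experiments, EXPERIMENTS, several.ok = TRUE)

  ids <- complete_case_ids(cohort, experiments)
  fms <- lapply(experiments, function(e) build_feature_matrix(cohort, e, subject_ids = ids))
  names(fms) <- experiments
  y <- fms[[1]]$y
  if (length(unique(y)) < 2) stop("training cohort must contain both MCI_AD and AD")
  if (is.null(plan)) {
    plan <- make_splits(y, n_folds = n_folds, train_size = train_size,
                        cv_size = cv_size, master_seed = master_seed,
                        stratified = stratified)
  }
  stopifnot(inherits(plan, "split_plan"), plan$n_subjects == length(y))

  gini <- array(NA_real_,
                dim = c(length(algorithms), length(experiments), plan$n_folds),
                dimnames = list(algorithms, experiments, NULL))
  for (f in seq_len(plan$n_folds)) {
    tr <- plan$train[[f]]
    cv <- plan$cv[[f]]
    cv_single <- length(unique(y[cv])) < 2
    for (a in algorithms) {
      seed_fa <- derive_seed(master_seed, "fit", f, a)
      spec <- algorithm_spec(a, hyperparameters[[a]] %||% list(), seed = seed_fa)
      for (e in experiments) {
        if (cv_single) next
        fm <- fms[[e]]
        fold_train <- structure(
          list(x = fm$x[tr, , drop = FALSE], y = fm$y[tr],
               feature_names = fm$feature_names, experiment = e,
               subject_ids = fm$subject_ids[tr], dropped_ids = character()),
          class = "feature_matrix"
        )
        g <- tryCatch({
          model <- fit_classifier(spec, fold_train)
          s <- score_model(model, fm$x[cv, , drop = FALSE])
          compute_gini(fm$y[cv], s)
        }, error = function(err) {
          xmittn_log("fold ", f, " ", a, " x ", e, " failed: ",
                     conditionMessage(err))
          NA_real_
        })
        gini[a, e, f] <- g
      }
    }
  }
  p_values <- apply(gini, c(1, 2), function(g) {
    if (all(is.na(g))) NA_real_ else stage3_pvalue(g)
  })
  dropped <- apply(gini, c(1, 2), function(g) sum(is.na(g)))
  structure(
    list(gini = gini, p_values = p_values, dropped_folds = dropped,
         algorithms = algorithms, experiments = experiments, plan = plan,
         subject_ids = fms[[1]]$subject_ids, master_seed = plan$master_seed,
         cohort_id = cohort$cohort_id),
    class = "xmittn_training"
  )
}

#' @export
print.xmittn_training <- function(x, ...) {
  cat("<xmittn_training> ", x$cohort_id, ": ", length(x$subject_ids),
      " subjects, ", x$plan$n_folds, " folds\n p-values (fraction of folds with Gini <= 0):\n",
      sep = "")
  print(round(x$p_values, 3))
  invisible(x)
}

#' Stage-Three model selection
#'
#' Selects every algorithm x experiment cell with `p < alpha`, strictly and
#' unadjusted (each selected cell still faces an independent test cohort,
#' so no multiplicity correction is applied at this stage). An empty
#' selection is a legitimate outcome.
#'
#' @param training an `xmittn_training` result (or its p-value matrix).
#' @param alpha significance threshold (default 0.05; strict `<`).
#' @return data.frame with columns `algorithm`, `experiment`, `p_value`,
#'   possibly zero rows.
#' @export
select_models <- function(training, alpha = 0.05) {
  p <- if (inherits(training, "xmittn_training")) training$p_values else as.matrix(training)
  if (!length(p)) stop("empty training results")
  hits <- which(!is.na(p) & p < alpha, arr.ind = TRUE)
  out <- data.frame(
    algorithm = rownames(p)[hits[, 1]],
    experiment = colnames(p)[hits[, 2]],
    p_value = p[hits],
    stringsAsFactors = FALSE
  )
  out[order(out$p_value), , drop = FALSE]
}

#' Stage Four, step one: freeze the final model
#'
#' Refits the selected (algorithm, experiment) once on *all* eligible
#' training-cohort subjects; the resulting `frozen_model` transfers to the
#' independent test cohort without any refitting. Freezing a combination
#' that was not Stage-3 selected is allowed but logged with a warning.
#'
#' @param cohort training `cohort`.
#' @param algorithm algorithm name.
#' @param experiment `"EXP1"` or `"EXP2"`.
#' @param selection optional [select_models()] output for the warning
#'   policy.
#' @param hyperparameters optional hyperparameter overrides for this
#'   algorithm.
#' @param master_seed seed for the final fit.
#' @return a `frozen_model` (see [save_model()] for on-disk transfer).
#' @export
freeze_final_model <- function(cohort, algorithm, experiment,
                               selection = NULL, hyperparameters = list(),
                               master_seed = 1L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  experiment <- match.arg(experiment, EXPERIMENTS)
  if (!is.null(selection) && nrow(selection) >= 0) {
    sel <- paste(selection$algorithm, selection$experiment)
    if (!(paste(algorithm, experiment) %in% sel)) {
      warning("freezing ", algorithm, " x ", experiment,
              ", which was not Stage-3 selected")
    }
  }
  fm <- build_feature_matrix(cohort, experiment)
  spec <- algorithm_spec(algorithm, hyperparameters,
                         seed = derive_seed(master_seed, "freeze", algorithm, experiment))
  fit_classifier(spec, fm)
}

#' Stage Four: bootstrap validation of a frozen model on the test cohort
#'
#' Generates `n_boot` class-balanced bootstrap test sets (default 50 MCI-AD
#' + 50 AD, sampled with replacement within class -- replacement is forced
#' because a test cohort may hold fewer subjects than slots), scores each
#' with the frozen model, and records the replicate Gini index. The
#' external p-value is the fraction of replicate Gini values at or below 0.
#' Sensitivity (AD labeled AD), specificity (MCI-AD labeled MCI-AD) and
#' accuracy are averaged over replicates, and per-subject sampling /
#' labeled-AD tallies are accumulated for the P(AD) score
#' ([compute_pad()]).
#'
#' @param model a `frozen_model` (its experiment decides the feature set).
#' @param test_cohort independent test `cohort`, z-scored against its *own*
#'   normal reference when the model uses EXP2 features.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param per_class subjects drawn per class per replicate (default 50).
#' @param master_seed integer seed for the bootstrap draws.
#' @return an object of class `bootstrap_validation`: replicate `gini`
#'   vector, `p_value`, mean `sensitivity`/`specificity`/`accuracy`
#'   (fractions), and a `tallies` data.frame (`subject_id`,
#'   `times_sampled`, `times_labeled_ad`, true `stage`).
#' @export
bootstrap_validate <- function(model, test_cohort, n_boot = 1000L,
                               per_class = 50L, master_seed = 1L) {
  stopifnot(inherits(model, "frozen_model"), inherits(test_cohort, "cohort"))
  fm <- build_feature_matrix(test_cohort, model$experiment)
  idx0 <- which(fm$y == 0L)
  idx1 <- which(fm$y == 1L)
  if (!length(idx0) || !length(idx1)) {
    stop("test cohort must contain both MCI_AD and AD subjects")
  }
  # a frozen model is deterministic: score every test subject once
  scores <- score_model(model, fm)
  pred <- as.integer(scores >= model$threshold)

  n <- length(fm$y)
  gini <- numeric(n_boot)
  sens <- numeric(n_boot)
  spec <- numeric(n_boot)
  acc <- numeric(n_boot)
  sampled <- integer(n)
  labeled_ad <- integer(n)
  for (b in seq_len(n_boot)) {
    draw <- with_seed(derive_seed(master_seed, "boot", b), {
      c(sample(idx0, per_class, replace = TRUE),
        sample(idx1, per_class, replace = TRUE))
    })
    yb <- fm$y[draw]
    gini[b] <- compute_gini(yb, scores[draw])
    pb <- pred[draw]
    sens[b] <- mean(pb[yb == 1L] == 1L)
    spec[b] <- mean(pb[yb == 0L] == 0L)
    acc[b] <- mean(pb == yb)
    tab <- tabulate(draw, nbins = n)
    sampled <- sampled + tab
    labeled_ad <- labeled_ad + tab * (pred == 1L)
  }
  structure(
    list(algorithm = model$spec$name, experiment = model$experiment,
         n_boot = as.integer(n_boot), per_class = as.integer(per_class),
         gini = gini, p_value = stage3_pvalue(gini),
         sensitivity = mean(sens), specificity = mean(spec),
         accuracy = mean(acc),
         tallies = data.frame(subject_id = fm$subject_ids,
                              times_sampled = sampled,
                              times_labeled_ad = labeled_ad,
                              stage = ifelse(fm$y == 1L, "AD", "MCI_AD"),
                              stringsAsFactors = FALSE),
         master_seed = as.integer(master_seed)),
    class = "bootstrap_validation"
  )
}

#' @export
print.bootstrap_validation <- function(x, ...) {
  cat("<bootstrap_validation> ", x$algorithm, " x ", x$experiment, ": ",
      x$n_boot, " replicates of ", x$per_class, "+", x$per_class, "\n",
      sprintf(" p = %.3f; mean sensitivity %.1f %%, specificity %.1f %%, accuracy %.1f %%\n",
              x$p_value, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$accuracy), sep = "")
  invisible(x)
}

#' Combined training/test p-value table
#'
#' One row per algorithm with four p-value columns: the two training-cohort
#' experiments for every algorithm, and the test-cohort experiments filled
#' only for combinations that were carried into Stage-4 validation (other
#' cells stay `NA`, matching the published layout where untested cells are
#' blank). Cells with p < alpha are flagged.
#'
#' @param training an `xmittn_training` result.
#' @param validations optional list of `bootstrap_validation` results.
#' @param alpha flagging threshold (default 0.05).
#' @return data.frame of class `xmittn_report` with columns `algorithm`,
#'   `p_exp1_train`, `p_exp2_train`, `p_exp1_test`, `p_exp2_test`,
#'   `significant`.
#' @export
report_table2 <- function(training, validations = list(), alpha = 0.05) {
  stopifnot(inherits(training, "xmittn_training"))
  p <- training$p_values
  out <- data.frame(algorithm = rownames(p), stringsAsFactors = FALSE)
  out$p_exp1_train <- if ("EXP1" %in% colnames(p)) p[, "EXP1"] else NA_real_
  out$p_exp2_train <- if ("EXP2" %in% colnames(p)) p[, "EXP2"] else NA_real_
  out$p_exp1_test <- NA_real_
  out$p_exp2_test <- NA_real_
  if (inherits(validations, "bootstrap_validation")) validations <- list(validations)
  for (v in validations) {
    col <- if (v$experiment == "EXP1") "p_exp1_test" else "p_exp2_test"
    out[out$algorithm == v$algorithm, col] <- v$p_value
  }
  pcols <- c("p_exp1_train", "p_exp2_train", "p_exp1_test", "p_exp2_test")
  out$significant <- apply(out[pcols], 1, function(r) any(!is.na(r) & r < alpha))
  rownames(out) <- NULL
  class(out) <- c("xmittn_report", "data.frame")
  out
}

#' @export
print.xmittn_report <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in grep("^p_", names(y), value = TRUE)) {
    y[[col]] <- ifelse(is.na(y[[col]]), "", sprintf("%.3f", y[[col]]))
  }
  print(y, row.names = FALSE)
  invisible(x)
}
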