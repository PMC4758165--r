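#' Repeated random train/CV split plan for the training cohort
#'
#' Draws `n_folds` independent random partitions of the training-cohort
#' rows into a train set (default n = 180) and a disjoint internal
#' cross-validation set (default n = 50), sampling without replacement
#' within each fold. By default the splits are stratified by class label so
#' that every fold's train and CV sets preserve the cohort's MCI-AD : AD
#' proportion to within integer rounding; an unstratified mode is available
#' (single-class CV sets then become possible and are dropped downstream).
#' Fully reproducible from `master_seed`.
#'
#' @param labels 0/1 class labels of the cohort rows (stratification uses
#'   them; in unstratified mode only their length matters).
#' @param n_folds number of random splits (default 1000).
#' @param train_size per-fold training-set size (default 180).
#' @param cv_size per-fold CV-set size (default 50).
#' @param master_seed integer master seed.
#' @param stratified stratify splits by class (default `TRUE`).
#' @return an object of class `split_plan`: list with `train` and `cv`
#'   (lists of disjoint index vectors) plus the configuration.
#' @export
make_splits <- function(labels, n_folds = 1000L, train_size = 180L,
                        cv_size = 50L, master_seed = 1L, stratified = TRUE) {
  n <- length(labels)
  labels <- as.integer(labels)
  if (train_size + cv_size > n) {
    stop("configuration error: train_size + cv_size (", train_size + cv_size,
         ") exceeds cohort size (", n, ")")
  }
  idx1 <- which(labels == 1L)
  idx0 <- which(labels == 0L)
  if (stratified) {
    t1 <- round(train_size * length(idx1) / n)
    t0 <- train_size - t1
    c1 <- round(cv_size * length(idx1) / n)
    c0 <- cv_size - c1
    if (t1 + c1 > length(idx1) || t0 + c0 > length(idx0)) {
      stop("configuration error: stratified sizes exceed per-class counts")
    }
  }
  train <- vector("list", n_folds)
  cv <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    seed_f <- derive_seed(master_seed, "split", f)
    if (stratified) {
      picks <- with_seed(seed_f, {
        s1 <- sample(idx1, t1 + c1)
        s0 <- sample(idx0, t0 + c0)
        list(tr = c(s1[seq_len(t1)], s0[seq_len(t0)]),
             cv = c(s1[-seq_len(t1)], s0[-seq_len(t0)]))
      })
    } else {
      picks <- with_seed(seed_f, {
        s <- sample.int(n, train_size + cv_size)
        list(tr = s[seq_len(train_size)], cv = s[-seq_len(train_size)])
      })
    }
    train[[f]] <- sort(picks$tr)
    cv[[f]] <- sort(picks$cv)
  }
  structure(
    list(train = train, cv = cv, n_folds = as.integer(n_folds),
         train_size = as.integer(train_size), cv_size = as.integer(cv_size),
         n_subjects = n, master_seed = as.integer(master_seed),
         stratified = stratified),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> ", x$n_folds, " folds of ", x$n_subjects, " subjects: ",
      x$train_size, " train + ", x$cv_size, " cv",
      if (x$stratified) ", stratified" else "", " (seed ", x$master_seed,
      ")\n", sep = "")
  invisible(x)
}
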