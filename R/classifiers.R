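#' @name classifiers
#' @title The nine-classifier registry
#'
#' @description The framework treats the learning algorithm itself as part
#' of the biomarker hypothesis, so nine standard classifiers run under one
#' uniform contract: [fit_classifier()] returns a `frozen_model`,
#' [score_model()] returns continuous AD-likeness scores (class probability
#' where the learner provides one, signed distance to the decision boundary
#' otherwise), and [predict_model()] thresholds the score into hard 0/1
#' stage labels. Nothing downstream depends on any one learner.
#'
#' The reference configuration (all hyperparameters overridable through
#' `algorithm_spec()`):
#' \describe{
#'   \item{LOGISTIC}{binomial GLM on standardized features.}
#'   \item{PERCEPTRON}{averaged perceptron, 100 epochs, standardized
#'     features; score is the linear margin.}
#'   \item{DECISION_TREE}{CART (`rpart`) with its usual defaults.}
#'   \item{BOOSTED_TREE}{100 boosted depth-1 trees (stumps), learning rate
#'     0.3, logistic loss.}
#'   \item{GRADIENT_BOOSTING}{100 boosted depth-3 trees, learning rate 0.1,
#'     logistic loss.}
#'   \item{NAIVE_BAYES}{Gaussian naive Bayes (`e1071`).}
#'   \item{RANDOM_FOREST}{500 trees (`ranger`), probability forest.}
#'   \item{KNN}{k = 5 nearest neighbours on standardized features; score is
#'     the neighbour vote fraction.}
#'   \item{SVM}{radial-basis-kernel SVM (`e1071`), cost 1; score is the
#'     signed decision value, oriented so larger means more AD-like.}
#' }
#' Scale-sensitive learners (LOGISTIC, PERCEPTRON, KNN, SVM) standardize
#' features internally using training-fold means/SDs only; the parameters
#' are stored in the frozen model, so cross-validation never leaks CV-fold
#' statistics into the fit.
NULL

ALGORITHMS <- c("LOGISTIC", "PERCEPTRON", "DECISION_TREE", "BOOSTED_TREE",
                "GRADIENT_BOOSTING", "NAIVE_BAYES", "RANDOM_FOREST",
                "KNN", "SVM")
# learners standardized internally (z-score with training statistics)
SCALED_ALGORITHMS <- c("LOGISTIC", "PERCEPTRON", "KNN", "SVM")
# learners whose score is a signed margin (threshold 0) rather than a
# probability (threshold 0.5)
MARGIN_ALGORITHMS <- c("PERCEPTRON", "SVM")

default_hyperparameters <- function(name) {
  switch(name,
    LOGISTIC = list(),
    PERCEPTRON = list(epochs = 100L, learning_rate = 1),
    DECISION_TREE = list(cp = 0.01, minsplit = 20L),
    BOOSTED_TREE = list(nrounds = 100L, max_depth = 1L, eta = 0.3),
    GRADIENT_BOOSTING = list(nrounds = 100L, max_depth = 3L, eta = 0.1),
    NAIVE_BAYES = list(laplace = 0),
    RANDOM_FOREST = list(num_trees = 500L),
    KNN = list(k = 5L),
    SVM = list(cost = 1, kernel = "radial")
  )
}

#' Specify one of the nine classification algorithms
#'
#' @param name one of `r paste0('\x60', ALGORITHMS, '\x60', collapse = ", ")`.
#' @param hyperparameters named list of overrides merged over the reference
#'   configuration (see [classifiers]).
#' @param seed integer seed for the learner's internal randomness.
#' @return an object of class `algorithm_spec`.
#' @export
algorithm_spec <- function(name, hyperparameters = list(), seed = 1L) {
  if (!is.character(name) || length(name) != 1L || !name %in% ALGORITHMS) {
    stop("unknown algorithm '", paste(name, collapse = ","),
         "'; must be one of: ", paste(ALGORITHMS, collapse = ", "))
  }
  hp <- utils::modifyList(default_hyperparameters(name), as.list(hyperparameters))
  structure(list(name = name, hyperparameters = hp, seed = as.integer(seed)),
            class = "algorithm_spec")
}

#' List the nine supported algorithm names
#' @return character vector of algorithm names in canonical order.
#' @export
xmittn_algorithms <- function() ALGORITHMS

standardize_params <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1 # constant column: leave centered only
  list(center = ctr, scale = scl)
}

apply_standardization <- function(x, std) {
  if (is.null(std)) return(x)
  scale(x, center = std$center, scale = std$scale)[, , drop = FALSE]
}

# averaged perceptron on y in {-1,+1}; returns list(w, b)
fit_perceptron <- function(x, y, epochs, lr, seed) {
  ord <- with_seed(seed, sample.int(nrow(x))) # one fixed presentation order
  perceptron_train_cpp(x, as.integer(y), ord, as.integer(epochs), lr)
}

#' Fit a frozen classifier on a feature matrix
#'
#' Deterministic given `(spec, features)`: all internal randomness derives
#' from `spec$seed`. Scale-sensitive learners standardize with
#' training-data statistics, stored in the returned model.
#'
#' @param spec an [algorithm_spec()] (or an algorithm name, taken with
#'   default hyperparameters and seed).
#' @param features a `feature_matrix` from [build_feature_matrix()] (both
#'   classes must be present).
#' @return an object of class `frozen_model` holding the fitted state, the
#'   feature names captured at fit time, the standardization parameters and
#'   the decision threshold.
#' @export
fit_classifier <- function(spec, features) {
  if (is.character(spec)) spec <- algorithm_spec(spec)
  stopifnot(inherits(spec, "algorithm_spec"), inherits(features, "feature_matrix"))
  x <- features$x
  y <- features$y
  if (!nrow(x)) stop("degenerate training: empty feature matrix")
  if (length(unique(y)) < 2) {
    stop("degenerate training: only one class present in labels")
  }
  hp <- spec$hyperparameters
  std <- if (spec$name %in% SCALED_ALGORITHMS) standardize_params(x) else NULL
  xs <- apply_standardization(x, std)
  df <- data.frame(xs, y = factor(y, levels = c(0, 1)))
  fitted <- switch(spec$name,
    LOGISTIC = {
      # glm.fit directly: identical model to glm(y ~ .), without the
      # formula-interface overhead that dominates at repeated-CV scale
      gf <- suppressWarnings(
        stats::glm.fit(cbind(1, xs), y, family = stats::binomial())
      )
      cf <- gf$coefficients
      cf[is.na(cf)] <- 0 # collinear columns contribute nothing
      list(coefficients = cf, converged = gf$converged)
    },
    PERCEPTRON = fit_perceptron(xs, y, hp$epochs, hp$learning_rate, spec$seed),
    DECISION_TREE = rpart::rpart(
      y ~ ., data = df, method = "class",
      control = rpart::rpart.control(cp = hp$cp, minsplit = hp$minsplit)
    ),
    BOOSTED_TREE = ,
    GRADIENT_BOOSTING = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                    eta = hp$eta, nthread = 1, seed = spec$seed),
      data = xgboost::xgb.DMatrix(xs, label = y, nthread = 1),
      nrounds = hp$nrounds, verbose = 0
    ),
    NAIVE_BAYES = e1071::naiveBayes(xs, factor(y, levels = c(0, 1)),
                                    laplace = hp$laplace),
    RANDOM_FOREST = ranger::ranger(
      y ~ ., data = df, num.trees = hp$num_trees, probability = TRUE,
      num.threads = 1, seed = spec$seed
    ),
    KNN = list(train_x = xs, train_y = factor(y, levels = c(0, 1)), k = hp$k),
    SVM = e1071::svm(xs, factor(y, levels = c(0, 1)), kernel = hp$kernel,
                     cost = hp$cost, scale = FALSE)
  )
  model <- structure(
    list(spec = spec, fitted = fitted,
         feature_names = features$feature_names,
         experiment = features$experiment,
         standardization = std,
         threshold = if (spec$name %in% MARGIN_ALGORITHMS) 0 else 0.5,
         orientation = 1),
    class = "frozen_model"
  )
  if (spec$name == "SVM") {
    # e1071 signs decision values by the first training label encountered;
    # calibrate orientation empirically so larger score = more AD-like
    dv <- svm_decision_values(model, xs)
    m1 <- mean(dv[y == 1]); m0 <- mean(dv[y == 0])
    if (isTRUE(m1 < m0)) model$orientation <- -1
  }
  model
}

svm_decision_values <- function(model, xs) {
  pr <- predict(model$fitted, xs, decision.values = TRUE)
  as.numeric(attr(pr, "decision.values"))
}

check_features <- function(model, features) {
  nm <- if (inherits(features, "feature_matrix")) features$feature_names else colnames(features)
  if (!identical(nm, model$feature_names)) {
    stop("feature mismatch: model was fit on [",
         paste(model$feature_names, collapse = ", "), "], got [",
         paste(nm, collapse = ", "), "]")
  }
  if (inherits(features, "feature_matrix")) features$x else features
}

#' Continuous AD-likeness scores from a frozen model
#'
#' Higher score = more AD-like. Probability learners return the class-1
#' probability; margin learners (perceptron, SVM) return the signed
#' distance to the decision boundary. Ties are permitted.
#'
#' @param model a `frozen_model`.
#' @param features a `feature_matrix` (or bare numeric matrix with matching
#'   column names) whose feature names must equal those captured at fit
#'   time.
#' @return numeric vector, one score per row.
#' @export
score_model <- function(model, features) {
  stopifnot(inherits(model, "frozen_model"))
  x <- check_features(model, features)
  xs <- apply_standardization(x, model$standardization)
  nd <- data.frame(xs)
  s <- switch(model$spec$name,
    MANUAL = as.numeric(model$fitted(x)),
    LOGISTIC = as.numeric(stats::plogis(cbind(1, xs) %*% model$fitted$coefficients)),
    PERCEPTRON = as.numeric(xs %*% model$fitted$w + model$fitted$b),
    DECISION_TREE = as.numeric(predict(model$fitted, nd, type = "prob")[, "1"]),
    BOOSTED_TREE = ,
    GRADIENT_BOOSTING = as.numeric(
      predict(model$fitted, xgboost::xgb.DMatrix(xs, nthread = 1))
    ),
    NAIVE_BAYES = as.numeric(predict(model$fitted, xs, type = "raw")[, "1"]),
    RANDOM_FOREST = as.numeric(
      predict(model$fitted, nd, num.threads = 1)$predictions[, "1"]
    ),
    KNN = {
      pr <- class::knn(model$fitted$train_x, xs, model$fitted$train_y,
                       k = model$fitted$k, prob = TRUE, use.all = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    SVM = model$orientation * svm_decision_values(model, xs)
  )
  unname(s)
}

#' Hard 0/1 stage labels from a frozen model
#'
#' Label 1 (AD) iff `score >= threshold`; the threshold is 0.5 for
#' probability learners and 0 for margin learners. A score exactly at the
#' threshold is labeled 1.
#'
#' @inheritParams score_model
#' @return integer vector of 0/1 labels.
#' @export
predict_model <- function(model, features) {
  as.integer(score_model(model, features) >= model$threshold)
}

#' @export
predict.frozen_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (type == "score") score_model(object, newdata) else predict_model(object, newdata)
}

#' @export
print.frozen_model <- function(x, ...) {
  cat("<frozen_model> ", x$spec$name, " x ", x$experiment %||% "?",
      " (", length(x$feature_names), " features, threshold ",
      x$threshold, ")\n", sep = "")
  invisible(x)
}

MODEL_ARTIFACT_VERSION <- "1"

#' Save / load a frozen model artifact
#'
#' Serializes a `frozen_model` to a versioned RDS artifact so that the
#' external-validation stage can run in a separate invocation from
#' training.
#'
#' @param model a `frozen_model`.
#' @param path artifact path.
#' @return `save_model()` the path invisibly; `load_model()` the
#'   `frozen_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "frozen_model"))
  saveRDS(list(artifact = "xmittn_frozen_model",
               version = MODEL_ARTIFACT_VERSION, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$artifact, "xmittn_frozen_model")) {
    stop("not a frozen-model artifact: ", path)
  }
  if (!identical(obj$version, MODEL_ARTIFACT_VERSION)) {
    stop("unsupported artifact version ", obj$version)
  }
  obj$model
}

#' Hand-built model for closed-form pipeline checks
#'
#' Wraps an arbitrary scoring function in the `frozen_model` contract so
#' that pipeline stages can be checked against models with known behaviour
#' (e.g. an oracle that scores by a single feature, or a constant scorer).
#' Intended for diagnostics and tests, not for data analysis.
#'
#' @param score_fun function taking the (unstandardized) feature matrix and
#'   returning one score per row.
#' @param feature_names feature names the model expects.
#' @param experiment experiment tag (`"EXP1"`/`"EXP2"`).
#' @param threshold decision threshold (default 0.5).
#' @return a `frozen_model` whose scores come from `score_fun`.
#' @export
manual_model <- function(score_fun, feature_names = EXP1_FEATURES,
                         experiment = "EXP1", threshold = 0.5) {
  stopifnot(is.function(score_fun))
  structure(
    list(spec = structure(list(name = "MANUAL", hyperparameters = list(),
                               seed = 0L), class = "algorithm_spec"),
         fitted = score_fun, feature_names = feature_names,
         experiment = experiment, standardization = NULL,
         threshold = threshold, orientation = 1),
    class = "frozen_model"
  )
}
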