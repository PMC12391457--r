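#' The classifier registry
#'
#' Six classical classifiers: a random forest, two gradient-boosted tree
#' ensembles (depth-wise boosting, and a leaf-wise histogram GBDT), logistic
#' regression, an RBF-kernel support-vector classifier, and k-nearest
#' neighbours. Hyperparameters are library defaults with seeds pinned.
#'
#' @return Character vector of model identifiers.
#' @export
model_registry <- function() {
  c("random_forest", "xgboost", "hist_gbdt", "logistic", "svm_rbf", "knn")
}

#' Construct a model specification
#'
#' @param model_id One of [model_registry()].
#' @param hyperparameters Named list of overrides for the fitting call.
#' @param seed Integer seed pinned into the fit.
#' @return A `motorfair_model_spec`.
#' @export
model_spec <- function(model_id, hyperparameters = list(), seed = 1L) {
  if (!model_id %in% model_registry())
    stop("unknown model_id: ", model_id, call. = FALSE)
  structure(list(model_id = model_id, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "motorfair_model_spec")
}

## numeric design matrix: every numeric column except identifiers/label
design_matrix <- function(data, label_col = "label") {
  drop <- c("participant_id", label_col, ".resampled")
  cols <- setdiff(names(data), drop)
  cols <- cols[vapply(data[cols], is.numeric, logical(1))]
  as.matrix(data[, cols, drop = FALSE])
}

fit_classifier <- function(spec, x, y_pos) {
  hp <- spec$hyperparameters
  with_seed(spec$seed, switch(spec$model_id,
    random_forest = randomForest::randomForest(
      x = x, y = factor(y_pos, levels = c(FALSE, TRUE)),
      ntree = hp$ntree %||% 500),
    xgboost = xgboost::xgboost(
      x, factor(y_pos, levels = c(FALSE, TRUE)),
      nrounds = hp$nrounds %||% 100, max_depth = hp$max_depth %||% 6,
      learning_rate = hp$learning_rate %||% 0.3,
      nthreads = 1, verbosity = 0, seed = spec$seed),
    hist_gbdt = xgboost::xgboost(
      x, factor(y_pos, levels = c(FALSE, TRUE)),
      nrounds = hp$nrounds %||% 100, tree_method = "hist",
      grow_policy = "lossguide", max_leaves = hp$max_leaves %||% 31,
      max_depth = 0, learning_rate = hp$learning_rate %||% 0.1,
      nthreads = 1, verbosity = 0, seed = spec$seed),
    logistic = suppressWarnings(stats::glm.fit(
      cbind(1, x), as.numeric(y_pos),
      family = stats::binomial())$coefficients),
    svm_rbf = e1071::svm(x = x, y = factor(y_pos, levels = c(FALSE, TRUE)),
                         probability = TRUE, kernel = "radial"),
    knn = list(x = x, y = y_pos, k = hp$k %||% 5)
  ))
}

predict_scores <- function(spec, fit, x) {
  switch(spec$model_id,
    random_forest = unname(stats::predict(fit, x, type = "prob")[, "TRUE"]),
    xgboost = ,
    hist_gbdt = as.numeric(stats::predict(fit, x)),
    logistic = {
      beta <- ifelse(is.na(fit), 0, fit)
      as.numeric(stats::plogis(cbind(1, x) %*% beta))
    },
    svm_rbf = {
      pr <- attr(stats::predict(fit, x, probability = TRUE), "probabilities")
      unname(pr[, "TRUE"])
    },
    knn = {
      pred <- class::knn(fit$x, x, factor(fit$y, levels = c(FALSE, TRUE)),
                         k = fit$k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "TRUE", p, 1 - p)
    }
  )
}

#' Area under the ROC curve by the rank (pair-counting) formulation
#'
#' Equals the probability that a uniformly random positive receives a
#' higher score than a uniformly random negative, with ties counted 1/2.
#'
#' @param scores Numeric scores.
#' @param labels Labels; `positive` names the positive class.
#' @param positive Positive-class value.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels, positive = "PD") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

f1_from_predictions <- function(labels, predicted, positive = "PD") {
  tp <- sum(labels == positive & predicted == positive)
  fp <- sum(labels != positive & predicted == positive)
  fn <- sum(labels == positive & predicted != positive)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(derive_seed(seed, "folds"), {
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Cross-validate a set of model specifications
#'
#' Stratified k-fold cross-validation with folds shared across models
#' (paired comparison); records per-fold F1 and AUROC and their mean and
#' standard deviation across folds.
#'
#' @param train Training feature `data.frame` with a label column.
#' @param specs List of [model_spec()] objects.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @param label_col,positive Label column and positive class.
#' @param threshold Score threshold for the F1 computation.
#' @return A list of per-model results, each with `model_id`, `folds`
#'   (per-fold `f1`/`auroc`), `mean_f1`, `sd_f1`, `mean_auroc`, `sd_auroc`.
#' @export
cross_validate <- function(train, specs, n_folds = 5L, seed = 1L,
                           label_col = "label", positive = "PD",
                           threshold = 0.5) {
  lab <- train[[label_col]]
  fold <- stratified_folds(lab, n_folds, seed)
  if (any(tabulate(fold, n_folds) == 0) ||
      any(vapply(seq_len(n_folds), function(f)
        length(unique(lab[fold != f])) < 2, logical(1))))
    stop("degenerate fold: a training fold lost a class", call. = FALSE)
  x <- design_matrix(train, label_col)
  y_pos <- lab == positive
  lapply(specs, function(spec) {
    f1 <- numeric(n_folds); auc <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- fit_classifier(spec, x[tr, , drop = FALSE], y_pos[tr])
      sc <- predict_scores(spec, fit, x[!tr, , drop = FALSE])
      pred <- ifelse(sc >= threshold, positive, "other")
      truth <- ifelse(y_pos[!tr], positive, "other")
      f1[f] <- f1_from_predictions(truth, pred, positive)
      auc[f] <- auroc(sc, truth, positive)
    }
    list(model_id = spec$model_id, spec = spec,
         folds = data.frame(fold = seq_len(n_folds), f1 = f1, auroc = auc),
         mean_f1 = mean(f1), sd_f1 = stats::sd(f1),
         mean_auroc = mean(auc), sd_auroc = stats::sd(auc))
  })
}

#' Select the top models from cross-validation results
#'
#' Ranks by mean F1, breaking ties by mean AUROC and then by model id
#' (lexicographic).
#'
#' @param results List from [cross_validate()].
#' @param k How many specs to return (default 3).
#' @return List of the winning `motorfair_model_spec`s, best first.
#' @export
select_top <- function(results, k = 3L) {
  if (!length(results)) stop("results is empty", call. = FALSE)
  if (k > length(results))
    stop("k = ", k, " exceeds the ", length(results), " models evaluated",
         call. = FALSE)
  ids <- vapply(results, `[[`, character(1), "model_id")
  f1 <- vapply(results, `[[`, numeric(1), "mean_f1")
  auc <- vapply(results, `[[`, numeric(1), "mean_auroc")
  ord <- order(-f1, -auc, ids)
  lapply(results[ord[seq_len(k)]], `[[`, "spec")
}

## builds the standard prediction table, carrying group attributes from the
## cohort file (never from the model inputs)
prediction_table <- function(ids, labels, scores, threshold, cohort,
                             positive = "PD") {
  predicted <- ifelse(scores >= threshold, positive, "non-PD")
  m <- match(ids, cohort$id)
  if (anyNA(m))
    stop("prediction rows missing from cohort: ",
         paste(utils::head(ids[is.na(m)]), collapse = ", "), call. = FALSE)
  data.frame(participant_id = ids, label = labels, score = scores,
             predicted = predicted,
             sex = cohort$sex[m], race_binary = cohort$race_binary[m],
             device = cohort$device[m], hand = cohort$hand[m],
             stringsAsFactors = FALSE)
}

#' Fit on the training partition and score the held-out test partition
#'
#' @param spec A [model_spec()].
#' @param train,test Feature data frames with matching schemas.
#' @param cohort Cohort `data.frame` supplying group attributes.
#' @param threshold Decision threshold on the calibrated score.
#' @param label_col,positive Label column and positive class.
#' @return A prediction table: one row per test participant with
#'   `participant_id`, `label`, `score`, `predicted`, `sex`,
#'   `race_binary`, `device`, `hand`.
#' @export
fit_predict <- function(spec, train, test, cohort, threshold = 0.5,
                        label_col = "label", positive = "PD") {
  mism <- union(setdiff(names(train), names(test)),
                setdiff(names(test), names(train)))
  mism <- setdiff(mism, ".resampled")
  if (length(mism))
    stop("train/test schema mismatch in columns: ",
         paste(mism, collapse = ", "), call. = FALSE)
  if (length(unique(train[[label_col]])) < 2)
    stop("training data contain a single class", call. = FALSE)
  xtr <- design_matrix(train, label_col)
  xte <- design_matrix(test, label_col)
  xte <- xte[, colnames(xtr), drop = FALSE]
  fit <- fit_classifier(spec, xtr, train[[label_col]] == positive)
  sc <- predict_scores(spec, fit, xte)
  prediction_table(test$participant_id, test[[label_col]], sc, threshold,
                   cohort, positive)
}

#' Out-of-fold cross-validated prediction table for a whole feature matrix
#'
#' Every participant is scored by a model that never saw their row,
#' using the same stratified folding as [cross_validate()]; useful when
#' group subsets of a 30% held-out partition would be too small to audit.
#'
#' @inheritParams cross_validate
#' @param features Full feature `data.frame`.
#' @param spec A [model_spec()].
#' @param cohort Cohort `data.frame` supplying group attributes.
#' @return A prediction table covering every row of `features`.
#' @export
cv_predict <- function(features, spec, cohort, n_folds = 5L, seed = 1L,
                       threshold = 0.5, label_col = "label",
                       positive = "PD") {
  lab <- features[[label_col]]
  fold <- stratified_folds(lab, n_folds, seed)
  x <- design_matrix(features, label_col)
  y_pos <- lab == positive
  sc <- numeric(nrow(features))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit <- fit_classifier(spec, x[tr, , drop = FALSE], y_pos[tr])
    sc[!tr] <- predict_scores(spec, fit, x[!tr, , drop = FALSE])
  }
  prediction_table(features$participant_id, lab, sc, threshold, cohort,
                   positive)
}

#' Write or read a prediction table CSV
#'
#' @param preds Prediction table `data.frame`.
#' @param path File path.
#' @return `read_predictions()` returns the `data.frame`.
#' @export
write_predictions <- function(preds, path) {
  utils::write.csv(preds, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "label", "score", "predicted",
            "sex", "race_binary", "device", "hand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("prediction file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}
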