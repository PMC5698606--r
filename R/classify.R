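#' Train the random-forest voting ensemble
#'
#' Fits a bootstrap-trained decision-tree ensemble (random forest) on a
#' feature table. Each tree is grown on a bootstrap resample with random
#' feature subsetting at every split (`mtry = sqrt(d)` by default);
#' prediction is by majority vote over the trees, evaluated explicitly in
#' [predict.nucleus_rf()]. Fits are deterministic given `seed`.
#'
#' @param table Data frame with a factor column `label` (levels
#'   `normal`, `HCC`) and numeric feature columns.
#' @param n_trees Number of trees, default 500.
#' @param mtry Features tried per split; `NULL` for the sqrt default.
#' @param seed Integer seed.
#' @return A `nucleus_rf` object wrapping the fitted forest.
#' @export
train_classifier <- function(table, n_trees = 500, mtry = NULL, seed = 1) {
  table <- check_feature_table(table)
  if (nlevels(droplevels(table$label)) < 2L)
    stop("training data contains a single class")
  fit <- ranger::ranger(
    formula = label ~ ., data = table,
    num.trees = n_trees, mtry = mtry,
    seed = seed, num.threads = 1L)
  structure(list(forest = fit, levels = levels(table$label),
                 positive = "HCC", n_trees = n_trees),
            class = "nucleus_rf")
}

check_feature_table <- function(table) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  table$label <- factor(as.character(table$label),
                        levels = c("normal", "HCC"))
  feats <- table[setdiff(names(table), "label")]
  if (!all(vapply(feats, is.numeric, logical(1))))
    stop("all feature columns must be numeric")
  if (any(!vapply(feats, function(x) all(is.finite(x)), logical(1))))
    stop("feature table contains missing or non-finite values")
  table
}

#' Predict with the voting ensemble
#'
#' Collects every tree's class vote and aggregates by majority,
#' `H(x) = argmax_Y sum_i I(h_i(x) = Y)`. Exact ties (possible with an
#' even tree count) go to the first class level (`normal`), a documented
#' deterministic rule.
#'
#' @param object A `nucleus_rf`.
#' @param data Data frame of features (a `label` column is ignored).
#' @param type `"class"` for the voted labels, `"votes"` for the
#'   per-class vote counts, `"trees"` for the full per-tree vote matrix.
#' @param ... Unused.
#' @return Factor of predictions, or a matrix for `"votes"`/`"trees"`.
#' @export
predict.nucleus_rf <- function(object, data,
                               type = c("class", "votes", "trees"), ...) {
  type <- match.arg(type)
  data <- data[setdiff(names(data), "label")]
  pr <- predict(object$forest, data = data, predict.all = TRUE,
                num.threads = 1L)$predictions
  # per-tree codes are forest class.values; map them to level indices
  fr <- object$forest$forest
  codes <- matrix(match(fr$levels[match(pr, fr$class.values)],
                        object$levels), nrow = nrow(pr))
  if (type == "trees") {
    out <- matrix(object$levels[codes], nrow = nrow(pr))
    return(out)
  }
  votes <- t(apply(codes, 1L, tabulate, nbins = length(object$levels)))
  colnames(votes) <- object$levels
  if (type == "votes") return(votes)
  factor(object$levels[max.col(votes, ties.method = "first")],
         levels = object$levels)
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity and specificity from a binary confusion matrix
#' with HCC as the positive class: `ACC = (TP+TN)/(TP+FN+TN+FP)`,
#' `SEN = TP/(TP+FN)` (HCC recall), `SPE = TN/(TN+FP)` (normal recall).
#' A zero denominator yields `NA` for that rate and sets the
#' `undefined` flag rather than silently reporting 0.
#'
#' @param predictions,labels Equal-length vectors of class labels.
#' @param positive Positive class, default `"HCC"`.
#' @return An `eval_metrics` list: `TP`, `FN`, `TN`, `FP`, `ACC`, `SEN`,
#'   `SPE`, `undefined`.
#' @export
evaluate_predictions <- function(predictions, labels, positive = "HCC") {
  if (length(predictions) == 0L) stop("empty predictions")
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  p <- as.character(predictions); y <- as.character(labels)
  tp <- sum(p == positive & y == positive)
  fn <- sum(p != positive & y == positive)
  tn <- sum(p != positive & y != positive)
  fp <- sum(p == positive & y != positive)
  rate <- function(num, den) if (den > 0L) num / den else NA_real_
  out <- list(TP = tp, FN = fn, TN = tn, FP = fp,
              ACC = (tp + tn) / (tp + fn + tn + fp),
              SEN = rate(tp, tp + fn),
              SPE = rate(tn, tn + fp))
  out$undefined <- is.na(out$SEN) || is.na(out$SPE)
  structure(out, class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  TN %d  FP %d\nACC %.4f  SEN %.4f  SPE %.4f%s\n",
              x$TP, x$FN, x$TN, x$FP, x$ACC, x$SEN, x$SPE,
              if (x$undefined) "  (some rates undefined)" else ""))
  invisible(x)
}

# seeded stratified fold assignment; returns integer vector of fold ids
stratified_folds <- function(labels, folds, seed) {
  if (folds < 2L) stop("folds must be >= 2")
  if (length(labels) < folds) stop("fewer samples than folds")
  assign_ <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(as.character(labels))) {
      idx <- which(as.character(labels) == cl)
      assign_[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assign_
}

#' Stratified k-fold cross-validation
#'
#' Seeded stratified fold assignment, per-fold training and evaluation of
#' the voting ensemble, and aggregation of ACC/SEN/SPE across folds (and
#' repeats).
#'
#' @param table Feature table with `label` column.
#' @param folds Number of folds, default 10.
#' @param repeats Independent repetitions with reshuffled folds,
#'   default 1.
#' @param n_trees,mtry Passed to [train_classifier()].
#' @param seed Integer seed controlling folds and forests.
#' @return List with `summary` (data frame of mean and sd for ACC, SEN,
#'   SPE), `folds` (per-fold metrics), and `assignments` (fold ids of the
#'   first repeat).
#' @export
cross_validate <- function(table, folds = 10, repeats = 1,
                           n_trees = 500, mtry = NULL, seed = 1) {
  table <- check_feature_table(table)
  rows <- list(); assignments <- NULL
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(table$label, folds, seed + 1000L * (r - 1L))
    if (r == 1L) assignments <- fold_id
    for (f in seq_len(folds)) {
      train <- table[fold_id != f, , drop = FALSE]
      test <- table[fold_id == f, , drop = FALSE]
      fit <- train_classifier(train, n_trees = n_trees, mtry = mtry,
                              seed = seed + 7919L * f + r)
      m <- evaluate_predictions(predict(fit, test), test$label)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f, ACC = m$ACC, SEN = m$SEN, SPE = m$SPE)
    }
  }
  per_fold <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("ACC", "SEN", "SPE"),
    mean = c(mean(per_fold$ACC), mean(per_fold$SEN, na.rm = TRUE),
             mean(per_fold$SPE, na.rm = TRUE)),
    sd = c(sd(per_fold$ACC), sd(per_fold$SEN, na.rm = TRUE),
           sd(per_fold$SPE, na.rm = TRUE)))
  list(summary = summ, folds = per_fold, assignments = assignments)
}

cv_mean_acc <- function(cv) cv$summary$mean[cv$summary$metric == "ACC"]

#' Balanced train/test split bookkeeping
#'
#' Draws a seeded stratified split with exact per-class counts, the
#' design used for the 9720-patch benchmark (2600 training and 2260
#' testing patches per class).
#'
#' @param labels Class labels.
#' @param n_train_per_class,n_test_per_class Exact per-class counts.
#' @param seed Integer seed.
#' @return List of integer index vectors `train` and `test` (disjoint).
#' @export
make_split <- function(labels, n_train_per_class = 2600,
                       n_test_per_class = 2260, seed = 1) {
  labels <- as.character(labels)
  need <- n_train_per_class + n_test_per_class
  with_seed(seed, {
    parts <- lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) < need)
        stop("class ", cl, " has ", length(idx),
             " samples; need ", need)
      pick <- sample(idx, need)
      list(train = pick[seq_len(n_train_per_class)],
           test = pick[n_train_per_class + seq_len(n_test_per_class)])
    })
    list(train = sort(unlist(lapply(parts, `[[`, "train"))),
         test = sort(unlist(lapply(parts, `[[`, "test"))))
  })
}
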