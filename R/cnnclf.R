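#' Confusion counts for binary case/control classification
#'
#' `TP` counts cases correctly identified as cases, `FP` controls wrongly
#' called cases, `TN` controls correctly identified, `FN` cases missed.
#'
#' @param TP,FP,TN,FN Nonnegative integer counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  v <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(v < 0) || any(v != floor(v)))
    stopf("confusion counts must be nonnegative integers")
  structure(as.list(stats::setNames(as.integer(v), names(v))),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

# Tally predictions against truth (positive class = "case").
confusion_from_predictions <- function(predicted, truth) {
  p <- label_to_binary(predicted)
  y <- label_to_binary(truth)
  stopifnot(length(p) == length(y))
  confusion_counts(TP = sum(p == 1 & y == 1), FP = sum(p == 1 & y == 0),
                   TN = sum(p == 0 & y == 0), FN = sum(p == 0 & y == 1))
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts A [confusion_counts()] object.
#' @return Accuracy in `[0, 1]`.
#' @examples
#' accuracy(confusion_counts(TP = 3, FP = 1, TN = 4, FN = 2))  # 0.7
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stopf("accuracy is undefined: all confusion counts are zero")
  (counts$TP + counts$TN) / total
}

# Stratified fold assignment: within each class, subjects are shuffled
# (seeded) and dealt round-robin into k folds.
stratified_folds <- function(labels, k, seed) {
  y <- label_to_binary(labels)
  n <- length(y)
  if (min(table(y)) < k)
    stopf("need at least %d subjects per class for %d-fold stratified CV", k, k)
  fold <- integer(n)
  with_seed(derive_seed(seed, 31L), {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validated classification
#'
#' For each of the `k` folds: the fold is held out as the test set, one of
#' the remaining folds (rotating) becomes the validation set, and the rest
#' train the model. The per-fold confusion counts and accuracies are
#' collected into a report whose `mean_accuracy` is the arithmetic mean of
#' the fold accuracies.
#'
#' When connectivity must be fitted on training subjects only (the tangent
#' method), pass the raw per-subject inputs as `x` together with a
#' `stack_fn(train_idx, x)` that returns the list of stacks for *all*
#' subjects using only the training subjects to fit group-level models.
#' Otherwise `x` is simply the list of precomputed [stack3d()] objects.
#'
#' @param x List of [stack3d()] objects, or arbitrary per-subject inputs
#'   consumed by `stack_fn`.
#' @param labels Factor (case/control) or 0/1 vector aligned with `x`.
#' @param backbone Backbone passed to [train_transfer()].
#' @param k Number of folds.
#' @param seed Seed controlling fold assignment and training randomness.
#' @param schedule A [training_schedule()].
#' @param stack_fn Optional `function(train_idx, x)` -> list of stacks.
#' @param classifier Optional override `function(train, val)` returning a
#'   prediction `function(test)` -> case/control labels, where train/val/
#'   test are lists with `stacks`, `labels`, `idx`. Used for stub
#'   classifiers in tests; defaults to the transfer-learning workflow.
#' @return Object of class `cv_report`: `k`, `per_fold` (confusion counts,
#'   accuracy, test indices per fold), `mean_accuracy`, `seed`,
#'   `fingerprint`.
#' @export
cross_validate <- function(x, labels, backbone = backbone_spec("TinyConv"),
                           k = 10L, seed = 1L,
                           schedule = training_schedule(seed = seed),
                           stack_fn = NULL, classifier = NULL) {
  n <- length(x)
  stopifnot(length(labels) == n)
  if (n < k) stopf("fewer subjects (%d) than folds (%d)", n, k)
  fold <- stratified_folds(labels, k, seed)

  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    if (k >= 3L) {
      # rotate one of the remaining folds into the validation role
      val_fold <- (f %% k) + 1L
      val_idx <- which(fold == val_fold)
      train_idx <- which(fold != f & fold != val_fold)
    } else {
      # k = 2: no fold left over, monitor on the training subjects
      val_idx <- train_idx <- which(fold != f)
    }

    stacks <- if (is.null(stack_fn)) x else stack_fn(train_idx, x)
    train <- list(stacks = stacks[train_idx], labels = labels[train_idx],
                  idx = train_idx)
    val <- list(stacks = stacks[val_idx], labels = labels[val_idx],
                idx = val_idx)
    test <- list(stacks = stacks[test_idx], labels = labels[test_idx],
                 idx = test_idx)

    predicted <- if (is.null(classifier)) {
      sched <- schedule
      sched$seed <- derive_seed(seed, 100L + f)
      fit <- train_transfer(train, val, backbone, sched)
      predict(fit, test$stacks, type = "label")
    } else {
      classifier(train, val)(test)
    }
    cc <- confusion_from_predictions(predicted, test$labels)
    per_fold[[f]] <- list(fold = f, confusion = cc, accuracy = accuracy(cc),
                          test_idx = test_idx)
  }
  accs <- vapply(per_fold, `[[`, 0, "accuracy")
  structure(list(k = as.integer(k), per_fold = per_fold,
                 mean_accuracy = mean(accs), seed = as.integer(seed),
                 fingerprint = fingerprint(list(k = k, seed = seed,
                                                schedule = schedule,
                                                fold = fold))),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  accs <- vapply(x$per_fold, `[[`, 0, "accuracy")
  cat(sprintf("<cv_report> %d folds, mean accuracy %.4f (folds: %s), seed %d\n",
              x$k, x$mean_accuracy, paste(sprintf("%.2f", accs), collapse = " "),
              x$seed))
  invisible(x)
}

#' Export a cross-validation report
#'
#' Writes the report as JSON (`<path>.json`-style) and, optionally, the
#' per-fold accuracies as CSV.
#'
#' @param report A [cross_validate()] report.
#' @param json_path Output JSON path.
#' @param csv_path Optional CSV path for the fold table.
#' @return `json_path`, invisibly.
#' @export
write_cv_report <- function(report, json_path, csv_path = NULL) {
  stopifnot(inherits(report, "cv_report"))
  folds <- lapply(report$per_fold, function(pf)
    list(fold = pf$fold, TP = pf$confusion$TP, FP = pf$confusion$FP,
         TN = pf$confusion$TN, FN = pf$confusion$FN, accuracy = pf$accuracy))
  jsonlite::write_json(
    list(k = report$k, mean_accuracy = report$mean_accuracy,
         seed = report$seed, fingerprint = report$fingerprint, folds = folds),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    df <- do.call(rbind, lapply(folds, as.data.frame))
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
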