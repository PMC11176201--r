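#' Stratified fold assignment
#'
#' Shuffles each class with the seeded RNG, then deals its members
#' round-robin over the k folds, so fold class counts differ by at most 1
#' within each class.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold indices in `1..k`.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  tab <- table(labels)
  if (any(tab < k))
    stop("class smaller than k: ", paste(names(tab)[tab < k], collapse = ", "))
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Train the fold classifier
#'
#' Default model: per-feature z-scaling (statistics from the training rows
#' only, SD floored at 1e-12 so constant features get zero weight) followed
#' by a linear maximum-margin classifier (linear-kernel support vector
#' machine, unit cost). `"logistic"` (unpenalized logistic regression) is
#' available as an alternative family.
#'
#' @param x numeric training matrix (cases x features).
#' @param y labels (`"negative"`/`"positive"`), both classes present.
#' @param model `"svm_linear"` (default) or `"logistic"`.
#' @param cost SVM cost parameter.
#' @return An object of class `wall_classifier` with a `predict` method
#'   returning oriented decision scores (positive score favours the
#'   positive class; the class rule thresholds at 0).
#' @export
train_classifier <- function(x, y, model = c("svm_linear", "logistic"),
                             cost = 1) {
  model <- match.arg(model)
  x <- as.matrix(x)
  y <- factor(y, levels = c("negative", "positive"))
  if (nlevels(droplevels(y)) < 2) stop("need both classes in training data")
  mu <- colMeans(x)
  sg <- pmax(apply(x, 2, sd), 1e-12)
  xs <- scale(x, mu, sg)
  if (model == "svm_linear") {
    fit <- e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE)
    # libsvm decision values are signed towards the first training label;
    # read the orientation off the reported level order
    dv <- attr(predict(fit, xs, decision.values = TRUE), "decision.values")
    sign_pos <- if (grepl("^positive/", colnames(dv)[1])) 1 else -1
    obj <- list(model = model, fit = fit, sign = sign_pos)
  } else {
    df <- data.frame(y = as.integer(y == "positive"), xs)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    obj <- list(model = model, fit = fit, sign = 1)
  }
  structure(c(obj, list(mu = mu, sg = sg, features = colnames(x))),
            class = "wall_classifier")
}

#' @export
predict.wall_classifier <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), object$mu, object$sg)
  if (object$model == "svm_linear") {
    dv <- attr(predict(object$fit, xs, decision.values = TRUE),
               "decision.values")
    as.numeric(dv[, 1]) * object$sign
  } else {
    df <- as.data.frame(xs)
    as.numeric(predict(object$fit, df, type = "link"))
  }
}

#' Classification metrics from scores
#'
#' Sensitivity is computed on the positive (IPSS >= 8) class, specificity
#' on the negative class; balanced accuracy is their mean. AUC is the
#' trapezoidal area under the score-swept ROC curve, which with midrank tie
#' handling equals the pair-counting (Mann-Whitney) statistic.
#'
#' @param truth labels (`"negative"`/`"positive"`), both classes present.
#' @param scores numeric decision scores, larger favouring positive.
#' @param threshold class decision threshold on the scores (default 0).
#' @return Named list: `accuracy`, `balanced_accuracy`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
compute_metrics <- function(truth, scores, threshold = 0) {
  pos <- truth == "positive"
  if (!any(pos) || all(pos)) stop("need both classes in truth")
  pred_pos <- scores > threshold
  tp <- sum(pred_pos & pos); fn <- sum(!pred_pos & pos)
  tn <- sum(!pred_pos & !pos); fp <- sum(pred_pos & !pos)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(accuracy = (tp + tn) / length(truth),
       balanced_accuracy = (sens + spec) / 2,
       sensitivity = sens, specificity = spec,
       auc = roc_auc(truth, scores)$auc)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the unique score values as thresholds (each distinct score is one
#' ROC vertex, so tied scores move diagonally — the midrank convention) and
#' integrates by the trapezoidal rule.
#'
#' @inheritParams compute_metrics
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(truth, scores) {
  pos <- truth == "positive"
  np <- sum(pos); nn <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))              # tie groups share a vertex
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / np); fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc = data.frame(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Repeated stratified K-fold evaluation of a feature subset
#'
#' For each repeat a fresh seeded stratified fold assignment is drawn; each
#' fold's model is trained on the remaining folds and scored on the held
#' out fold. Metrics are computed per repeat from the pooled validation
#' scores (stabler for AUC with few positives than per-fold averaging) and
#' averaged over repeats.
#'
#' @param table [feature_table()] or numeric matrix.
#' @param labels class labels.
#' @param subset character vector of feature column names (default: all).
#' @param k folds per repeat. @param repeats number of repeats.
#' @param seed master seed; repeat r uses fold seed `seed + r - 1`.
#' @param model classifier family, see [train_classifier()].
#' @return An `evaluation_report`: list with `mean` and `sd` metric lists,
#'   `per_repeat` data frame, pooled `roc` points of the first repeat,
#'   and the fold scheme.
#' @export
repeated_cv <- function(table, labels, subset = NULL, k = 5L, repeats = 100L,
                        seed = 1L, model = "svm_linear") {
  x <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  if (!is.null(subset)) {
    if (!length(subset)) stop("empty feature subset")
    miss <- setdiff(subset, colnames(x))
    if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
    x <- x[, subset, drop = FALSE]
  }
  per <- vector("list", repeats)
  roc1 <- NULL
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(labels, k, seed + r - 1L)
    scores <- numeric(length(labels))
    for (f in seq_len(k)) {
      tr <- fold != f
      clf <- train_classifier(x[tr, , drop = FALSE], labels[tr], model = model)
      scores[!tr] <- predict(clf, x[!tr, , drop = FALSE])
    }
    m <- compute_metrics(labels, scores)
    if (r == 1L) roc1 <- roc_auc(labels, scores)$roc
    per[[r]] <- as.data.frame(m)
  }
  per <- do.call(rbind, per)
  structure(list(mean = as.list(colMeans(per)),
                 sd = as.list(apply(per, 2, sd)),
                 per_repeat = per, roc = roc1,
                 scheme = list(k = k, repeats = repeats, seed = seed,
                               model = model),
                 subset = subset %||% colnames(x)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report> %d-fold x %d repeats | acc %.3f",
                     " bal %.3f sens %.3f spec %.3f auc %.3f\n"),
              x$scheme$k, x$scheme$repeats, x$mean$accuracy,
              x$mean$balanced_accuracy, x$mean$sensitivity,
              x$mean$specificity, x$mean$auc))
  invisible(x)
}

#' Majority-class naive baseline
#'
#' The reference point for any classifier on imbalanced labels: predicting
#' the majority class for everyone gives accuracy equal to the majority
#' fraction and balanced accuracy 0.5. The naive classifier is
#' threshold-free, so its AUC is reported as 0.5 with a degenerate flag.
#'
#' @param labels class labels.
#' @return Named list of metrics plus `majority` and `degenerate_auc`.
#' @export
naive_baseline <- function(labels) {
  stopifnot(length(labels) > 0)
  tab <- table(labels)
  maj <- names(tab)[which.max(tab)]
  acc <- max(tab) / length(labels)
  if (length(tab) == 1L)
    return(list(accuracy = 1, balanced_accuracy = NA_real_,
                sensitivity = NA_real_, specificity = NA_real_,
                auc = 0.5, majority = maj, degenerate_auc = TRUE,
                degenerate_labels = TRUE))
  sens <- if (maj == "positive") 1 else 0
  list(accuracy = acc, balanced_accuracy = 0.5,
       sensitivity = sens, specificity = 1 - sens,
       auc = 0.5, majority = maj, degenerate_auc = TRUE)
}

#' Compare feature subsets under identical fold seeds
#'
#' Evaluates each named subset with [repeated_cv()] using the same seed, so
#' every subset sees identical fold assignments (paired comparison).
#'
#' @param table [feature_table()] or matrix. @param labels class labels.
#' @param subsets named list of character vectors of feature names.
#' @param k,repeats,seed,model passed to [repeated_cv()].
#' @return Data frame, one row per subset: metric means, SDs and sizes.
#' @export
subset_comparison <- function(table, labels, subsets, k = 5L, repeats = 100L,
                              seed = 1L, model = "svm_linear") {
  stopifnot(length(subsets) >= 1, !is.null(names(subsets)))
  rows <- lapply(names(subsets), function(nm) {
    rep <- repeated_cv(table, labels, subsets[[nm]], k = k, repeats = repeats,
                       seed = seed, model = model)
    data.frame(subset = nm, n_features = length(subsets[[nm]]),
               accuracy = rep$mean$accuracy,
               balanced_accuracy = rep$mean$balanced_accuracy,
               sensitivity = rep$mean$sensitivity,
               specificity = rep$mean$specificity,
               auc = rep$mean$auc,
               accuracy_sd = rep$sd$accuracy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize an evaluation report
#' @param report an `evaluation_report`. @param path JSON path.
#' @param roc_path optional CSV path for the ROC points.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path, roc_path = NULL) {
  jsonlite::write_json(list(mean = report$mean, sd = report$sd,
                            scheme = report$scheme, subset = report$subset,
                            per_repeat = report$per_repeat),
                       path, auto_unbox = TRUE, digits = NA)
  if (!is.null(roc_path))
    write.csv(report$roc, roc_path, row.names = FALSE)
  invisible(path)
}
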