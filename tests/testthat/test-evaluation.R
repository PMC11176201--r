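test_that("stratified folds balance classes and are seed-deterministic", {
  labels <- rep(c("negative", "positive"), c(50, 37))
  fold <- stratified_folds(labels, 5, seed = 71)
  for (f in 1:5) {
    expect_equal(sum(fold == f & labels == "negative"), 10)
    expect_true(sum(fold == f & labels == "positive") %in% 7:8)
  }
  expect_identical(fold, stratified_folds(labels, 5, seed = 71))
  expect_false(identical(fold, stratified_folds(labels, 5, seed = 72)))

  # leave-one-out degenerate case: singleton folds within each class
  lab2 <- rep(c("negative", "positive"), each = 4)
  f8 <- stratified_folds(lab2, 4, seed = 1)
  expect_equal(sort(unique(f8)), 1:4)
  expect_true(all(table(f8) == 2))
  expect_error(stratified_folds(lab2, 5), "smaller than k")
})

test_that("the classifier separates separable data and orients its scores", {
  set.seed(72)
  n <- 40
  labels <- rep(c("negative", "positive"), each = n / 2)
  x <- cbind(a = rnorm(n) + ifelse(labels == "positive", 4, -4),
             b = rnorm(n))
  clf <- train_classifier(x, labels)
  sc <- predict(clf, x)
  expect_true(all(sc[labels == "positive"] > 0))
  expect_true(all(sc[labels == "negative"] < 0))
  # logistic alternative agrees on the separable toy's predicted classes
  clfl <- train_classifier(x, labels, model = "logistic")
  expect_true(all((predict(clfl, x) > 0) == (labels == "positive")))
  expect_error(train_classifier(x, rep("negative", n)), "both classes")

  # duplicated feature column: same predicted classes as single column
  x1 <- x[, "a", drop = FALSE]
  x2 <- cbind(a = x[, "a"], a2 = x[, "a"])
  p1 <- predict(train_classifier(x1, labels), x1) > 0
  p2 <- predict(train_classifier(x2, labels), x2) > 0
  expect_identical(p1, p2)
})

test_that("metrics match the worked examples and the pair-counting oracle", {
  truth <- c("negative", "negative", "positive", "positive")
  m <- compute_metrics(truth, c(0.1, 0.4, 0.35, 0.8), threshold = 0.375)
  expect_equal(m$auc, 0.75)

  perfect <- compute_metrics(truth, c(-2, -1, 1, 2))
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$accuracy, 1.0)
  expect_equal(perfect$balanced_accuracy, 1.0)

  ties <- compute_metrics(truth, rep(0.5, 4))
  expect_equal(ties$auc, 0.5)

  expect_error(compute_metrics(rep("positive", 4), 1:4), "both classes")

  set.seed(73)
  for (rep in 1:100) {
    n <- sample(6:20, 1)
    truth <- sample(c("negative", "positive"), n, TRUE)
    if (length(unique(truth)) < 2) next
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    expect_equal(roc_auc(truth, scores)$auc, auc_pair_oracle(truth, scores),
                 tolerance = 1e-10)
  }
})

test_that("balanced accuracy is exactly the mean of sensitivity and specificity", {
  set.seed(74)
  labels <- rep(c("negative", "positive"), c(14, 10))
  x <- matrix(rnorm(24 * 3), 24, 3)
  x[, 1] <- x[, 1] + ifelse(labels == "positive", 1.5, 0)
  colnames(x) <- c("s", "n1", "n2")
  rep_ <- repeated_cv(x, labels, k = 4, repeats = 6, seed = 75)
  per <- rep_$per_repeat
  expect_equal(per$balanced_accuracy,
               (per$sensitivity + per$specificity) / 2, tolerance = 1e-12)
  expect_true(all(unlist(per) >= 0 & unlist(per) <= 1))
})

test_that("repeated CV is prefix-deterministic in the seed stream", {
  set.seed(76)
  labels <- rep(c("negative", "positive"), c(12, 10))
  x <- matrix(rnorm(22 * 2), 22, 2)
  colnames(x) <- c("a", "b")
  r1 <- repeated_cv(x, labels, k = 3, repeats = 1, seed = 77)
  r5 <- repeated_cv(x, labels, k = 3, repeats = 5, seed = 77)
  expect_equal(unlist(r5$per_repeat[1, ]), unlist(r1$per_repeat[1, ]))
  r5b <- repeated_cv(x, labels, k = 3, repeats = 5, seed = 77)
  expect_identical(r5$per_repeat, r5b$per_repeat)
})

test_that("feature scaling never leaks validation information", {
  set.seed(78)
  n <- 40
  labels <- rep(c("negative", "positive"), each = n / 2)
  noise <- matrix(rnorm(n * 2), n, 2); colnames(noise) <- c("a", "b")

  # canary 1: a feature equal to the label leaks perfect accuracy
  leak <- cbind(noise, lab = ifelse(labels == "positive", 1, 0))
  r_leak <- repeated_cv(leak, labels, k = 4, repeats = 3, seed = 79)
  expect_equal(r_leak$mean$accuracy, 1.0)

  # canary 2: a feature equal to the label only on one fold's validation
  # rows must not score above chance levels
  fold <- stratified_folds(labels, 2, seed = 80)
  canary <- ifelse(fold == 2, ifelse(labels == "positive", 1, 0),
                   rnorm(n))
  x2 <- cbind(noise, canary = canary)
  scores <- numeric(n)
  for (f in 1:2) {
    clf <- train_classifier(x2[fold != f, ], labels[fold != f])
    scores[fold == f] <- predict(clf, x2[fold == f, ])
  }
  acc <- mean((scores > 0) == (labels == "positive"))
  expect_lt(acc, 0.8)
})

test_that("naive baseline reproduces the majority-class arithmetic", {
  labels <- rep(c("negative", "positive"), c(50, 37))
  nb <- naive_baseline(labels)
  expect_equal(nb$accuracy, 50 / 87)
  expect_equal(round(nb$accuracy, 2), 0.57)
  expect_equal(nb$balanced_accuracy, 0.5)
  expect_equal(nb$majority, "negative")
  expect_equal(nb$sensitivity, 0)
  expect_equal(nb$specificity, 1)
  expect_true(nb$degenerate_auc)
  expect_equal(nb$auc, 0.5)

  one <- naive_baseline(rep("positive", 5))
  expect_equal(one$accuracy, 1.0)
  expect_true(is.na(one$balanced_accuracy))
})

test_that("subset comparison is paired and rejects bad subsets", {
  set.seed(81)
  labels <- rep(c("negative", "positive"), c(12, 10))
  x <- matrix(rnorm(22 * 4), 22, 4)
  x[, 1] <- x[, 1] + ifelse(labels == "positive", 2, 0)
  colnames(x) <- c("s", "a", "b", "c")
  cmp <- subset_comparison(x, labels,
                           list(one = "s", again = "s", noise = c("a", "b")),
                           k = 3, repeats = 4, seed = 82)
  expect_equal(cmp$accuracy[1], cmp$accuracy[2])  # identical subset rows
  expect_equal(cmp$auc[1], cmp$auc[2])
  expect_error(subset_comparison(x, labels, list(bad = "zzz"), repeats = 2),
               "unknown feature")
  expect_error(subset_comparison(x, labels, list(empty = character(0)),
                                 repeats = 2), "empty")
})
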