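sel_table <- function(x, cats = NULL) {
  p <- ncol(x)
  desc <- data.frame(name = colnames(x) %||% paste0("f", seq_len(p)),
                     category = cats %||% rep("texture", p),
                     feature = NA, angle = NA, distance = NA,
                     bins = NA, window = NA)
  colnames(x) <- desc$name
  feature_table(x, desc, paste0("c", seq_len(nrow(x))))
}

test_that("redundancy pruning drops the worse-ranked of correlated pairs", {
  set.seed(61)
  x <- matrix(rnorm(50 * 6), 50, 6)
  x[, 4] <- x[, 1] + rnorm(50, sd = 1e-6)   # near-duplicate of f1
  colnames(x) <- paste0("f", 1:6)
  r <- correlation_matrix(x)
  kept <- redundancy_prune(paste0("f", 1:6), r, 0.9)
  expect_false("f4" %in% kept)
  expect_true(all(c("f1", "f2", "f3", "f5", "f6") %in% kept))

  # rho = 1 drops nothing (|r| > 1 impossible)
  expect_equal(redundancy_prune(paste0("f", 1:6), r, 1.0), paste0("f", 1:6))

  # greedy oracle replay on a known correlation block
  set.seed(62)
  z <- matrix(rnorm(80 * 10), 80, 10)
  z[, 2] <- z[, 1] * 0.99 + rnorm(80, sd = 0.05)
  z[, 7] <- -z[, 3] + rnorm(80, sd = 0.01)
  colnames(z) <- paste0("g", 1:10)
  rz <- correlation_matrix(z)
  ranked <- paste0("g", 1:10)
  oracle <- character(0)
  for (f in ranked)
    if (!length(oracle) || all(abs(rz[f, oracle]) <= 0.9))
      oracle <- c(oracle, f)
  expect_equal(redundancy_prune(ranked, rz, 0.9), oracle)
})

test_that("a perfectly separating feature is selected first with objective 1", {
  set.seed(63)
  n <- 30
  labels <- rep(c("negative", "positive"), each = n / 2)
  x <- matrix(rnorm(n * 8), n, 8)
  x[, 5] <- ifelse(labels == "positive", 10, -10) + rnorm(n, sd = 0.1)
  colnames(x) <- paste0("f", 1:8)
  cfg <- selection_config(filter_pool_size = 8, max_subset_size = 3,
                          repeats = 3, seed = 64)
  res <- obm_search(sel_table(x), labels, cfg)
  expect_equal(res$selected[1], "f5")
  expect_equal(res$objective, 1.0)
  expect_true(res$converged)
  # determinism: identical inputs give identical results
  res2 <- obm_search(sel_table(x), labels, cfg)
  expect_identical(res$selected, res2$selected)
  expect_identical(res$trace, res2$trace)
  # trace never decreases at accepted moves
  expect_true(all(diff(res$trace) >= 0))
  expect_error(obm_search(sel_table(x), rep("positive", n), cfg),
               "single class")
})

test_that("baseline selectors return k names with the expected rankings", {
  set.seed(65)
  n <- 40
  labels <- rep(c("negative", "positive"), each = n / 2)
  x <- matrix(rnorm(n * 15), n, 15)
  x[, 3] <- x[, 3] + ifelse(labels == "positive", 2, 0)
  x[, 9] <- x[, 9] + ifelse(labels == "positive", 1, 0)
  colnames(x) <- paste0("f", 1:15)
  tab <- sel_table(x)

  for (m in c("mrmr", "chi2", "anova", "kruskal")) {
    sel <- baseline_select(tab, labels, m, 10)
    expect_length(sel, 10)
    expect_true(!anyDuplicated(sel))
    expect_true(all(sel %in% colnames(x)))
  }
  expect_error(baseline_select(tab, labels, "pca", 10), "arg")

  # ANOVA ranking equals squared-t ranking for two classes
  an <- baseline_select(tab, labels, "anova", 15)
  tstat <- apply(x, 2, function(col)
    t.test(col[labels == "positive"], col[labels == "negative"],
           var.equal = TRUE)$statistic^2)
  expect_equal(an, names(sort(tstat, decreasing = TRUE)))
  expect_equal(an[1], "f3")

  # Kruskal-Wallis is invariant under rank-preserving transforms
  xr <- x; xr[, ] <- exp(x)   # monotone transform
  colnames(xr) <- colnames(x)
  expect_equal(baseline_select(sel_table(xr), labels, "kruskal", 10),
               baseline_select(tab, labels, "kruskal", 10))
})

test_that("selection results serialize to JSON", {
  set.seed(66)
  n <- 20
  labels <- rep(c("negative", "positive"), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5)
  x[, 2] <- ifelse(labels == "positive", 5, -5)
  colnames(x) <- paste0("f", 1:5)
  res <- obm_search(sel_table(x), labels,
                    selection_config(filter_pool_size = 5,
                                     max_subset_size = 2, repeats = 2,
                                     seed = 67))
  f <- tempfile(fileext = ".json")
  write_selection_result(res, f)
  got <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(got$selected, res$selected)
  expect_equal(got$objective, res$objective)
})
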