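#' Configuration of the hybrid biomarker search
#'
#' Parameters of the optimal-biomarker-style selection: a filter stage
#' keeps the `filter_pool_size` lowest-p features, redundancy control drops
#' features correlated above `redundancy_threshold` with a better-ranked
#' keeper, and a wrapper search over subsets is scored by repeated
#' stratified cross-validation of the downstream classifier.
#'
#' @param filter_pool_size features kept by the univariate filter.
#' @param redundancy_threshold absolute Pearson correlation above which the
#'   worse-ranked member of a pair is pruned (`0 < rho <= 1`).
#' @param max_subset_size largest subset the wrapper may grow to.
#' @param folds,repeats inner CV scheme scoring each candidate subset
#'   (fewer repeats than final evaluation, for tractability).
#' @param convergence_patience full sweeps without an accepted move before
#'   the search stops.
#' @param objective `"accuracy"` or `"balanced_accuracy"`.
#' @param model classifier family, see [train_classifier()].
#' @param seed seed for the inner CV splits (the search is deterministic).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(filter_pool_size = 200L,
                             redundancy_threshold = 0.9,
                             max_subset_size = 10L,
                             folds = 5L, repeats = 10L,
                             convergence_patience = 2L,
                             objective = c("accuracy", "balanced_accuracy"),
                             model = "svm_linear",
                             seed = 1L) {
  objective <- match.arg(objective)
  stopifnot(filter_pool_size >= max_subset_size, max_subset_size >= 1,
            redundancy_threshold > 0, redundancy_threshold <= 1,
            folds >= 2, repeats >= 1, convergence_patience >= 1)
  structure(list(filter_pool_size = filter_pool_size,
                 redundancy_threshold = redundancy_threshold,
                 max_subset_size = max_subset_size,
                 folds = folds, repeats = repeats,
                 convergence_patience = convergence_patience,
                 objective = objective, model = model, seed = seed),
            class = "selection_config")
}

#' Redundancy pruning of a ranked feature pool
#'
#' Scans features in rank order (best first) and drops any feature whose
#' absolute correlation with an already-kept feature exceeds `rho`. The
#' result is deterministic in the ranking.
#'
#' @param ranked character vector of feature names, best first.
#' @param corr correlation matrix covering at least these features.
#' @param rho threshold on `|r|` (a kept pair never exceeds it).
#' @return Character vector of surviving names, in rank order.
#' @export
redundancy_prune <- function(ranked, corr, rho = 0.9) {
  kept <- character(0)
  for (f in ranked) {
    if (!length(kept) || all(abs(corr[f, kept]) <= rho))
      kept <- c(kept, f)
  }
  kept
}

# Inner wrapper objective: mean repeated-CV metric of a subset, cached.
make_subset_scorer <- function(x, labels, cfg) {
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  score <- function(subset) {
    key <- paste(sort(subset), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    rep <- repeated_cv(x, labels, subset, k = cfg$folds,
                       repeats = cfg$repeats, seed = cfg$seed,
                       model = cfg$model)
    val <- rep$mean[[cfg$objective]]
    cache[[key]] <- val
    n_eval <<- n_eval + 1L
    val
  }
  list(score = score, evaluated = function() n_eval)
}

#' Optimal-biomarker wrapper search
#'
#' Hybrid selection in three legs. Filter: rank features by
#' [univariate_pvalues()] and keep the lowest-p pool. Redundancy: prune the
#' pool with [redundancy_prune()]. Wrapper with embedded refinement: greedy
#' forward selection with swap moves — each sweep tries adding every pool
#' feature and, once the subset has two members, replacing each member with
#' every pool feature; the single best move is accepted if it improves the
#' repeated-CV objective by more than 1e-6. The search stops after
#' `convergence_patience` sweeps without an accepted move, or at
#' `max_subset_size`. All CV splits derive from the config seed, so
#' identical inputs give identical results.
#'
#' @param table a [feature_table()] or numeric matrix.
#' @param labels class labels (both classes present).
#' @param cfg a [selection_config()].
#' @return A `selection_result`: list with `selected` (names, in inclusion
#'   order), `objective` (final score), `trace` (accepted-move scores,
#'   non-decreasing), `converged`, `n_evaluated`, `pool`.
#' @export
obm_search <- function(table, labels, cfg = selection_config()) {
  x <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  if (length(unique(labels)) < 2) stop("degenerate labels: single class")
  uv <- univariate_pvalues(table, labels)
  ranked <- head(uv$name[!is.na(uv$p_value)], cfg$filter_pool_size)
  corr <- correlation_matrix(x[, ranked, drop = FALSE])
  pool <- redundancy_prune(ranked, corr, cfg$redundancy_threshold)

  scorer <- make_subset_scorer(x, labels, cfg)
  selected <- character(0)
  best <- -Inf
  trace <- numeric(0)
  stale <- 0L
  converged <- FALSE
  eps <- 1e-6
  repeat {
    cand_best <- NULL; cand_score <- best
    # add moves
    if (length(selected) < cfg$max_subset_size) {
      for (f in setdiff(pool, selected)) {
        s <- scorer$score(c(selected, f))
        if (s > cand_score + eps) { cand_score <- s; cand_best <- c(selected, f) }
      }
    }
    # swap moves (embedded refinement: the classifier drives replacement)
    if (length(selected) >= 2) {
      for (i in seq_along(selected)) {
        for (f in setdiff(pool, selected)) {
          cand <- selected; cand[i] <- f
          s <- scorer$score(cand)
          if (s > cand_score + eps) { cand_score <- s; cand_best <- cand }
        }
      }
    }
    if (is.null(cand_best)) {
      # a sweep without an accepted move; the search is deterministic, so
      # further sweeps cannot differ — patience counts them anyway per the
      # stopping contract
      stale <- stale + 1L
      if (stale >= cfg$convergence_patience) { converged <- TRUE; break }
    } else {
      stale <- 0L
      selected <- cand_best
      best <- cand_score
      trace <- c(trace, best)
      if (best >= 1) { converged <- TRUE; break }  # perfect objective
    }
  }
  structure(list(selected = selected, objective = best, trace = trace,
                 converged = converged, n_evaluated = scorer$evaluated(),
                 pool = pool, config = cfg),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d feature(s), objective %.3f, %s after %d evaluations\n",
              length(x$selected), x$objective,
              if (x$converged) "converged" else "stopped", x$n_evaluated))
  cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a selection result as JSON
#' @param result a `selection_result`. @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_result <- function(result, path) {
  jsonlite::write_json(list(selected = result$selected,
                            objective = result$objective,
                            trace = result$trace,
                            converged = result$converged,
                            n_evaluated = result$n_evaluated,
                            pool_size = length(result$pool)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Literature baseline feature selectors
#'
#' Top-k ranking by four standard criteria. `anova`: one-way F statistic
#' (identical ranking to squared t with two classes). `kruskal`:
#' Kruskal-Wallis rank statistic. `chi2`: the chi-square statistic on
#' nonnegative feature mass per class (columns are shifted by their minimum
#' to be nonnegative first). `mrmr`: greedy minimum-redundancy
#' maximum-relevance — repeatedly add the feature maximizing F-statistic
#' relevance minus mean absolute Pearson correlation with the already
#' selected set.
#'
#' @param table a [feature_table()] or numeric matrix.
#' @param labels class labels.
#' @param method one of `"mrmr"`, `"chi2"`, `"anova"`, `"kruskal"`.
#' @param k number of features to return.
#' @return Character vector of `k` feature names.
#' @export
baseline_select <- function(table, labels,
                            method = c("mrmr", "chi2", "anova", "kruskal"),
                            k = 10L) {
  method <- match.arg(method)
  x <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  stopifnot(k >= 1, k <= ncol(x))
  pos <- labels == "positive"
  fstat <- function(xx) {
    n1 <- sum(!pos); n2 <- sum(pos); n <- n1 + n2
    m1 <- colMeans(xx[!pos, , drop = FALSE]); m2 <- colMeans(xx[pos, , drop = FALSE])
    gm <- colMeans(xx)
    ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
    ssw <- colSums((t(t(xx[!pos, , drop = FALSE]) - m1))^2) +
      colSums((t(t(xx[pos, , drop = FALSE]) - m2))^2)
    ifelse(ssw > 0, (ssb / 1) / (ssw / (n - 2)), ifelse(ssb > 0, Inf, 0))
  }
  stat <- switch(method,
    anova = fstat(x),
    kruskal = apply(x, 2, function(col)
      suppressWarnings(stats::kruskal.test(col, factor(pos))$statistic)),
    chi2 = {
      xm <- sweep(x, 2, apply(x, 2, min))  # shift columns nonnegative
      obs <- rbind(colSums(xm[!pos, , drop = FALSE]),
                   colSums(xm[pos, , drop = FALSE]))
      tot <- colSums(obs)
      exp_ <- rbind(tot * mean(!pos), tot * mean(pos))
      ifelse(tot > 0, colSums((obs - exp_)^2 / pmax(exp_, 1e-300)), 0)
    },
    mrmr = NULL)
  if (method != "mrmr") {
    names(stat) <- colnames(x)
    return(names(sort(stat, decreasing = TRUE))[seq_len(k)])
  }
  rel <- fstat(x); names(rel) <- colnames(x)
  rel[!is.finite(rel)] <- max(rel[is.finite(rel)], 1) * 2
  sel <- names(which.max(rel))
  cr <- correlation_matrix(x)
  while (length(sel) < k) {
    rest <- setdiff(colnames(x), sel)
    red <- rowMeans(abs(cr[rest, sel, drop = FALSE]))
    gain <- rel[rest] - red
    sel <- c(sel, rest[which.max(gain)])
  }
  sel
}
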