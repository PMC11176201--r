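#' Per-feature class discrimination statistics
#'
#' Welch's unequal-variance two-sample t-test of the class mean difference,
#' one test per feature, vectorized over columns. Features are ranked by
#' ascending p-value with ties broken by descending absolute standardized
#' mean difference, then by name. These p-values are a ranking device for
#' the filter stage, not corrected inference; Benjamini-Hochberg q-values
#' are reported alongside for information. Degenerate features (zero
#' variance in both groups) get a sentinel p of `NA` and rank last, except
#' that a zero mean difference is reported as p = 1.
#'
#' @param table a [feature_table()] or numeric matrix.
#' @param labels character/factor vector, `"negative"`/`"positive"`.
#' @param method `"welch"` (default) or `"wilcoxon"` (Mann-Whitney).
#' @return A data frame (one row per feature, ranked): `name`, `category`,
#'   `mean_negative`, `mean_positive`, `sd_negative`, `sd_positive`,
#'   `p_value`, `q_value`, `smd`.
#' @export
univariate_pvalues <- function(table, labels, method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  x <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  desc <- if (inherits(table, "feature_table")) table$descriptors else
    plain_descriptors(colnames(x) %||% paste0("f", seq_len(ncol(x))), NA)
  pos <- labels == "positive"
  if (sum(pos) < 2 || sum(!pos) < 2)
    stop("need at least 2 cases per class")
  xn <- x[!pos, , drop = FALSE]; xp <- x[pos, , drop = FALSE]
  n1 <- nrow(xn); n2 <- nrow(xp)
  m1 <- colMeans(xn); m2 <- colMeans(xp)
  v1 <- apply(xn, 2, var); v2 <- apply(xp, 2, var)
  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    t <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(t), df)
  } else {
    p <- apply(x, 2, function(col)
      suppressWarnings(stats::wilcox.test(col[pos], col[!pos])$p.value))
  }
  degen <- v1 == 0 & v2 == 0
  p[degen & m1 == m2] <- 1
  p[degen & m1 != m2] <- NA  # infinite separation; flagged, ranked last
  sp <- sqrt((v1 + v2) / 2)
  smd <- ifelse(sp > 0, (m2 - m1) / sp, ifelse(m1 == m2, 0, Inf))
  res <- data.frame(name = desc$name, category = desc$category,
                    mean_negative = m1, mean_positive = m2,
                    sd_negative = sqrt(v1), sd_positive = sqrt(v2),
                    p_value = p,
                    q_value = stats::p.adjust(p, "BH"),
                    smd = smd, stringsAsFactors = FALSE,
                    row.names = NULL)
  ord <- order(is.na(res$p_value), res$p_value, -abs(res$smd), res$name)
  res[ord, , drop = FALSE]
}

#' Top discriminating features within a category
#'
#' @param result ranked data frame from [univariate_pvalues()].
#' @param category one of the feature families, or `NULL` for all.
#' @param k number of features to keep; if the category holds fewer, all
#'   are returned (with a message).
#' @return The `k` lowest-p rows of the category, in rank order.
#' @export
top_k_by_category <- function(result, category = NULL, k = 10L) {
  stopifnot(k >= 1)
  sub <- if (is.null(category)) result else
    result[result$category == category, , drop = FALSE]
  if (nrow(sub) < k)
    message(sprintf("category has only %d features (requested %d)",
                    nrow(sub), k))
  head(sub, k)
}

#' Feature correlation matrix
#'
#' Pearson correlation between feature columns. Zero-variance columns get 0
#' off-diagonal (flagged via the `degenerate` attribute) and 1 on the
#' diagonal so the matrix stays well-formed.
#'
#' @param table a [feature_table()] or numeric matrix (>= 3 cases).
#' @return Symmetric correlation matrix with unit diagonal and attribute
#'   `degenerate` (logical per column).
#' @export
correlation_matrix <- function(table) {
  x <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  stopifnot(nrow(x) >= 3)
  sds <- apply(x, 2, sd)
  degen <- sds == 0
  r <- suppressWarnings(cor(x))
  r[degen, ] <- 0; r[, degen] <- 0
  diag(r) <- 1
  r <- (r + t(r)) / 2
  structure(r, degenerate = degen)
}

#' Export a correlation heat map
#'
#' @param r correlation matrix from [correlation_matrix()].
#' @param path PNG output path.
#' @param max_features subsample evenly to at most this many columns so
#'   very wide tables stay readable.
#' @return `path`, invisibly.
#' @export
correlation_heatmap <- function(r, path, max_features = 200L) {
  idx <- if (ncol(r) > max_features)
    unique(round(seq(1, ncol(r), length.out = max_features))) else seq_len(ncol(r))
  rr <- r[idx, idx, drop = FALSE]
  grDevices::png(path, width = 900, height = 900)
  on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(c("red", "white", "blue"))(101)
  graphics::image(seq_len(ncol(rr)), seq_len(ncol(rr)), t(rr[rev(seq_len(nrow(rr))), ]),
                  zlim = c(-1, 1), col = pal, xlab = "feature", ylab = "feature",
                  main = "feature correlation", useRaster = TRUE)
  invisible(path)
}
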