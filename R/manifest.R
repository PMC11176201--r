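#' Dichotomize an IPSS score
#'
#' The International Prostate Symptom Score (0-35) is split at 8: scores of
#' 0-7 (mild symptoms) form the negative class, scores of 8-35 (moderate to
#' severe) the positive class.
#'
#' @param ipss integer vector of scores in `[0, 35]`.
#' @return Character vector, `"negative"` or `"positive"`.
#' @examples
#' ipss_to_label(c(0, 7, 8, 35))
#' @export
ipss_to_label <- function(ipss) {
  if (any(!is.finite(ipss)) || any(ipss < 0 | ipss > 35))
    stop("IPSS must be in [0, 35]")
  ifelse(ipss >= 8, "positive", "negative")
}

#' Load a cohort manifest
#'
#' Reads a CSV with columns `case_id`, `image`, `mask`, `age`, `bmi`,
#' `prostate_size`, `ipss`. Rows with any missing clinical variable,
#' non-positive clinical values, or IPSS outside `[0, 35]` are excluded
#' (case exclusion, not imputation), and a log line reports the counts.
#' Binary labels are derived with [ipss_to_label()]. Relative `image`/`mask`
#' paths are resolved against the manifest's directory.
#'
#' @param path path to the manifest CSV.
#' @param quiet suppress the kept/dropped log line.
#' @return A data frame of surviving case records with a `label` column,
#'   plus attribute `n_dropped`.
#' @export
load_manifest <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("case_id", "image", "mask", "age", "bmi", "prostate_size", "ipss")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest missing columns: ", paste(miss, collapse = ", "))
  clin <- c("age", "bmi", "prostate_size")
  for (cc in clin) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  df$ipss <- suppressWarnings(as.integer(df$ipss))
  bad_clin <- Reduce(`|`, lapply(df[clin], function(x) !is.finite(x) | x <= 0))
  bad_ipss <- !is.finite(df$ipss) | df$ipss < 0 | df$ipss > 35
  drop <- bad_clin | bad_ipss
  if (!quiet) {
    for (i in which(drop))
      message(sprintf("excluding case %s: %s", df$case_id[i],
                      if (bad_ipss[i]) "IPSS missing or out of range"
                      else "missing or invalid clinical variable"))
    message(sprintf("manifest %s: kept %d cases, dropped %d",
                    basename(path), sum(!drop), sum(drop)))
  }
  df <- df[!drop, , drop = FALSE]
  if (nrow(df) == 0L) stop("no cases survive manifest quality control")
  root <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(root, p))
  df$image <- fix(df$image)
  df$mask <- fix(df$mask)
  df$label <- ipss_to_label(df$ipss)
  rownames(df) <- NULL
  structure(df, n_dropped = sum(drop))
}
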