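#' Construct a cases-by-features table with descriptors
#'
#' The central tabular container of the pipeline: a numeric matrix of cases
#' (rows) by features (columns), and one descriptor per column recording its
#' family (`morphological`, `intensity`, `texture`, `clinical`) and, for
#' texture features, the co-occurrence parameters that generated it
#' (haralick feature, angle, distance, bins, window).
#'
#' @param values numeric matrix, cases x features.
#' @param descriptors data frame with columns `name`, `category` and the
#'   texture parameter columns `feature`, `angle`, `distance`, `bins`,
#'   `window` (NA for non-texture features).
#' @param case_ids character row labels, one per case.
#' @param check require all entries finite (default `TRUE`; assembly turns
#'   sentinels into imputed values before this holds).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, descriptors, case_ids, check = TRUE) {
  values <- as.matrix(values)
  if (nrow(descriptors) != ncol(values))
    stop("descriptor count ", nrow(descriptors),
         " does not match column count ", ncol(values))
  if (anyDuplicated(descriptors$name))
    stop("descriptor names are not unique")
  if (length(case_ids) != nrow(values))
    stop("case_ids length does not match row count")
  if (check && !all(is.finite(values)))
    stop("feature table contains non-finite entries")
  for (cc in c("angle", "distance", "bins", "window"))
    if (is.null(descriptors[[cc]])) descriptors[[cc]] <- NA_integer_
  if (is.null(descriptors$feature)) descriptors$feature <- NA_character_
  colnames(values) <- descriptors$name
  rownames(values) <- case_ids
  structure(list(values = values,
                 descriptors = descriptors[, c("name", "category", "feature",
                                               "angle", "distance", "bins",
                                               "window")],
                 case_ids = as.character(case_ids)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d cases x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$descriptors$category)),
                            table(x$descriptors$category)), collapse = ", ")))
  invisible(x)
}

#' Write a feature table as annotated TSV
#'
#' The file starts with a commented metadata block (`#d` lines, one per
#' descriptor) followed by a plain TSV body whose first column is
#' `case_id`. Numeric values are written with 15 significant digits so a
#' round-trip is lossless well beyond 12 digits.
#'
#' @param table a [feature_table()].
#' @param path output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (!all(is.finite(table$values)))
    stop("refusing to write a feature table with non-finite entries")
  d <- table$descriptors
  hdr <- c("#wallradiomics_feature_table\tv1",
           paste0("#d\t", d$name, "\t", d$category, "\t",
                  ifelse(is.na(d$feature), ".", d$feature), "\t",
                  ifelse(is.na(d$angle), ".", d$angle), "\t",
                  ifelse(is.na(d$distance), ".", d$distance), "\t",
                  ifelse(is.na(d$bins), ".", d$bins), "\t",
                  ifelse(is.na(d$window), ".", d$window)))
  writeLines(hdr, path)
  body <- data.table::data.table(case_id = table$case_ids)
  body <- cbind(body, data.table::as.data.table(table$values))
  data.table::fwrite(body, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path path to the annotated TSV.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  dl <- hdr[startsWith(hdr, "#d\t")]
  if (!length(dl)) stop("no descriptor block in ", path)
  parts <- do.call(rbind, strsplit(dl, "\t", fixed = TRUE))
  tonum <- function(x) suppressWarnings(as.integer(ifelse(x == ".", NA, x)))
  desc <- data.frame(name = parts[, 2], category = parts[, 3],
                     feature = ifelse(parts[, 4] == ".", NA, parts[, 4]),
                     angle = tonum(parts[, 5]), distance = tonum(parts[, 6]),
                     bins = tonum(parts[, 7]), window = tonum(parts[, 8]),
                     stringsAsFactors = FALSE)
  body <- data.table::fread(path, sep = "\t", skip = length(hdr),
                            header = TRUE, data.table = FALSE)
  if (!identical(setdiff(names(body), "case_id"), desc$name))
    stop("descriptor block does not match table columns in ", path)
  vals <- as.matrix(body[, -1, drop = FALSE])
  feature_table(vals, desc, body$case_id)
}
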