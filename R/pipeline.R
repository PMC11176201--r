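#' Default pipeline configuration
#'
#' One nested list drives every stage; each stage consumes only its own
#' section plus the global seed. The same structure can be stored as YAML
#' and loaded with [read_pipeline_config()]. Stage seeds are derived from
#' the global seed by a stable hash of the stage name so stages can be
#' re-run independently yet reproducibly.
#'
#' @param seed global seed.
#' @param out_dir output directory for all artifacts.
#' @return Nested list of class `pipeline_config` with sections
#'   `synthetic`, `standardization`, `texture`, `selection`, `evaluation`.
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = "wallrad_out") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    synthetic = list(n_negative = 50L, n_positive = 37L,
                     texture_effect = 1.2, intensity_effect = 0,
                     morphology_effect = 0),
    standardization = list(s_min = 0, s_max = 4095, pc_low = 1, pc_high = 99),
    texture = list(angles = c(0, 45, 90, 135), distances = c(1, 2, 4),
                   bins = c(8, 16), windows = c(5, 9)),
    selection = list(filter_pool_size = 200L, redundancy_threshold = 0.9,
                     max_subset_size = 10L, folds = 5L, repeats = 10L,
                     objective = "accuracy"),
    evaluation = list(folds = 5L, repeats = 100L, model = "svm_linear")),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param seed,out_dir optional overrides applied last.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, seed = NULL, out_dir = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    merge2 <- function(base, over) {
      for (nm in names(over))
        base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
          merge2(base[[nm]], over[[nm]]) else over[[nm]]
      base
    }
    cfg <- merge2(cfg, user)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  class(cfg) <- "pipeline_config"
  cfg
}

# Stage seed: stable hash of the stage name folded into the global seed,
# kept inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

pipeline_paths <- function(cfg) {
  o <- cfg$out_dir
  list(cohort = file.path(o, "cohort"),
       manifest = file.path(o, "cohort", "manifest.csv"),
       standardizer = file.path(o, "standardizer.json"),
       features = file.path(o, "features.tsv"),
       univariate = file.path(o, "univariate"),
       selection = file.path(o, "selection.json"),
       evaluation = file.path(o, "evaluation.json"),
       roc = file.path(o, "roc.csv"),
       comparison = file.path(o, "subset_comparison.tsv"))
}

run_log <- function(cfg, stage, inputs, outputs) {
  rec <- list(stage = stage, seed = cfg$seed,
              stage_seed = stage_seed(cfg$seed, stage),
              inputs = inputs, outputs = outputs,
              config_hash = substr(digest_config(cfg), 1, 12),
              time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  path <- file.path(cfg$out_dir, "run_log.json")
  old <- if (file.exists(path)) jsonlite::read_json(path) else list()
  jsonlite::write_json(c(old, list(rec)), path, auto_unbox = TRUE)
  invisible(rec)
}

digest_config <- function(cfg) {
  # deterministic fingerprint without extra dependencies
  s <- paste(deparse(cfg[setdiff(names(cfg), "out_dir")]), collapse = "")
  paste(sprintf("%02x", utf8ToInt(substr(s, 1, 1))),
        sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max),
        sep = "")
}

#' Run one pipeline stage (or the whole chain)
#'
#' Orchestrates the analysis behind a single entry point with subcommands:
#' `simulate` (phantom cohort), `standardize` (train + apply the intensity
#' standardizer), `extract` (feature table), `univariate` (per-category
#' ranked tables, correlation matrix and heat map), `select` (biomarker
#' search), `evaluate` (repeated-CV report, ROC points, subset
#' comparison), `run-all` (everything in order). Each stage writes its
#' artifacts under the config's output directory and appends a record
#' (inputs, seed, config hash) to `run_log.json`.
#'
#' @param name subcommand name.
#' @param config a `pipeline_config` (see [default_pipeline_config()]).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list of the stage's main artifact paths.
#' @export
run_subcommand <- function(name = c("simulate", "standardize", "extract",
                                    "univariate", "select", "evaluate",
                                    "run-all"),
                           config = default_pipeline_config(),
                           quiet = FALSE) {
  name <- match.arg(name)
  cfg <- config
  p <- pipeline_paths(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  if (name == "run-all") {
    for (st in c("simulate", "standardize", "extract", "univariate",
                 "select", "evaluate"))
      run_subcommand(st, cfg, quiet = quiet)
    return(invisible(p))
  }

  if (name == "simulate") {
    sc <- do.call(synthetic_config,
                  c(cfg$synthetic, list(seed = stage_seed(cfg$seed, "simulate"))))
    generate_cohort(sc, p$cohort)
    say("simulate: wrote %s", p$manifest)
    run_log(cfg, name, list(), list(manifest = p$manifest))
    return(invisible(p))
  }

  if (!file.exists(p$manifest))
    stop("missing cohort manifest ", p$manifest, "; run `simulate` first")
  manifest <- load_manifest(p$manifest, quiet = quiet)

  if (name == "standardize") {
    sc <- do.call(standardization_config, cfg$standardization)
    imgs <- lapply(manifest$image, read_volume)
    msks <- Map(read_mask, manifest$mask, imgs)
    model <- train_standardizer(imgs, msks, sc)
    write_standardizer(model, p$standardizer)
    for (i in seq_len(nrow(manifest))) {
      std <- apply_standardizer(model, imgs[[i]], msks[[i]])
      write_volume(std, sub("\\.nii(\\.gz)?$", "_std.nii", manifest$image[i]))
    }
    say("standardize: model %s (n=%d)", p$standardizer, model$n_train)
    run_log(cfg, name, list(manifest = p$manifest),
            list(model = p$standardizer))
    return(invisible(p))
  }

  if (name == "extract") {
    tc <- do.call(texture_config, cfg$texture)
    std <- if (file.exists(p$standardizer)) read_standardizer(p$standardizer)
           else NULL
    tab <- extract_features(manifest, tc, standardizer = std, quiet = quiet)
    write_feature_table(tab, p$features)
    say("extract: %d cases x %d features -> %s", nrow(tab$values),
        ncol(tab$values), p$features)
    run_log(cfg, name, list(manifest = p$manifest),
            list(features = p$features))
    return(invisible(p))
  }

  if (!file.exists(p$features))
    stop("missing feature table ", p$features, "; run `extract` first")
  tab <- read_feature_table(p$features)
  labels <- manifest$label[match(tab$case_ids, manifest$case_id)]

  if (name == "univariate") {
    dir.create(p$univariate, showWarnings = FALSE)
    uv <- univariate_pvalues(tab, labels)
    for (cat in unique(uv$category)) {
      top <- if (quiet) suppressMessages(top_k_by_category(uv, cat, 10L))
             else top_k_by_category(uv, cat, 10L)
      write.table(top, file.path(p$univariate, paste0("top10_", cat, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    r <- correlation_matrix(tab)
    utils::write.table(round(r, 6), file.path(p$univariate, "correlation.tsv"),
                       sep = "\t", quote = FALSE)
    correlation_heatmap(r, file.path(p$univariate, "correlation.png"))
    say("univariate: ranked tables in %s", p$univariate)
    run_log(cfg, name, list(features = p$features),
            list(dir = p$univariate))
    return(invisible(p))
  }

  if (name == "select") {
    sc <- do.call(selection_config,
                  c(cfg$selection, list(seed = stage_seed(cfg$seed, "select"))))
    res <- obm_search(tab, labels, sc)
    write_selection_result(res, p$selection)
    say("select: %d feature(s), objective %.3f", length(res$selected),
        res$objective)
    run_log(cfg, name, list(features = p$features),
            list(selection = p$selection))
    return(invisible(p))
  }

  # evaluate
  if (!file.exists(p$selection))
    stop("missing selection result ", p$selection, "; run `select` first")
  sel <- jsonlite::read_json(p$selection, simplifyVector = TRUE)
  ev <- cfg$evaluation
  eseed <- stage_seed(cfg$seed, "evaluate")
  report <- repeated_cv(tab, labels, sel$selected, k = ev$folds,
                        repeats = ev$repeats, seed = eseed, model = ev$model)
  write_evaluation_report(report, p$evaluation, p$roc)
  clin <- tab$descriptors$name[tab$descriptors$category == "clinical"]
  subsets <- list(optimal = sel$selected,
                  age_only = "clin_age", bmi_only = "clin_bmi",
                  prostate_only = "clin_prostate_size",
                  all_clinical = clin)
  cmp <- subset_comparison(tab, labels, subsets, k = ev$folds,
                           repeats = max(10L, ev$repeats %/% 5L),
                           seed = eseed, model = ev$model)
  nb <- naive_baseline(labels)
  cmp <- rbind(cmp, data.frame(subset = "naive_majority", n_features = 0L,
                               accuracy = nb$accuracy,
                               balanced_accuracy = nb$balanced_accuracy,
                               sensitivity = nb$sensitivity,
                               specificity = nb$specificity,
                               auc = nb$auc, accuracy_sd = 0))
  write.table(cmp, p$comparison, sep = "\t", row.names = FALSE, quote = FALSE)
  say("evaluate: acc %.3f auc %.3f -> %s", report$mean$accuracy,
      report$mean$auc, p$evaluation)
  run_log(cfg, name, list(features = p$features, selection = p$selection),
          list(evaluation = p$evaluation, roc = p$roc,
               comparison = p$comparison))
  invisible(p)
}
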