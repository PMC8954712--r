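#' Default end-to-end pipeline configuration
#'
#' Every stage constant of the analysis protocol is a named, overridable
#' default: potency cutoff pIC50 6.0 (1 uM), 3:1 train:test ratio, 5-fold
#' cross-validation, random forest with 20 trees of depth 15, descriptor
#' screens at 0.80 modal fraction and 0.95 correlation, fragment support
#' threshold 2.
#'
#' @return nested named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    data = list(activity = NULL, fingerprints = NULL,
                simulate = list()),   # generator_config() overrides
    label = list(cutoff = 6.0),
    split = list(ratio = "3:1"),
    balance = list(enabled = TRUE, policy = "both", k = 5),
    classify = list(algorithms = ALGORITHMS, folds = 5),
    mine = list(min_support = 2, min_ig = 0.0, top = 30),
    chemspace = list(constant_fraction = 0.80, corr_cutoff = 0.95)
  )
}

merge_config <- function(defaults, user, path = "config") {
  extra <- setdiff(names(user), names(defaults))
  if (length(extra) > 0)
    stop("unknown ", path, " key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        key != "simulate") {
      defaults[[key]] <- merge_config(defaults[[key]], as.list(user[[key]]),
                                      paste(path, key, sep = "$"))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

load_config <- function(config) {
  user <- if (is.character(config)) {
    if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  } else if (is.list(config)) config
  else stop("`config` must be a list or a YAML/JSON file path", call. = FALSE)
  cfg <- merge_config(default_pipeline_config(), user)
  cfg$classify$algorithms <- unlist(cfg$classify$algorithms)
  if (!cfg$balance$policy %in% c("both", "majority-only"))
    stop("balance$policy must be 'both' or 'majority-only'", call. = FALSE)
  bad <- setdiff(cfg$classify$algorithms, ALGORITHMS)
  if (length(bad) > 0)
    stop("unknown algorithm(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg
}

#' Render publication-style report tables
#'
#' Formats evaluation rows and fragment statistics the way published
#' fingerprint-classification tables are laid out: model rows with columns
#' `Model, AUC, CA, MCC, TP, TN, FP, FN, SE, SP, BA`, metrics rounded
#' half-up to 3 decimals (undefined MCC rendered `-`, BA averaged from the
#' rounded SE and SP), and fragment rows with frequencies printed as
#' `"value (count)"`. Pure function of its inputs; files are written only
#' when `out_dir` is given.
#'
#' @param eval_rows data frame from [run_grid()] (or any frame with its
#'   metric columns plus `fingerprint`, `algorithm`, `split`).
#' @param fragment_rows data frame from [rank_fragments()], or `NULL`.
#' @param out_dir optional output directory for CSV + text files.
#' @return list with `models` and `fragments` character data frames (and
#'   `paths` when written).
#' @export
render_tables <- function(eval_rows, fragment_rows = NULL, out_dir = NULL) {
  models <- NULL
  if (!is.null(eval_rows)) {
    models <- data.frame(
      Split = eval_rows$split,
      Model = paste(eval_rows$fingerprint, eval_rows$algorithm, sep = "-"),
      AUC = fmt_metric(eval_rows$AUC), CA = fmt_metric(eval_rows$CA),
      MCC = fmt_metric(eval_rows$MCC),
      TP = eval_rows$TP, TN = eval_rows$TN,
      FP = eval_rows$FP, FN = eval_rows$FN,
      SE = fmt_metric(eval_rows$SE), SP = fmt_metric(eval_rows$SP),
      BA = fmt_metric(eval_rows$BA),
      stringsAsFactors = FALSE)
  }
  fragments <- NULL
  if (!is.null(fragment_rows)) {
    fragments <- data.frame(
      Bit = fragment_rows$bit_name,
      IG = fmt_metric(fragment_rows$ig),
      FP = sprintf("%s (%d)", fmt_metric(fragment_rows$freq_P),
                   fragment_rows$n_fragment_P),
      FN = sprintf("%s (%d)", fmt_metric(fragment_rows$freq_N),
                   fragment_rows$n_fragment_N),
      Polarity = fragment_rows$polarity,
      stringsAsFactors = FALSE)
  }
  out <- list(models = models, fragments = fragments)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    if (!is.null(models)) {
      p <- file.path(out_dir, "model_report.csv")
      write.csv(models, p, row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
    if (!is.null(fragments)) {
      p <- file.path(out_dir, "fragment_report.csv")
      write.csv(fragments, p, row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
    txt <- file.path(out_dir, "report.txt")
    con <- file(txt, "w"); on.exit(close(con))
    if (!is.null(models)) {
      writeLines("== Model performance ==", con)
      writeLines(capture_table(models), con)
    }
    if (!is.null(fragments)) {
      writeLines("", con)
      writeLines("== Ranked fragments ==", con)
      writeLines(capture_table(fragments), con)
    }
    paths <- c(paths, txt)
    out$paths <- paths
  }
  out
}

capture_table <- function(df) {
  utils::capture.output(print(df, row.names = FALSE))
}

log_stage <- function(verbose, stage, ...) {
  if (verbose)
    message(sprintf("[fragminer] %s: %s", stage, paste0(..., collapse = "")))
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates `simulate (or load) -> label -> split -> balance ->
#' train/evaluate -> mine -> report` and writes every stage output plus a
#' run manifest (configuration snapshot, seeds, package versions, and an
#' md5 digest of every output file) into `out_dir`. With the same
#' configuration and seed, all deterministic stage outputs are
#' byte-identical across runs.
#'
#' @param config configuration list or YAML/JSON file path; see
#'   [default_pipeline_config()] for the schema and defaults. Unknown keys
#'   fail before any computation.
#' @param out_dir output directory (created if needed).
#' @param verbose emit per-stage log messages with seeds and row counts.
#' @return invisibly, a list with the manifest and main in-memory results.
#' @export
run_pipeline <- function(config = list(), out_dir, verbose = TRUE) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed

  # -- data ------------------------------------------------------------
  if (!is.null(cfg$data$activity) && !is.null(cfg$data$fingerprints)) {
    activity <- load_activity_table(cfg$data$activity, cfg$label$cutoff)
    fp <- load_fingerprint_table(cfg$data$fingerprints)
    log_stage(verbose, "load", nrow(activity), " compounds from supplied files")
  } else {
    sim_cfg <- do.call(generator_config,
                       modifyList(list(seed = seed), cfg$data$simulate))
    sim <- generate_fingerprint_dataset(sim_cfg)
    activity <- sim$activity
    fp <- sim$fingerprints
    log_stage(verbose, "simulate", nrow(fp), " compounds x ", ncol(fp),
              " bits (seed ", seed, ")")
  }
  activity <- label_activity(activity, cfg$label$cutoff)
  fp <- fp[activity$compound_id, , drop = FALSE]
  cls_tab <- table(activity$potency_class)
  log_stage(verbose, "label", paste(names(cls_tab), cls_tab, collapse = " / "))

  # fail fast before any training if stratification is impossible
  test_frac <- 1 - parse_ratio(cfg$split$ratio)
  min_train_class <- floor(min(cls_tab) * (1 - test_frac))
  if (min_train_class < cfg$classify$folds)
    stop("stratification error: smallest class leaves ~", min_train_class,
         " training members for ", cfg$classify$folds, "-fold CV", call. = FALSE)

  write_activity_table(activity, file.path(out_dir, "activity.csv"))
  write_fingerprint_table(fp, file.path(out_dir, "fingerprints.csv"))

  split <- stratified_split(activity, ratio = cfg$split$ratio, seed = seed)
  jsonlite::write_json(
    list(train_ids = split$train_ids, test_ids = split$test_ids),
    file.path(out_dir, "split.json"))
  log_stage(verbose, "split", length(split$train_ids), " train / ",
            length(split$test_ids), " test")

  labels <- setNames(activity$potency_class, activity$compound_id)

  if (isTRUE(cfg$balance$enabled)) {
    res <- smote_tomek(fp[split$train_ids, , drop = FALSE],
                       labels[split$train_ids], seed = seed,
                       k = cfg$balance$k, policy = cfg$balance$policy)
    write_fingerprint_table(res$matrix, file.path(out_dir, "balanced_train.csv"))
    write.csv(data.frame(row = rownames(res$matrix), label = res$labels,
                         provenance = res$provenance),
              file.path(out_dir, "balanced_provenance.csv"), row.names = FALSE)
    log_stage(verbose, "balance",
              paste(names(table(res$labels)), table(res$labels), collapse = " / "),
              " after SMOTE+Tomek (", length(res$removed_ids), " removed)")
  }

  specs <- lapply(cfg$classify$algorithms, algorithm_spec)
  grid <- run_grid(list(FP = fp), labels, specs = specs, split = split,
                   folds = cfg$classify$folds,
                   balance = isTRUE(cfg$balance$enabled),
                   k_smote = cfg$balance$k, seed = seed)
  log_stage(verbose, "train-eval", nrow(grid), " evaluation rows")

  frags <- rank_fragments(fp, labels, min_ig = cfg$mine$min_ig,
                          min_support = cfg$mine$min_support)
  frags <- head(frags, cfg$mine$top)
  log_stage(verbose, "mine", nrow(frags), " ranked fragments")

  report <- render_tables(grid, frags, out_dir = out_dir)

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    config = cfg,
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    versions = list(
      R = paste(R.version$major, R.version$minor, sep = "."),
      fragminer = as.character(utils::packageVersion("fragminer"))),
    outputs = as.list(setNames(as.character(tools::md5sum(files)),
                               basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage(verbose, "report", "manifest + reports written to ", out_dir)
  invisible(list(manifest = manifest, grid = grid, fragments = frags,
                 split = split, activity = activity))
}
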