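ALGORITHMS <- c("SVM", "LR", "kNN", "ANN", "NB", "RF", "DT")

#' Specify a classification algorithm
#'
#' Seven classical algorithms are supported: support vector machine
#' (`SVM`), logistic regression (`LR`), k-nearest neighbors (`kNN`),
#' artificial neural network (`ANN`), naive Bayes (`NB`), random forest
#' (`RF`), and decision tree (`DT`). Hyperparameters not given fall back
#' to fixed defaults; the random forest defaults are 20 trees with maximum
#' depth 15.
#'
#' @param name algorithm name, one of `SVM`, `LR`, `kNN`, `ANN`, `NB`,
#'   `RF`, `DT`.
#' @param ... hyperparameter overrides (e.g. `k = 3` for kNN,
#'   `num.trees = 50` for RF).
#' @return object of class `algorithm_spec`.
#' @export
algorithm_spec <- function(name, ...) {
  if (!is.character(name) || length(name) != 1L || !(name %in% ALGORITHMS))
    stop("unknown algorithm '", name, "'; valid names: ",
         paste(ALGORITHMS, collapse = ", "), call. = FALSE)
  defaults <- switch(name,
    SVM = list(kernel = "radial", cost = 1),
    LR = list(),
    kNN = list(k = 5),
    ANN = list(size = 5, decay = 0.1, maxit = 300),
    NB = list(laplace = 1),
    RF = list(num.trees = 20, max.depth = 15),
    DT = list()
  )
  structure(list(name = name,
                 hyperparameters = modifyList(defaults, list(...))),
            class = "algorithm_spec")
}

#' Default list of the seven algorithm specifications
#'
#' @return named list of [algorithm_spec()] objects.
#' @export
default_algorithms <- function() {
  setNames(lapply(ALGORITHMS, algorithm_spec), ALGORITHMS)
}

as_label_factor <- function(labels) factor(as.character(labels), levels = c("P", "N"))

#' Create a trainable model handle
#'
#' Returns a handle with `$fit(x, y)`; fitting returns a trained handle
#' whose `$predict_prob(x)` yields the positive-class (`"P"`) probability
#' for each row. All stochastic elements (probability calibration, weight
#' initialization, bootstrap draws) are seeded, so the same seed and data
#' give identical predictions.
#'
#' @param spec an [algorithm_spec()] (or algorithm name).
#' @param seed integer seed.
#' @return object of class `fragminer_model`.
#' @export
make_model <- function(spec, seed = 1) {
  if (is.character(spec)) spec <- algorithm_spec(spec)
  if (!inherits(spec, "algorithm_spec"))
    stop("`spec` must be an algorithm_spec", call. = FALSE)
  hp <- spec$hyperparameters
  model <- list(spec = spec, seed = seed, trained = FALSE)
  model$fit <- function(x, y) {
    x <- as.matrix(x)
    y <- as_label_factor(y)
    if (any(is.na(y)) || length(unique(y)) < 2)
      stop("training labels must contain both classes", call. = FALSE)
    fitted <- with_seed(seed, switch(spec$name,
      SVM = {
        f <- e1071::svm(x, y, kernel = hp$kernel, cost = hp$cost,
                        probability = TRUE, scale = FALSE)
        function(newx) attr(predict(f, newx, probability = TRUE),
                            "probabilities")[, "P"]
      },
      LR = {
        df <- as.data.frame(x); df$..y <- as.numeric(y == "P")
        f <- suppressWarnings(glm(..y ~ ., data = df, family = binomial()))
        function(newx) suppressWarnings(
          predict(f, as.data.frame(newx), type = "response"))
      },
      kNN = {
        # lazy learner: remember the training set, vote at predict time
        function(newx) {
          pred <- with_seed(seed,
            class::knn(x, as.matrix(newx), y, k = hp$k, prob = TRUE))
          win <- attr(pred, "prob")
          ifelse(pred == "P", win, 1 - win)
        }
      },
      ANN = {
        f <- nnet::nnet(x, as.numeric(y == "P"), size = hp$size,
                        decay = hp$decay, maxit = hp$maxit, trace = FALSE,
                        MaxNWts = 50000)
        function(newx) as.numeric(predict(f, as.matrix(newx)))
      },
      NB = {
        df <- as.data.frame(lapply(as.data.frame(x),
                                   function(col) factor(col, levels = c(0, 1))))
        f <- e1071::naiveBayes(df, y, laplace = hp$laplace)
        function(newx) {
          nd <- as.data.frame(lapply(as.data.frame(newx),
                                     function(col) factor(col, levels = c(0, 1))))
          predict(f, nd, type = "raw")[, "P"]
        }
      },
      RF = {
        df <- as.data.frame(x); df$..y <- y
        f <- ranger::ranger(dependent.variable.name = "..y", data = df,
                            num.trees = hp$num.trees, max.depth = hp$max.depth,
                            probability = TRUE, seed = seed)
        function(newx) predict(f, as.data.frame(newx))$predictions[, "P"]
      },
      DT = {
        df <- as.data.frame(x); df$..y <- y
        f <- rpart::rpart(..y ~ ., data = df, method = "class")
        function(newx) predict(f, as.data.frame(newx), type = "prob")[, "P"]
      }
    ))
    trained <- model
    trained$trained <- TRUE
    trained$feature_names <- colnames(x)
    trained$predict_prob <- function(newx) {
      newx <- as.matrix(newx)
      if (!is.null(colnames(newx)) && !is.null(trained$feature_names) &&
          !identical(colnames(newx), trained$feature_names))
        stop("feature columns of new data do not align with training columns",
             call. = FALSE)
      p <- as.numeric(fitted(newx))
      pmin(pmax(p, 0), 1)
    }
    structure(trained, class = "fragminer_model")
  }
  structure(model, class = "fragminer_model")
}

#' @export
print.fragminer_model <- function(x, ...) {
  hp <- x$spec$hyperparameters
  cat(sprintf("<%s model (%s), seed %d>\n", x$spec$name,
              if (x$trained) "trained" else "untrained", x$seed))
  if (length(hp) > 0)
    cat("  ", paste(names(hp), unlist(hp), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds.
make_folds <- function(labels, folds, seed = NULL) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < folds))
    stop("class(es) smaller than the number of folds: ",
         paste(names(tab)[tab < folds], collapse = ", "), call. = FALSE)
  assignment <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

#' Pooled stratified k-fold cross-validation
#'
#' Assigns compounds to stratified folds, trains one model per fold on the
#' complement, and predicts each held-out fold once. The pooled
#' out-of-fold predictions feed a single confusion table, so the counts
#' sum to the full training-set size. An optional `preprocess` function
#' (e.g. a balancing step) is applied to each fold's training portion
#' only, never to the held-out fold.
#'
#' @param spec an [algorithm_spec()] or algorithm name.
#' @param x feature matrix.
#' @param labels class labels aligned with rows.
#' @param folds number of folds (default 5); every class must have at
#'   least `folds` members.
#' @param seed integer seed (fold assignment and model fitting).
#' @param preprocess optional `function(x, labels)` returning
#'   `list(x =, labels =)`, applied per-fold to the training portion.
#' @return list with pooled `scores`, `predicted`, `truth`, `confusion`,
#'   `auc`, the `fold` assignment, and per-fold `models`.
#' @export
cross_validate <- function(spec, x, labels, folds = 5, seed = 1,
                           preprocess = NULL) {
  x <- as.matrix(x)
  labels <- as_label_factor(labels)
  fold <- make_folds(labels, folds, seed)
  scores <- rep(NA_real_, nrow(x))
  models <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    tr_x <- x[tr, , drop = FALSE]
    tr_y <- labels[tr]
    if (!is.null(preprocess)) {
      pp <- preprocess(tr_x, tr_y)
      tr_x <- pp$x; tr_y <- pp$labels
    }
    m <- make_model(spec, seed = seed + f)$fit(tr_x, tr_y)
    models[[f]] <- m
    scores[!tr] <- m$predict_prob(x[!tr, , drop = FALSE])
  }
  predicted <- factor(ifelse(scores >= 0.5, "P", "N"), levels = c("P", "N"))
  ct <- confusion_from_labels(labels, predicted)
  list(scores = scores, predicted = predicted, truth = labels,
       confusion = ct, auc = roc_auc(scores, labels), fold = fold,
       models = models)
}

#' Evaluate a trained model on a held-out split
#'
#' @param model trained [make_model()] handle.
#' @param x feature matrix of the held-out compounds (columns must align
#'   with the training columns).
#' @param labels true class labels.
#' @return list with `scores`, `predicted`, `confusion`, `auc` and a
#'   display-rounded `metrics` row.
#' @export
evaluate_on_split <- function(model, x, labels) {
  if (!inherits(model, "fragminer_model") || !isTRUE(model$trained))
    stop("`model` must be a trained fragminer model", call. = FALSE)
  x <- as.matrix(x)
  labels <- as_label_factor(labels)
  scores <- model$predict_prob(x)
  predicted <- factor(ifelse(scores >= 0.5, "P", "N"), levels = c("P", "N"))
  ct <- confusion_from_labels(labels, predicted)
  auc <- if (length(unique(labels)) == 2) roc_auc(scores, labels) else NA_real_
  list(scores = scores, predicted = predicted, confusion = ct, auc = auc,
       metrics = report_metrics(ct, auc))
}

#' Run the fingerprint x algorithm evaluation grid
#'
#' For every (fingerprint table, algorithm) pair, evaluates the model by
#' pooled stratified cross-validation on the training set and on the
#' held-out test set, optionally balancing the training set with
#' SMOTE+Tomek first. The default balancing order (balance the whole
#' training set, then cross-validate) mirrors the historical protocol of
#' published fingerprint-classification studies but lets synthetic
#' neighbors leak across folds; `balance_within_folds = TRUE` instead
#' balances each fold's training portion only, the statistically sound
#' alternative.
#'
#' @param fingerprints named list of fingerprint matrices (shared
#'   compound ids as row names).
#' @param labels factor/character class labels named by compound id.
#' @param specs list of [algorithm_spec()]s (default all seven).
#' @param split optional [stratified_split()]; built from `labels` at
#'   `ratio` when `NULL`.
#' @param ratio train:test ratio used when `split` is `NULL`.
#' @param folds cross-validation folds.
#' @param balance apply SMOTE+Tomek balancing to the training data.
#' @param balance_within_folds balance inside each CV fold instead of
#'   before CV (only meaningful with `balance = TRUE`).
#' @param k_smote SMOTE neighborhood size.
#' @param seed integer seed.
#' @return data frame with one row per (fingerprint, algorithm, split in
#'   `cv_train`/`test`), display-rounded metric columns, ranked within
#'   each split by AUC then CA (descending).
#' @export
run_grid <- function(fingerprints, labels, specs = default_algorithms(),
                     split = NULL, ratio = 3, folds = 5, balance = FALSE,
                     balance_within_folds = FALSE, k_smote = 5, seed = 1) {
  if (!is.list(fingerprints) || is.null(names(fingerprints)))
    stop("`fingerprints` must be a named list of matrices", call. = FALSE)
  labels <- setNames(as_label_factor(labels), names(labels))
  ids <- names(labels)
  if (is.null(ids)) stop("`labels` must be named by compound id", call. = FALSE)
  for (nm in names(fingerprints)) {
    if (!all(ids %in% rownames(fingerprints[[nm]])))
      stop("fingerprint table '", nm, "' is missing compounds: ",
           paste(head(setdiff(ids, rownames(fingerprints[[nm]])), 5),
                 collapse = ", "), call. = FALSE)
  }
  if (is.null(split)) {
    records <- data.frame(compound_id = ids, potency_class = labels,
                          stringsAsFactors = FALSE)
    split <- stratified_split(records, ratio = ratio, seed = seed)
  }
  balance_fun <- function(x, y) {
    res <- smote_tomek(x, y, seed = seed, k = k_smote)
    list(x = res$matrix, labels = as_label_factor(res$labels))
  }
  rows <- list()
  for (fp_name in names(fingerprints)) {
    fp <- fingerprints[[fp_name]]
    tr_x <- fp[split$train_ids, , drop = FALSE]
    tr_y <- labels[split$train_ids]
    te_x <- fp[split$test_ids, , drop = FALSE]
    te_y <- labels[split$test_ids]
    cv_train_x <- tr_x; cv_train_y <- tr_y
    preprocess <- NULL
    if (balance && !balance_within_folds) {
      b <- balance_fun(tr_x, tr_y)
      cv_train_x <- b$x; cv_train_y <- b$labels
    } else if (balance && balance_within_folds) {
      preprocess <- balance_fun
    }
    for (sp in specs) {
      if (is.character(sp)) sp <- algorithm_spec(sp)
      cv <- cross_validate(sp, cv_train_x, cv_train_y, folds = folds,
                           seed = seed, preprocess = preprocess)
      final <- make_model(sp, seed = seed)$fit(cv_train_x, cv_train_y)
      te <- evaluate_on_split(final, te_x, te_y)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(fingerprint = fp_name, algorithm = sp$name,
                   split = "cv_train", stringsAsFactors = FALSE),
        report_metrics(cv$confusion, cv$auc))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(fingerprint = fp_name, algorithm = sp$name,
                   split = "test", stringsAsFactors = FALSE),
        te$metrics)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$split, -out$AUC, -out$CA), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "split") <- split
  attr(out, "balanced") <- balance
  out
}
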