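sim_small <- small_sim(seed = 21, n_bits = 60)
labels_small <- setNames(sim_small$activity$potency_class,
                         sim_small$activity$compound_id)

test_that("algorithm specs validate names and carry fixed RF defaults", {
  rf <- algorithm_spec("RF")
  expect_equal(rf$hyperparameters$num.trees, 20)
  expect_equal(rf$hyperparameters$max.depth, 15)
  expect_error(algorithm_spec("XGB"), "SVM, LR, kNN, ANN, NB, RF, DT")
  expect_equal(algorithm_spec("kNN", k = 3)$hyperparameters$k, 3)
  expect_length(default_algorithms(), 7)
})

test_that("models are deterministic under a fixed seed", {
  x <- sim_small$fingerprints
  y <- labels_small
  for (alg in c("SVM", "RF", "ANN", "kNN")) {
    m1 <- make_model(alg, seed = 3)$fit(x, y)
    m2 <- make_model(alg, seed = 3)$fit(x, y)
    expect_identical(m1$predict_prob(x), m2$predict_prob(x))
  }
})

test_that("every algorithm trains and emits probabilities in [0, 1]", {
  x <- sim_small$fingerprints
  y <- labels_small
  for (alg in c("SVM", "LR", "kNN", "ANN", "NB", "RF", "DT")) {
    m <- make_model(alg, seed = 1)$fit(x, y)
    p <- m$predict_prob(x)
    expect_length(p, nrow(x))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("cross-validation pools one honest prediction per compound", {
  cv <- cross_validate("RF", sim_small$fingerprints, labels_small,
                       folds = 5, seed = 2)
  ct <- cv$confusion
  expect_equal(ct$tp + ct$tn + ct$fp + ct$fn, 60)
  expect_true(all(!is.na(cv$scores)))
  # stratification: each fold holds both classes
  for (f in 1:5)
    expect_setequal(unique(as.character(cv$truth[cv$fold == f])), c("P", "N"))
  # fold models trained without their own fold: per-fold training size
  expect_length(cv$models, 5)
  expect_error(cross_validate("RF", sim_small$fingerprints,
                              labels_small, folds = 20), "smaller than")
  # leave-one-out-like degenerate folds still predict each row once
  few <- planted_count_matrix(6, 6, 5, 1, extra = 4)
  cv2 <- cross_validate("NB", few$fp, few$labels, folds = 6, seed = 1)
  expect_length(cv2$scores, 12)
  expect_true(all(!is.na(cv2$scores)))
})

test_that("perfectly separable planted data is classified perfectly", {
  # margin >> noise: five redundant bits encode the class exactly, so
  # every bootstrap tree finds a pure split
  n <- 40
  cls <- rep(c("P", "N"), each = n / 2)
  key <- matrix(as.numeric(cls == "P"), n, 5)
  fp <- cbind(key, matrix(rbinom(n * 5, 1, 0.5), n, 5))
  colnames(fp) <- c(sprintf("key%d", 1:5), sprintf("b%02d", 1:5))
  cv <- cross_validate("RF", fp, cls, folds = 5, seed = 4)
  expect_equal(accuracy(cv$confusion), 1.0)
  expect_equal(cv$auc, 1.0)
})

test_that("held-out evaluation computes confusion, AUC and alignment checks", {
  sp <- stratified_split(sim_small$activity, "3:1", seed = 5)
  tr <- sim_small$fingerprints[sp$train_ids, ]
  te <- sim_small$fingerprints[sp$test_ids, ]
  m <- make_model("RF", seed = 1)$fit(tr, labels_small[sp$train_ids])
  ev <- evaluate_on_split(m, te, labels_small[sp$test_ids])
  ct <- ev$confusion
  expect_equal(ct$tp + ct$tn + ct$fp + ct$fn, length(sp$test_ids))
  expect_true(ev$auc >= 0 && ev$auc <= 1)
  expect_error(evaluate_on_split(m, te[, rev(seq_len(ncol(te)))],
                                 labels_small[sp$test_ids]), "align")
  # a degenerate always-potent scorer has SE 1 and SP 0
  always_p <- m
  always_p$predict_prob <- function(newx) rep(1, nrow(newx))
  ev2 <- evaluate_on_split(always_p, te, labels_small[sp$test_ids])
  expect_equal(sensitivity(ev2$confusion), 1.0)
  expect_equal(specificity(ev2$confusion), 0.0)
})

test_that("the evaluation grid has full cardinality and is rank-ordered", {
  fps <- list(FPA = sim_small$fingerprints,
              FPB = sim_small$fingerprints[, 1:30])
  grid <- run_grid(fps, labels_small,
                   specs = lapply(c("NB", "DT"), algorithm_spec),
                   ratio = 3, folds = 5, seed = 6)
  expect_equal(nrow(grid), 2 * 2 * 2)  # fingerprints x algorithms x splits
  expect_equal(sum(grid$split == "cv_train"), 4)
  for (s in c("cv_train", "test")) {
    g <- grid[grid$split == s, ]
    d_auc <- diff(g$AUC)
    expect_true(all(d_auc <= 1e-12))                    # AUC non-increasing
    ties <- abs(d_auc) <= 1e-12
    expect_true(all(diff(g$CA)[ties] <= 1e-12))         # ties broken by CA
  }
  # metric self-consistency: every row recomputes from its own confusion
  for (i in seq_len(nrow(grid))) {
    ct <- confusion_table(grid$TP[i], grid$TN[i], grid$FP[i], grid$FN[i])
    rm_ <- report_metrics(ct)
    for (col in c("CA", "MCC", "SE", "SP", "BA"))
      expect_equal(grid[[i, col]], rm_[[col]], info = paste("row", i, col))
  }
  expect_error(run_grid(list(FPA = sim_small$fingerprints[1:10, ]),
                        labels_small, specs = list(algorithm_spec("NB"))),
               "missing compounds")
})
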