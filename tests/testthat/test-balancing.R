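test_that("nearest neighbors match an exhaustive scan with index tie-breaks", {
  x <- matrix(c(0, 1, 3), ncol = 1)
  expect_equal(nearest_neighbors(x, 1, 1), 2L)
  # identical rows: lowest-index duplicate first
  dup <- matrix(c(1, 1, 1, 0, 1, 0, 1, 0), 4, 2, byrow = TRUE)
  expect_equal(nearest_neighbors(dup, 4, 2), c(2L, 3L))
  expect_error(nearest_neighbors(x, 1, 3), "eligible")
  # random binary matrix vs brute-force all-pairs oracle
  set.seed(101)
  m <- matrix(rbinom(200, 1, 0.4), 20, 10)
  d <- as.matrix(dist(m))
  for (i in c(1, 7, 20)) {
    ord <- order(d[i, -i], setdiff(1:20, i))
    expect_equal(nearest_neighbors(m, i, 5), setdiff(1:20, i)[ord][1:5])
  }
})

test_that("SMOTE interpolates inside parent bounding boxes and binarizes", {
  two <- matrix(c(1, 0, 1, 1, 0, 1), 2, 3, byrow = TRUE)
  same <- two[c(1, 1), ]
  syn <- smote_oversample(same, 5, seed = 1)
  expect_true(all(apply(syn, 1, function(r) all(r == same[1, ]))))

  set.seed(7)
  minority <- matrix(rbinom(80, 1, 0.5), 8, 10)
  syn <- smote_oversample(minority, 30, k = 3, seed = 2, binarize = FALSE)
  expect_equal(nrow(syn), 30)
  par <- attr(syn, "parents")
  for (s in 1:30) {
    lo <- pmin(minority[par[s, 1], ], minority[par[s, 2], ])
    hi <- pmax(minority[par[s, 1], ], minority[par[s, 2], ])
    expect_true(all(syn[s, ] >= lo - 1e-12 & syn[s, ] <= hi + 1e-12))
  }
  synb <- smote_oversample(minority, 30, k = 3, seed = 2)
  expect_true(all(synb %in% c(0, 1)))
  # binarization threshold: >= 0.5 goes to 1
  expect_equal(unname((matrix(0.5, 1, 1) >= 0.5) * 1)[1, 1], 1)
  expect_error(smote_oversample(minority[1, , drop = FALSE], 3), "at least 2")
})

test_that("Tomek links equal the brute-force mutual-NN oracle", {
  # 1-D: P at 0, 1, 2; N at 0.4 -> single link between 0.0 and 0.4
  x <- matrix(c(0, 1, 2, 0.4), ncol = 1)
  l <- c("P", "P", "P", "N")
  links <- find_tomek_links(x, l)
  expect_equal(nrow(links), 1)
  expect_equal(as.vector(links[1, ]), c(1L, 4L))
  # well-separated clusters: none
  y <- rbind(matrix(0, 5, 2), matrix(10, 5, 2)) + runif(20, 0, 0.1)
  expect_equal(nrow(find_tomek_links(y, rep(c("P", "N"), each = 5))), 0)
  # one class only: empty
  expect_equal(nrow(find_tomek_links(y, rep("P", 10))), 0)
  # random 30-point instances vs O(n^2) oracle, and P<->N symmetry
  for (s in 1:5) {
    set.seed(200 + s)
    z <- matrix(runif(60), 30, 2)
    lab <- sample(c("P", "N"), 30, replace = TRUE)
    got <- find_tomek_links(z, lab)
    oracle <- brute_force_tomek(z, lab)
    expect_equal(unname(got), unname(oracle))
    flipped <- ifelse(lab == "P", "N", "P")
    expect_equal(find_tomek_links(z, flipped), got)
  }
})

test_that("SMOTE+Tomek balances training sets and conserves provenance", {
  for (s in 1:20) {
    sim <- generate_fingerprint_dataset(
      generator_config(n_compounds = 88, n_potent = 69, seed = 300 + s))
    lab <- as.character(sim$activity$potency_class)
    res <- smote_tomek(sim$fingerprints, lab, seed = s)
    counts <- table(res$labels)
    expect_lte(abs(counts[["P"]] - counts[["N"]]), 4)
    # original majority rows never increase
    expect_lte(sum(res$labels == "P" & res$provenance == "original"), 69)
    # synthetic rows are minority-class only
    expect_true(all(res$labels[res$provenance == "synthetic"] == "N"))
    expect_equal(nrow(res$matrix), length(res$labels))
    expect_equal(nrow(res$matrix) + length(res$removed_ids), 69 + 69)
  }
})

test_that("already balanced, separated data passes through unchanged", {
  x <- rbind(matrix(0, 6, 4), matrix(1, 6, 4))
  x[, 1] <- rep(c(0, 1, 0, 1), 3)  # some within-class variety
  lab <- rep(c("P", "N"), each = 6)
  res <- smote_tomek(x, lab, seed = 1)
  expect_equal(nrow(res$matrix), 12)
  expect_length(res$removed_ids, 0)
  expect_true(all(res$provenance == "original"))
})

test_that("removal policy controls which link members are dropped", {
  # minority P pair far apart; one cross-class mutual-NN pair at the origin
  x <- matrix(c(0, 0, 10, 0, 0.1, 0, 20, 0, 20.1, 0), 5, 2, byrow = TRUE)
  lab <- c("P", "P", "N", "N", "N")
  both <- smote_tomek(x, lab, seed = 1, policy = "both", binarize = FALSE)
  maj <- smote_tomek(x, lab, seed = 1, policy = "majority-only",
                     binarize = FALSE)
  # same seed -> same synthetic rows -> same links; policies differ only
  # in which members die
  expect_equal(length(both$removed_ids), 2 * length(maj$removed_ids))
  expect_gte(length(maj$removed_ids), 1)
  labeled <- setNames(c(lab, "P"), c(sprintf("row_%03d", 1:5), "syn_001"))
  expect_true(all(labeled[maj$removed_ids] == "N"))
})
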