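test_that("bit counts are exact on planted fixtures and trivial bits", {
  fx <- planted_count_matrix(89, 28, 49, 2)
  counts <- bit_class_counts(fx$fp, fx$labels)
  planted <- counts[counts$bit_name == "planted", ]
  expect_equal(planted$n_fragment_P, 49)
  expect_equal(planted$n_fragment_N, 2)
  expect_equal(planted$n_fragment_total, 51)
  expect_equal(planted$n_P, 89)
  expect_equal(planted$n_total, 117)

  all1 <- matrix(1, 5, 2, dimnames = list(NULL, c("a", "b")))
  c1 <- bit_class_counts(all1, c("P", "P", "P", "N", "N"))
  expect_true(all(c1$n_fragment_total == c1$n_total))
  c0 <- bit_class_counts(all1 * 0, c("P", "P", "P", "N", "N"))
  expect_true(all(c0$n_fragment_P == 0 & c0$n_fragment_N == 0))
  expect_error(bit_class_counts(all1, c("P", "N")), "match")
})

test_that("class frequency matches worked examples and edge cases", {
  expect_equal(round_half_up(class_frequency(49, 51, 117, 89)), 1.263)
  expect_equal(round_half_up(class_frequency(2, 31, 117, 28)), 0.270)
  expect_equal(round_half_up(class_frequency(29, 31, 117, 89)), 1.230)
  expect_equal(round_half_up(class_frequency(2, 34, 117, 28)), 0.246)
  expect_equal(round_half_up(class_frequency(2, 51, 117, 28)), 0.164)
  # bit present everywhere cancels exactly
  expect_equal(class_frequency(89, 117, 117, 89), 1.0)
  expect_true(is.na(class_frequency(0, 0, 117, 89)))
  expect_error(class_frequency(5, 3, 117, 89), "exceed")
})

test_that("information gain matches worked examples and is well-behaved", {
  expect_equal(round_half_up(information_gain(49, 2, 89, 28)), 0.144)
  expect_equal(round_half_up(information_gain(32, 2, 89, 28)), 0.064)
  # identical prevalence in both classes -> zero gain
  expect_equal(information_gain(30, 30, 60, 60), 0)
  expect_equal(information_gain(0, 0, 89, 28), 0)
  expect_equal(information_gain(89, 28, 89, 28), 0)
  # invariant under swapping the present/absent encoding
  set.seed(5)
  for (i in 1:50) {
    nP <- sample(5:90, 1); nN <- sample(5:90, 1)
    fP <- sample(0:nP, 1); fN <- sample(0:nN, 1)
    ig <- information_gain(fP, fN, nP, nN)
    expect_gte(ig, 0)
    expect_equal(information_gain(nP - fP, nN - fN, nP, nN), ig)
  }
  expect_error(information_gain(90, 2, 89, 28), "exceed")
})

test_that("frequency pair is exactly consistent with its counts", {
  # freq_P * n_P + freq_N * n_N = n_total for every bit with support
  ref <- reference_fragment_rows()
  for (i in seq_len(nrow(ref))) {
    tot <- ref$count_P[i] + ref$count_N[i]
    fP <- class_frequency(ref$count_P[i], tot, REF_N_TOTAL, REF_N_P)
    fN <- class_frequency(ref$count_N[i], tot, REF_N_TOTAL, REF_N_N)
    expect_equal(fP * REF_N_P + fN * REF_N_N, REF_N_TOTAL)
  }
})

test_that("fragment ranking orders by IG and labels polarity", {
  fx <- planted_count_matrix(89, 28, 49, 2, extra = 3)
  fp <- cbind(fx$fp, constant = 1,
              negbit = c(rep(0, 89), rep(1, 5), rep(0, 23)),
              singleton = c(1, rep(0, 116)))
  ranked <- rank_fragments(fp, fx$labels)
  expect_equal(ranked$bit_name[1], "planted")
  expect_equal(ranked$polarity[1], "positive")
  expect_equal(ranked$polarity[ranked$bit_name == "negbit"], "negative")
  # constant bit: zero gain, neutral, ranked last
  cb <- ranked[ranked$bit_name == "constant", ]
  expect_equal(cb$ig, 0)
  expect_equal(cb$polarity, "neutral")
  expect_equal(ranked$bit_name[nrow(ranked)], "constant")
  # singleton support filtered at the default threshold
  expect_false("singleton" %in% ranked$bit_name)
  expect_true("singleton" %in%
                rank_fragments(fp, fx$labels, min_support = 1)$bit_name)
  # IG ordering is non-increasing
  expect_true(all(diff(ranked$ig) <= 1e-12))
})

test_that("two bits with the reference top gain tie at the head of the list", {
  # two copies of the 49/2 pattern plus weaker bits: both share rank 1-2
  fx <- planted_count_matrix(89, 28, 49, 2, extra = 2)
  fp <- cbind(fx$fp, planted2 = fx$fp[, "planted"],
              weaker = c(rep(1, 32), rep(0, 57), rep(1, 2), rep(0, 26)))
  ranked <- rank_fragments(fp, fx$labels)
  expect_setequal(ranked$bit_name[1:2], c("planted", "planted2"))
  expect_equal(round_half_up(ranked$ig[1]), 0.144)
  expect_equal(round_half_up(ranked$ig[3]), 0.064)
})
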