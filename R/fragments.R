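#' Per-bit class occurrence counts
#'
#' For every fingerprint bit, counts how many potent (`"P"`) and
#' non-potent (`"N"`) compounds contain it.
#'
#' @param fp binary fingerprint matrix (compounds x bits).
#' @param labels class labels aligned with rows.
#' @return data frame with one row per bit: `bit_name`, `n_fragment_P`,
#'   `n_fragment_N`, `n_fragment_total`, and the dataset totals `n_P`,
#'   `n_N`, `n_total`.
#' @export
bit_class_counts <- function(fp, labels) {
  if (!is.matrix(fp)) fp <- as.matrix(fp)
  if (is.null(colnames(fp)))
    colnames(fp) <- sprintf("bit_%04d", seq_len(ncol(fp)))
  if (length(labels) != nrow(fp))
    stop("`labels` length must match fingerprint rows", call. = FALSE)
  labels <- as.character(labels)
  nP <- sum(labels == "P"); nN <- sum(labels == "N")
  cP <- colSums(fp[labels == "P", , drop = FALSE])
  cN <- colSums(fp[labels == "N", , drop = FALSE])
  data.frame(bit_name = colnames(fp),
             n_fragment_P = as.integer(cP), n_fragment_N = as.integer(cN),
             n_fragment_total = as.integer(cP + cN),
             n_P = nP, n_N = nN, n_total = nP + nN,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Class-frequency enrichment of a substructure
#'
#' The frequency of a substructure in a class is
#' `(N_fragment_class * N_total) / (N_fragment_total * N_class)`:
#' the prevalence of the fragment among class members relative to its
#' prevalence in the whole dataset. Values above 1 mean the fragment is
#' over-represented in that class; a fragment present in every compound
#' scores exactly 1 in both classes.
#'
#' @param n_fragment_class compounds of the class containing the fragment.
#' @param n_fragment_total compounds (any class) containing the fragment.
#' @param n_total total number of compounds.
#' @param n_class number of compounds in the class.
#' @return enrichment ratio (vectorized); `NA` where the fragment is
#'   absent everywhere (`n_fragment_total = 0`).
#' @export
class_frequency <- function(n_fragment_class, n_fragment_total, n_total, n_class) {
  if (any(n_class <= 0) || any(n_total <= 0))
    stop("`n_class` and `n_total` must be positive", call. = FALSE)
  if (any(n_fragment_class > n_fragment_total))
    stop("`n_fragment_class` cannot exceed `n_fragment_total`", call. = FALSE)
  out <- (n_fragment_class * n_total) / (n_fragment_total * n_class)
  out[n_fragment_total == 0] <- NA_real_
  out
}

plogp <- function(p) ifelse(p > 0, p * log2(p), 0)

entropy2 <- function(a, b) {
  n <- a + b
  ifelse(n > 0, -(plogp(a / n) + plogp(b / n)), 0)
}

#' Information gain of a binary fingerprint bit
#'
#' Shannon information gain (base 2) of the potency class given the
#' present/absent status of a bit:
#' `IG = H(class) - P(present) H(class | present) - P(absent) H(class | absent)`,
#' with the convention `0 * log2(0) = 0`. IG is non-negative, zero exactly
#' when the bit is independent of the class in counts, and invariant to
#' swapping the present/absent encoding.
#'
#' @param n_fragment_P potent compounds containing the bit.
#' @param n_fragment_N non-potent compounds containing the bit.
#' @param n_P total potent compounds.
#' @param n_N total non-potent compounds.
#' @return information gain in bits (vectorized).
#' @export
information_gain <- function(n_fragment_P, n_fragment_N, n_P, n_N) {
  if (any(n_P <= 0) || any(n_N <= 0))
    stop("both classes must be non-empty", call. = FALSE)
  if (any(n_fragment_P > n_P) || any(n_fragment_N > n_N))
    stop("fragment counts cannot exceed class sizes", call. = FALSE)
  if (any(n_fragment_P < 0) || any(n_fragment_N < 0))
    stop("fragment counts must be non-negative", call. = FALSE)
  n <- n_P + n_N
  pres <- n_fragment_P + n_fragment_N
  absP <- n_P - n_fragment_P
  absN <- n_N - n_fragment_N
  h0 <- entropy2(n_P, n_N)
  hc <- (pres / n) * entropy2(n_fragment_P, n_fragment_N) +
    ((n - pres) / n) * entropy2(absP, absN)
  pmax(h0 - hc, 0)
}

#' Rank fingerprint bits as candidate pharmacophoric fragments
#'
#' Computes per-bit occurrence counts, information gain and both class
#' frequencies, filters by support and minimum IG, and ranks by IG
#' (descending; ties by potent-class frequency then bit name). Polarity
#' labels a bit `positive` when it is more frequent in the potent class,
#' `negative` when more frequent in the non-potent class, and `neutral`
#' when the two frequencies coincide (e.g. a constant bit).
#'
#' @param fp binary fingerprint matrix.
#' @param labels class labels aligned with rows.
#' @param min_ig minimum information gain to keep a bit.
#' @param min_support minimum number of compounds containing the bit; the
#'   default 2 discards singletons, which cannot evidence a reusable
#'   pharmacophore.
#' @return data frame of fragment statistics, ranked; columns of
#'   [bit_class_counts()] plus `ig`, `freq_P`, `freq_N`, `polarity`.
#' @export
rank_fragments <- function(fp, labels, min_ig = 0, min_support = 2) {
  stats <- bit_class_counts(fp, labels)
  if (stats$n_P[1] == 0 || stats$n_N[1] == 0)
    stop("both classes must be present to rank fragments", call. = FALSE)
  stats$ig <- information_gain(stats$n_fragment_P, stats$n_fragment_N,
                               stats$n_P, stats$n_N)
  stats$freq_P <- class_frequency(stats$n_fragment_P, stats$n_fragment_total,
                                  stats$n_total, stats$n_P)
  stats$freq_N <- class_frequency(stats$n_fragment_N, stats$n_fragment_total,
                                  stats$n_total, stats$n_N)
  stats$polarity <- ifelse(is.na(stats$freq_P), "neutral",
                    ifelse(stats$freq_P > stats$freq_N, "positive",
                    ifelse(stats$freq_N > stats$freq_P, "negative", "neutral")))
  keep <- stats$n_fragment_total >= min_support & stats$ig >= min_ig
  stats <- stats[keep, , drop = FALSE]
  ord <- order(-stats$ig, -stats$freq_P, stats$bit_name)
  stats <- stats[ord, , drop = FALSE]
  rownames(stats) <- NULL
  stats
}
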