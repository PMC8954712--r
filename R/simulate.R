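#' Default enrichment specification for the synthetic generator
#'
#' Eight bits whose class-conditional prevalences echo the count patterns
#' seen for privileged substructures in real kinase-inhibitor fingerprint
#' data (e.g. a bit present in roughly 55% of potent but 7% of non-potent
#' compounds).
#'
#' @return data frame with columns `bit_name`, `p_P`, `p_N`.
#' @export
default_enrichment <- function() {
  data.frame(
    bit_name = sprintf("EB%03d", 1:8),
    p_P = c(0.55, 0.54, 0.46, 0.40, 0.36, 0.33, 0.26, 0.20),
    p_N = c(0.07, 0.07, 0.14, 0.11, 0.07, 0.07, 0.00, 0.07),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic fingerprint generator
#'
#' Defaults emulate the shape of a curated DYRK1A inhibitor dataset: 117
#' compounds with an 89:28 potent:non-potent imbalance and 881 binary bits,
#' of which a handful are strongly enriched in the potent class, some are
#' constant, and some are near-duplicates of other bits.
#'
#' @param n_compounds total number of compounds.
#' @param n_potent number of potent (`"P"`) compounds.
#' @param n_bits total number of fingerprint bits.
#' @param enriched data frame (`bit_name`, `p_P`, `p_N`) of class-enriched
#'   bits drawn Bernoulli per class.
#' @param background_p presence probability of uninformative background
#'   bits (identical in both classes).
#' @param n_constant_bits number of all-ones bits.
#' @param n_correlated_pairs number of bits generated as a copy of a
#'   background bit with each entry flipped with probability `flip_p`.
#' @param flip_p flip probability for correlated duplicate bits.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_compounds = 117, n_potent = 89, n_bits = 881,
                             enriched = default_enrichment(),
                             background_p = 0.3, n_constant_bits = 30,
                             n_correlated_pairs = 40, flip_p = 0.05,
                             seed = 1) {
  cfg <- list(n_compounds = n_compounds, n_potent = n_potent, n_bits = n_bits,
              enriched = enriched, background_p = background_p,
              n_constant_bits = n_constant_bits,
              n_correlated_pairs = n_correlated_pairs, flip_p = flip_p,
              seed = seed)
  probs <- c(cfg$enriched$p_P, cfg$enriched$p_N, background_p, flip_p)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("generator probabilities must lie in [0, 1]", call. = FALSE)
  if (n_potent > n_compounds)
    stop("n_potent cannot exceed n_compounds", call. = FALSE)
  n_special <- nrow(cfg$enriched) + n_constant_bits + n_correlated_pairs
  if (n_special > n_bits)
    stop("enriched + constant + correlated bits exceed n_bits", call. = FALSE)
  if (n_correlated_pairs > 0 && n_bits - n_special < 1)
    stop("correlated pairs need at least one background bit to copy", call. = FALSE)
  if (anyDuplicated(cfg$enriched$bit_name))
    stop("duplicate enriched bit names", call. = FALSE)
  structure(cfg, class = "generator_config")
}

#' Generate a labeled synthetic fingerprint dataset
#'
#' Bits are class-conditionally independent Bernoulli draws (the simplest
#' structure consistent with per-bit frequency analysis); correlation
#' enters only through explicit duplicate-with-flip bit pairs, and
#' constant bits are all ones. Class sizes are exact, and pIC50 values are
#' drawn so that relabeling them reproduces the classes.
#'
#' @param config a [generator_config()].
#' @return list with `fingerprints` (binary matrix) and `activity`
#'   (labeled activity data frame).
#' @export
generate_fingerprint_dataset <- function(config = generator_config()) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, config)
  with_seed(config$seed, {
    n <- config$n_compounds
    ids <- sprintf("cmpd_%03d", seq_len(n))
    cls <- factor(sample(rep(c("P", "N"), c(config$n_potent, n - config$n_potent))),
                  levels = c("P", "N"))
    n_enr <- nrow(config$enriched)
    n_back <- config$n_bits - n_enr - config$n_constant_bits -
      config$n_correlated_pairs
    cols <- vector("list", config$n_bits)
    nm <- character(config$n_bits)
    j <- 0L
    for (e in seq_len(n_enr)) {
      p <- ifelse(cls == "P", config$enriched$p_P[e], config$enriched$p_N[e])
      j <- j + 1L; cols[[j]] <- rbinom(n, 1, p); nm[j] <- config$enriched$bit_name[e]
    }
    back_idx <- integer(0)
    for (b in seq_len(n_back)) {
      j <- j + 1L; cols[[j]] <- rbinom(n, 1, config$background_p)
      nm[j] <- sprintf("BG%04d", b); back_idx <- c(back_idx, j)
    }
    for (cst in seq_len(config$n_constant_bits)) {
      j <- j + 1L; cols[[j]] <- rep(1, n); nm[j] <- sprintf("CONST%03d", cst)
    }
    if (config$n_correlated_pairs > 0) {
      src <- sample(back_idx, config$n_correlated_pairs, replace = TRUE)
      for (p in seq_len(config$n_correlated_pairs)) {
        flip <- rbinom(n, 1, config$flip_p)
        j <- j + 1L; cols[[j]] <- abs(cols[[src[p]]] - flip)
        nm[j] <- sprintf("DUP%03d_%s", p, nm[src[p]])
      }
    }
    fp <- do.call(cbind, cols)
    storage.mode(fp) <- "double"
    dimnames(fp) <- list(ids, nm)
    validate_fingerprint_matrix(fp)
    pic50 <- generate_activity_values(cls)
    activity <- label_activity(data.frame(
      compound_id = ids, pic50 = pic50, stringsAsFactors = FALSE))
    stopifnot(identical(as.character(activity$potency_class), as.character(cls)))
    list(fingerprints = fp, activity = activity)
  })
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  pmin(pmax(qnorm(u, mean, sd), lo), hi)
}

#' Generate pIC50 values consistent with given potency classes
#'
#' Potent compounds are drawn from a normal (mean 6.9, sd 0.5) truncated to
#' `[cutoff, 8.5]`, non-potent from a normal (mean 5.4, sd 0.5) truncated
#' to `[4.5, cutoff)`, emulating an activity distribution with modes near
#' 6 and 7 over the range 4.5-8.5. Truncation guarantees that
#' [assign_class()] on the output reproduces the input classes exactly.
#'
#' @param classes factor/character vector of `"P"`/`"N"` labels.
#' @param seed optional integer seed.
#' @param cutoff potency boundary on the pIC50 scale.
#' @return numeric vector of pIC50 values, aligned with `classes`.
#' @export
generate_activity_values <- function(classes, seed = NULL, cutoff = 6.0) {
  with_seed(seed, {
    n <- length(classes)
    out <- numeric(n)
    isP <- as.character(classes) == "P"
    out[isP] <- rtrunc_norm(sum(isP), 6.9, 0.5, cutoff, 8.5)
    out[!isP] <- rtrunc_norm(sum(!isP), 5.4, 0.5, 4.5, cutoff)
    # the non-potent interval is open at the cutoff
    out[!isP & out >= cutoff] <- cutoff - 1e-9
    out
  })
}

#' Generate a molecular-descriptor table with planted screening defects
#'
#' Produces a numeric descriptor table whose defects are known by
#' construction: exactly `n_nearly_constant` columns in which more than
#' 80% of rows share one value, and exactly `n_high_corr_pairs` column
#' pairs with |Pearson r| > 0.95 (a duplicate plus small noise). All other
#' columns are independent standard normals.
#'
#' @param n_rows number of compounds.
#' @param n_descriptors total number of descriptor columns.
#' @param n_nearly_constant number of near-constant columns to plant.
#' @param n_high_corr_pairs number of highly correlated pairs to plant.
#' @param seed optional integer seed.
#' @return data frame of descriptors with compound ids as row names.
#' @export
generate_descriptor_table <- function(n_rows, n_descriptors,
                                      n_nearly_constant = 0,
                                      n_high_corr_pairs = 0, seed = NULL) {
  n_planted <- n_nearly_constant + 2 * n_high_corr_pairs
  if (n_planted > n_descriptors)
    stop("planted columns exceed n_descriptors", call. = FALSE)
  if (n_high_corr_pairs > 0 && n_descriptors - n_nearly_constant - n_high_corr_pairs < 1)
    stop("high-correlation pairs need a source column", call. = FALSE)
  with_seed(seed, {
    n_back <- n_descriptors - n_nearly_constant - n_high_corr_pairs
    tab <- matrix(stats::rnorm(n_rows * n_back), n_rows, n_back)
    colnames(tab) <- sprintf("D%03d", seq_len(n_back))
    if (n_nearly_constant > 0) {
      nc <- sapply(seq_len(n_nearly_constant), function(i) {
        col <- stats::rnorm(n_rows)
        keep <- sample(n_rows, ceiling(0.85 * n_rows))
        col[keep] <- 1
        col
      })
      colnames(nc) <- sprintf("NC%03d", seq_len(n_nearly_constant))
      tab <- cbind(tab, nc)
    }
    if (n_high_corr_pairs > 0) {
      src <- sample(n_back, n_high_corr_pairs, replace = TRUE)
      hc <- sapply(seq_len(n_high_corr_pairs), function(i)
        tab[, src[i]] + stats::rnorm(n_rows, sd = 0.05))
      colnames(hc) <- sprintf("HC%03d_D%03d", seq_len(n_high_corr_pairs), src)
      tab <- cbind(tab, hc)
    }
    out <- as.data.frame(tab)
    rownames(out) <- sprintf("cmpd_%03d", seq_len(n_rows))
    out
  })
}
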