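euclid_to_all <- function(matrix, i) {
  d2 <- rowSums(sweep(matrix, 2, matrix[i, ], "-")^2)
  sqrt(pmax(d2, 0))
}

#' Nearest neighbors of one row by Euclidean distance
#'
#' Distances are Euclidean on the raw feature values (for 0/1 fingerprint
#' bits this is the square root of the Hamming distance). The query row is
#' excluded; ties are broken toward the lower row index, which makes every
#' neighbor query deterministic.
#'
#' @param matrix numeric feature matrix.
#' @param index row index of the query point.
#' @param k number of neighbors to return.
#' @param restrict_to optional logical/index vector of eligible rows.
#' @return integer vector of `k` row indices, closest first.
#' @export
nearest_neighbors <- function(matrix, index, k, restrict_to = NULL) {
  n <- nrow(matrix)
  eligible <- setdiff(
    if (is.null(restrict_to)) seq_len(n) else seq_len(n)[restrict_to], index)
  if (k < 1 || k > length(eligible))
    stop("k = ", k, " but only ", length(eligible),
         " eligible rows besides the query", call. = FALSE)
  d <- euclid_to_all(matrix, index)[eligible]
  eligible[order(d, eligible)][seq_len(k)]
}

#' SMOTE oversampling of a minority class
#'
#' Each synthetic row interpolates between a randomly chosen minority row
#' `x_i` and a random one of its `k` minority-class nearest neighbors
#' `x_nn`: `x_new = x_i + u * (x_nn - x_i)` with `u ~ Uniform(0, 1)`. For
#' binary fingerprints the interpolated row is then binarized at 0.5 (ties
#' to 1), which keeps synthetic fingerprints semantically valid bit
#' vectors; set `binarize = FALSE` for continuous features.
#'
#' @param minority feature matrix of minority-class rows (at least 2).
#' @param target_count number of synthetic rows to create.
#' @param k neighborhood size (capped at `nrow(minority) - 1`).
#' @param seed optional integer seed.
#' @param binarize binarize synthetic rows at 0.5 (default `TRUE`).
#' @return matrix of `target_count` synthetic rows with an integer
#'   `parents` attribute (columns `i`, `nn`: the two parent row indices).
#' @export
smote_oversample <- function(minority, target_count, k = 5, seed = NULL,
                             binarize = TRUE) {
  if (!is.matrix(minority)) minority <- as.matrix(minority)
  m <- nrow(minority)
  if (m < 2)
    stop("SMOTE needs at least 2 minority rows to interpolate", call. = FALSE)
  if (target_count < 0) stop("`target_count` must be >= 0", call. = FALSE)
  k <- min(k, m - 1)
  with_seed(seed, {
    out <- matrix(0, target_count, ncol(minority),
                  dimnames = list(NULL, colnames(minority)))
    parents <- matrix(0L, target_count, 2, dimnames = list(NULL, c("i", "nn")))
    for (s in seq_len(target_count)) {
      i <- sample.int(m, 1)
      nn <- nearest_neighbors(minority, i, k)[sample.int(k, 1)]
      u <- runif(1)
      out[s, ] <- minority[i, ] + u * (minority[nn, ] - minority[i, ])
      parents[s, ] <- c(i, nn)
    }
    if (binarize) out <- (out >= 0.5) * 1
    rownames(out) <- sprintf("syn_%03d", seq_len(target_count))
    attr(out, "parents") <- parents
    out
  })
}

#' Find Tomek links
#'
#' A Tomek link is an unordered pair of samples from different classes
#' that are each other's nearest neighbor over the whole dataset. Because
#' nearest neighbors are tie-broken deterministically, every sample
#' belongs to at most one link and the output is deterministic.
#'
#' @param matrix numeric feature matrix.
#' @param labels class labels aligned with rows.
#' @return integer matrix with columns `a`, `b` (`a < b`), ordered by `a`;
#'   zero rows when no links (or only one class) exist.
#' @export
find_tomek_links <- function(matrix, labels) {
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  if (length(labels) != n)
    stop("`labels` length must match row count", call. = FALSE)
  labels <- as.character(labels)
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("a", "b")))
  if (length(unique(labels)) < 2 || n < 2) return(empty)
  nn1 <- vapply(seq_len(n), function(i) nearest_neighbors(matrix, i, 1), integer(1))
  links <- list()
  for (a in seq_len(n)) {
    b <- nn1[a]
    if (a < b && nn1[b] == a && labels[a] != labels[b])
      links[[length(links) + 1L]] <- c(a, b)
  }
  if (length(links) == 0) return(empty)
  out <- do.call(rbind, links)
  colnames(out) <- c("a", "b")
  out[order(out[, 1]), , drop = FALSE]
}

#' SMOTE + Tomek-link hybrid balancing
#'
#' Oversamples the minority class with SMOTE up to the majority count,
#' then detects Tomek links in the combined set and removes the linked
#' samples. The default policy removes both members of every link (each
#' link holds one sample per class, so class counts stay balanced);
#' `policy = "majority-only"` removes only the majority-class member.
#' Balancing is meant for the training set only; held-out sets should be
#' left untouched.
#'
#' @param matrix feature matrix of the training set.
#' @param labels binary class labels aligned with rows.
#' @param seed optional integer seed (neighbor and interpolation draws).
#' @param k SMOTE neighborhood size.
#' @param policy `"both"` (default) or `"majority-only"`.
#' @param binarize passed to [smote_oversample()].
#' @return an object of class `resampling_result`: list with `matrix`,
#'   `labels`, per-row `provenance` (`"original"`/`"synthetic"`), and
#'   `removed_ids` (row names removed as Tomek-link members).
#' @export
smote_tomek <- function(matrix, labels, seed = NULL, k = 5,
                        policy = c("both", "majority-only"), binarize = TRUE) {
  policy <- match.arg(policy)
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  labels <- as.character(labels)
  if (length(labels) != nrow(matrix))
    stop("`labels` length must match row count", call. = FALSE)
  tab <- table(labels)
  if (length(tab) != 2)
    stop("smote_tomek needs exactly two classes present", call. = FALSE)
  if (is.null(rownames(matrix)))
    rownames(matrix) <- sprintf("row_%03d", seq_len(nrow(matrix)))
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  deficit <- as.integer(tab[majority] - tab[minority])
  syn <- smote_oversample(matrix[labels == minority, , drop = FALSE],
                          deficit, k = k, seed = seed, binarize = binarize)
  full <- rbind(matrix, syn)
  full_labels <- c(labels, rep(minority, deficit))
  provenance <- c(rep("original", nrow(matrix)), rep("synthetic", deficit))
  links <- find_tomek_links(full, full_labels)
  linked <- unique(as.vector(links))
  drop_idx <- if (policy == "both") linked else
    linked[full_labels[linked] == majority]
  keep <- setdiff(seq_len(nrow(full)), drop_idx)
  structure(list(
    matrix = full[keep, , drop = FALSE],
    labels = full_labels[keep],
    provenance = provenance[keep],
    removed_ids = rownames(full)[drop_idx]
  ), class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat("SMOTE+Tomek resampling result:", nrow(x$matrix), "rows\n")
  print(table(class = x$labels, provenance = x$provenance))
  cat("removed as Tomek-link members:", length(x$removed_ids), "\n")
  invisible(x)
}
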