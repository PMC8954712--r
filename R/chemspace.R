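#' Pairwise Euclidean distance matrix of fingerprints
#'
#' Chemical-diversity characterization: the full symmetric matrix of
#' pairwise Euclidean distances between compound fingerprints, optionally
#' normalized by the maximum distance to a \[0, 1\] color scale for heat
#' maps.
#'
#' @param fp fingerprint (or any numeric feature) matrix, >= 2 rows.
#' @param normalize scale by the maximum distance (default `TRUE`).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_heat_matrix <- function(fp, normalize = TRUE) {
  if (!is.matrix(fp)) fp <- as.matrix(fp)
  if (nrow(fp) < 2)
    stop("need at least two compounds for a distance matrix", call. = FALSE)
  d <- as.matrix(dist(fp, method = "euclidean"))
  if (normalize && max(d) > 0) d <- d / max(d)
  d
}

#' Screen descriptors for near-constancy and inter-correlation
#'
#' Standard QSAR descriptor pre-screening: first drop every descriptor
#' whose modal value is shared by more than `constant_fraction` of
#' compounds (constant and nearly constant variance), then walk the
#' remaining descriptors in column order and drop the later member of
#' every pair with |Pearson r| > `corr_cutoff` (keep-first-listed, so the
#' outcome is deterministic and row-order invariant).
#'
#' @param table numeric descriptor data frame or matrix (>= 3 rows).
#' @param constant_fraction modal-frequency threshold (strictly greater
#'   removes; default 0.80).
#' @param corr_cutoff absolute-correlation threshold (strictly greater
#'   removes; default 0.95).
#' @return object of class `screen_report`: list with `removed_constant`,
#'   `removed_correlated`, `retained` name vectors.
#' @export
screen_descriptors <- function(table, constant_fraction = 0.80,
                               corr_cutoff = 0.95) {
  tab <- as.data.frame(table)
  if (nrow(tab) < 3) stop("need at least 3 compounds to screen", call. = FALSE)
  nms <- names(tab)
  modal_frac <- vapply(tab, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0) return(1)
    max(table(col)) / nrow(tab)
  }, numeric(1))
  removed_constant <- nms[modal_frac > constant_fraction]
  left <- setdiff(nms, removed_constant)
  removed_correlated <- character(0)
  if (length(left) > 1) {
    cm <- suppressWarnings(abs(cor(tab[left], use = "pairwise.complete.obs")))
    cm[is.na(cm)] <- 0
    alive <- rep(TRUE, length(left))
    for (i in seq_along(left)) {
      if (!alive[i]) next
      for (j in seq_along(left)) {
        if (j <= i || !alive[j]) next
        if (cm[i, j] > corr_cutoff) alive[j] <- FALSE
      }
    }
    removed_correlated <- left[!alive]
  }
  retained <- setdiff(left, removed_correlated)
  if (length(retained) == 0)
    warning("descriptor screen removed every descriptor", call. = FALSE)
  structure(list(removed_constant = removed_constant,
                 removed_correlated = removed_correlated,
                 retained = retained),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("descriptor screen:", length(x$removed_constant), "near-constant and",
      length(x$removed_correlated), "inter-correlated removed;",
      length(x$retained), "retained\n")
  invisible(x)
}

#' Principal-component projection of a descriptor table
#'
#' Centers and unit-variance scales the descriptors (their units are
#' heterogeneous) and projects onto principal components, for
#' chemical-space visualization.
#'
#' @param table numeric descriptor data frame or matrix (screened first:
#'   constant columns are an error).
#' @param n_components number of leading components to return (default 3).
#' @return list with `coordinates` (rows x `n_components` scores),
#'   `explained` (variance fractions of the returned components),
#'   `explained_all` (all fractions, non-increasing, summing to 1),
#'   and `rotation` (full loading matrix).
#' @export
project_descriptors <- function(table, n_components = 3) {
  tab <- as.matrix(as.data.frame(table))
  if (nrow(tab) <= n_components)
    stop("need more compounds than components", call. = FALSE)
  sds <- apply(tab, 2, sd)
  if (any(sds == 0))
    stop("constant descriptor column(s): ",
         paste(colnames(tab)[sds == 0], collapse = ", "),
         " (screen descriptors first)", call. = FALSE)
  pc <- prcomp(tab, center = TRUE, scale. = TRUE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  list(coordinates = pc$x[, seq_len(k), drop = FALSE],
       explained = frac[seq_len(k)],
       explained_all = frac,
       rotation = pc$rotation,
       center = pc$center, scale = pc$scale)
}

#' Lipinski rule-of-five profile
#'
#' Extracts the five drug-likeness descriptors (molecular weight, logP,
#' hydrogen-bond donors and acceptors, rotatable bonds) per compound and
#' summarizes them (min / median / max) for radar-chart rendering.
#'
#' @param table descriptor data frame containing columns `MW`, `logP`,
#'   `HBD`, `HBA`, `RotB`.
#' @return list with `per_compound` (data frame of the five columns) and
#'   `summary` (rows min/median/max).
#' @export
lipinski_profile <- function(table) {
  tab <- as.data.frame(table)
  needed <- c("MW", "logP", "HBD", "HBA", "RotB")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0)
    stop("missing Lipinski column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0) stop("empty descriptor table", call. = FALSE)
  per <- tab[needed]
  summ <- t(vapply(per, function(col)
    c(min = min(col), median = median(col), max = max(col)), numeric(3)))
  list(per_compound = per, summary = as.data.frame(summ))
}
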