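#' Convert a micromolar IC50 to pIC50
#'
#' pIC50 is the negative decadic logarithm of the molar IC50, so for an
#' IC50 given in micromolar units `pIC50 = 6 - log10(IC50_uM)`; 1 uM maps
#' to pIC50 6.0, the conventional potency boundary for kinase inhibitors.
#'
#' @param ic50_uM numeric vector of positive IC50 values in micromolar.
#' @return numeric vector of pIC50 values.
#' @examples
#' pic50_from_ic50(1)      # 6.0
#' pic50_from_ic50(0.056)  # 7.252
#' @export
pic50_from_ic50 <- function(ic50_uM) {
  if (!is.numeric(ic50_uM)) stop("`ic50_uM` must be numeric", call. = FALSE)
  if (any(!is.finite(ic50_uM)) || any(ic50_uM <= 0))
    stop("`ic50_uM` must be finite and strictly positive", call. = FALSE)
  6 - log10(ic50_uM)
}

#' Convert a pIC50 back to a micromolar IC50
#'
#' @param pic50 numeric vector of pIC50 values.
#' @return numeric vector of IC50 values in micromolar.
#' @export
ic50_from_pic50 <- function(pic50) {
  if (!is.numeric(pic50) || any(!is.finite(pic50)))
    stop("`pic50` must be finite numeric", call. = FALSE)
  10^(6 - pic50)
}

#' Assign the potent / non-potent class from pIC50
#'
#' Compounds at or above the cutoff are labeled potent (`"P"`), below it
#' non-potent (`"N"`). The boundary itself counts as potent, so an IC50 of
#' exactly 1 uM (pIC50 6.0, the default cutoff) is the last potent value.
#'
#' @param pic50 numeric vector of pIC50 values.
#' @param cutoff potency boundary on the pIC50 scale (default 6.0 = 1 uM).
#' @return factor with levels `c("P", "N")`.
#' @export
assign_class <- function(pic50, cutoff = 6.0) {
  if (!is.numeric(pic50) || any(is.na(pic50)) || any(!is.finite(pic50)))
    stop("`pic50` must be finite numeric with no missing values", call. = FALSE)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff))
    stop("`cutoff` must be a single finite number", call. = FALSE)
  factor(ifelse(pic50 >= cutoff, "P", "N"), levels = c("P", "N"))
}

#' Label an activity table with pIC50 and potency class
#'
#' Fills the missing one of `ic50_uM` / `pic50` (at least one must be
#' present per compound; when both are present they must agree) and derives
#' `potency_class` at the given cutoff.
#'
#' @param records data frame with column `compound_id` and at least one of
#'   `ic50_uM`, `pic50`; an optional `smiles` column is carried through.
#' @param cutoff potency boundary on the pIC50 scale.
#' @return the input data frame with complete `ic50_uM`, `pic50` and
#'   `potency_class` columns.
#' @export
label_activity <- function(records, cutoff = 6.0) {
  if (!is.data.frame(records) || !"compound_id" %in% names(records))
    stop("`records` must be a data frame with a `compound_id` column", call. = FALSE)
  if (anyDuplicated(records$compound_id))
    stop("duplicate compound_id in activity table", call. = FALSE)
  has_ic <- "ic50_uM" %in% names(records)
  has_p <- "pic50" %in% names(records)
  if (!has_ic && !has_p)
    stop("activity table needs an `ic50_uM` or `pic50` column", call. = FALSE)
  if (!has_ic) records$ic50_uM <- NA_real_
  if (!has_p) records$pic50 <- NA_real_
  both_na <- is.na(records$ic50_uM) & is.na(records$pic50)
  if (any(both_na))
    stop("compounds with neither ic50_uM nor pic50: ",
         paste(records$compound_id[both_na], collapse = ", "), call. = FALSE)
  both <- !is.na(records$ic50_uM) & !is.na(records$pic50)
  if (any(both)) {
    diff <- abs(records$pic50[both] - pic50_from_ic50(records$ic50_uM[both]))
    if (any(diff > 1e-9))
      stop("inconsistent ic50_uM / pic50 pair for: ",
           paste(records$compound_id[both][diff > 1e-9], collapse = ", "),
           call. = FALSE)
  }
  fill_p <- is.na(records$pic50)
  records$pic50[fill_p] <- pic50_from_ic50(records$ic50_uM[fill_p])
  fill_ic <- is.na(records$ic50_uM)
  records$ic50_uM[fill_ic] <- ic50_from_pic50(records$pic50[fill_ic])
  records$potency_class <- assign_class(records$pic50, cutoff)
  records
}

#' Read an activity table from CSV
#'
#' Expects columns `compound_id` (or `id`/`Name` as synonyms), optionally
#' `smiles`, and at least one of `ic50_uM` / `pic50`.
#'
#' @param path CSV file path.
#' @param cutoff potency boundary passed to [label_activity()].
#' @return labeled activity data frame.
#' @export
load_activity_table <- function(path, cutoff = 6.0) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  id_col <- intersect(c("compound_id", "id", "Name"), names(tab))[1]
  if (is.na(id_col)) stop("no compound id column in ", path, call. = FALSE)
  names(tab)[names(tab) == id_col] <- "compound_id"
  tab$compound_id <- as.character(tab$compound_id)
  label_activity(tab, cutoff)
}

#' Write an activity table to CSV
#'
#' @param records labeled activity data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

parse_ratio <- function(ratio) {
  if (is.character(ratio)) {
    parts <- suppressWarnings(as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]]))
    if (length(parts) != 2L || any(is.na(parts)) || any(parts < 0) || sum(parts) == 0)
      stop("`ratio` string must look like \"3:1\"", call. = FALSE)
    return(parts[1] / sum(parts))
  }
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) || ratio < 0)
    stop("`ratio` must be a train:test odds number or a \"3:1\" string", call. = FALSE)
  if (is.infinite(ratio)) return(1)
  ratio / (ratio + 1)
}

round_half_up_int <- function(x) floor(x + 0.5 + 1e-9)

# Largest-remainder apportionment of `total` among classes proportional to
# `sizes`, capped at the class sizes.
apportion <- function(sizes, total) {
  quota <- sizes * total / sum(sizes)
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  over <- base > sizes
  if (any(over)) {
    spill <- sum(base[over] - sizes[over])
    base[over] <- sizes[over]
    room <- which(base < sizes)
    for (i in room) {
      give <- min(spill, sizes[i] - base[i]); base[i] <- base[i] + give
      spill <- spill - give
      if (spill == 0) break
    }
  }
  base
}

#' Stratified train/test split of labeled compounds
#'
#' Splits compounds into a training and a test set at the requested
#' train:test ratio, preserving class proportions. The training size per
#' class is apportioned by largest remainder, so per-class proportions are
#' within one compound of the whole. When the realized design of a
#' published dataset must be matched size-for-size (a published split need
#' not be exactly proportional), per-class training counts can be imposed
#' via `train_counts`.
#'
#' @param records labeled activity data frame (columns `compound_id`,
#'   `potency_class`).
#' @param ratio train:test ratio as a number (`3` = 3:1) or string `"3:1"`;
#'   `"1:0"` puts everything in the training set.
#' @param seed integer seed controlling which compounds land in which part;
#'   the same seed always yields the same split.
#' @param train_counts optional named integer vector (names = class levels)
#'   of per-class training-set sizes, overriding proportional apportionment.
#' @return an object of class `dataset_split`: list with `train_ids`,
#'   `test_ids`, `stratification_ratio` and a `counts` table.
#' @export
stratified_split <- function(records, ratio = 3, seed = NULL, train_counts = NULL) {
  if (!is.data.frame(records) ||
      !all(c("compound_id", "potency_class") %in% names(records)))
    stop("`records` needs columns compound_id and potency_class", call. = FALSE)
  frac <- parse_ratio(ratio)
  cls <- as.factor(records$potency_class)
  sizes <- table(cls)
  if (any(sizes < 2))
    stop("refusing to stratify: class(es) with fewer than 2 members: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  n <- nrow(records)
  n_train <- round_half_up_int(n * frac)
  if (is.null(train_counts)) {
    per_class <- apportion(as.numeric(sizes), n_train)
    names(per_class) <- names(sizes)
  } else {
    if (!all(names(sizes) %in% names(train_counts)))
      stop("`train_counts` must name every class", call. = FALSE)
    per_class <- train_counts[names(sizes)]
    if (any(per_class < 0) || any(per_class > sizes))
      stop("`train_counts` exceed class sizes", call. = FALSE)
  }
  train_ids <- with_seed(seed, {
    unlist(lapply(names(sizes), function(cl) {
      ids <- records$compound_id[cls == cl]
      sample(ids, per_class[[cl]])
    }), use.names = FALSE)
  })
  test_ids <- setdiff(records$compound_id, train_ids)
  counts <- rbind(
    train = table(cls[match(train_ids, records$compound_id)]),
    test = table(cls[match(test_ids, records$compound_id)])
  )
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 stratification_ratio = frac, counts = counts),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("Stratified split (train fraction ",
      formatC(x$stratification_ratio, digits = 3, format = "g"), ")\n", sep = "")
  print(x$counts)
  invisible(x)
}
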