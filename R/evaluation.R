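#' Confusion counts for one positive class
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @param positive_label Name of the positive class (tumor, conventionally).
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, fn, tn, positive_label = "tumor") {
  for (v in list(tp = tp, fp = fp, fn = fn, tn = tn)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != floor(v))
      stop_invalid("confusion counts must be non-negative integers")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 positive_label = assert_string(positive_label,
                                                "positive_label")),
            class = "confusion_counts")
}

guarded_rate <- function(num, den) {
  if (den == 0) return(structure(0, degenerate = TRUE))
  structure(100 * num / den, degenerate = FALSE)
}

#' Precision (positive predictive value), percent
#'
#' `100 * tp / (tp + fp)`; when the denominator is zero the value is 0 and
#' the result carries a `degenerate = TRUE` attribute.
#'
#' @param c A [confusion_counts()].
#' @return Percent in \[0, 100\] with attribute `degenerate`.
#' @export
precision <- function(c) {
  if (!inherits(c, "confusion_counts"))
    stop_invalid("`c` must be confusion_counts")
  guarded_rate(c$tp, c$tp + c$fp)
}

#' Sensitivity (recall), percent
#'
#' `100 * tp / (tp + fn)`, guarded like [precision()].
#'
#' @param c A [confusion_counts()].
#' @return Percent in \[0, 100\] with attribute `degenerate`.
#' @export
sensitivity <- function(c) {
  if (!inherits(c, "confusion_counts"))
    stop_invalid("`c` must be confusion_counts")
  guarded_rate(c$tp, c$tp + c$fn)
}

#' F1 score from precision and sensitivity, percent
#'
#' Harmonic mean `2ps / (p + s)`; 0 when both inputs are 0.
#'
#' @param p,s Precision and sensitivity on the percent scale.
#' @return Percent in \[0, 100\].
#' @export
f1 <- function(p, s) {
  assert_scalar_number(p, "p"); assert_scalar_number(s, "s")
  if (p < 0 || p > 100 || s < 0 || s > 100)
    stop_invalid("precision and sensitivity must be on the percent scale")
  if (p + s == 0) return(0)
  2 * p * s / (p + s)
}

#' Grouped k-fold split
#'
#' Groups (slides) are shuffled by seed and partitioned into k folds as
#' evenly as possible. Tiles follow their group, so no group ever spans a
#' training/validation boundary.
#'
#' @param group_ids Character/integer vector of group memberships, one per
#'   item (or just the unique group ids).
#' @param k Number of folds; at most the number of distinct groups.
#' @param seed RNG seed for the shuffle.
#' @return A `fold_split`: named integer vector `assignments` mapping each
#'   group to a fold in `1..k`, plus `k`.
#' @export
kfold_by_group <- function(group_ids, k, seed = 1L) {
  groups <- sort_labels(unique(as.character(group_ids)))
  k <- assert_count(k, "k", min = 2L)
  if (k > length(groups))
    stop_invalid("k = %d exceeds the number of groups (%d)", k,
                 length(groups))
  shuffled <- with_rng(seed, sample(groups))
  sizes <- rep(length(groups) %/% k, k)
  extra <- length(groups) %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- rep(seq_len(k), times = sizes)
  assignments <- stats::setNames(fold[match(groups, shuffled)], groups)
  structure(list(assignments = assignments, k = k), class = "fold_split")
}

#' Fold of each item, by its group
#' @param split A [kfold_by_group()] result.
#' @param group_ids Group id per item.
#' @return Integer fold per item.
#' @export
fold_of <- function(split, group_ids) {
  if (!inherits(split, "fold_split")) stop_invalid("`split` must be a fold_split")
  unname(split$assignments[as.character(group_ids)])
}

#' Subsample a minority class to a fixed fraction of the majority
#'
#' Draws `floor(ratio * majority_count)` items uniformly without
#' replacement (seeded), emulating extreme class imbalance such as 1 tumor
#' tile per 10 non-tumor tiles.
#'
#' @param minority_tiles List (or vector) of minority-class items.
#' @param majority_count Size of the majority class.
#' @param ratio Target minority/majority ratio in (0, 1].
#' @param seed RNG seed.
#' @return The subsampled collection, in original relative order.
#' @export
resample_imbalance <- function(minority_tiles, majority_count, ratio,
                               seed = 1L) {
  majority_count <- assert_count(majority_count, "majority_count", min = 0L)
  assert_scalar_number(ratio, "ratio")
  if (ratio <= 0 || ratio > 1) stop_invalid("`ratio` must be in (0, 1]")
  m <- floor(ratio * majority_count)
  n <- length(minority_tiles)
  if (m > n)
    stop_invalid("requested %d tiles but only %d are available", m, n)
  keep <- with_rng(seed, sort(sample.int(n, m)))
  minority_tiles[keep]
}

#' Evaluate per-fold registries on labeled validation tiles
#'
#' Classifies every tile of each fold with that fold's registry, builds a
#' one-vs-rest confusion table for the positive class, and reports per-fold
#' and aggregate precision, sensitivity and F1 on the percent scale
#' (two-decimal rounding in the table; aggregate mean, sample SD (n-1),
#' and median).
#'
#' @param registries List of one trained [model_registry()] per fold.
#' @param fold_tiles List (same length) of labeled tile lists.
#' @param metric Dissimilarity metric for classification.
#' @param positive_label Positive class; defaults to a registry label
#'   starting with "tumor", else the lexicographically first label.
#' @return An `evaluation_report`: `per_fold` data frame, `aggregate`
#'   list, `positive_label`, `metric`.
#' @export
evaluate_folds <- function(registries, fold_tiles, metric = "mse",
                           positive_label = NULL) {
  if (!is.list(registries) || !is.list(fold_tiles) ||
      length(registries) != length(fold_tiles))
    stop_invalid("`registries` and `fold_tiles` must be lists of equal length")
  labels <- registry_labels(registries[[1]])
  if (is.null(positive_label)) {
    hit <- grep("^tumor", labels, value = TRUE)
    positive_label <- if (length(hit)) hit[1] else labels[1]
  }
  per_fold <- lapply(seq_along(registries), function(fi) {
    reg <- registries[[fi]]
    tiles <- fold_tiles[[fi]]
    truth <- vapply(tiles, function(t) tile_label(t) %||% NA_character_, "")
    pred <- vapply(tiles, function(t)
      classify_tile(reg, t, metric = metric)$predicted_label, "")
    tp <- sum(pred == positive_label & truth == positive_label)
    fp <- sum(pred == positive_label & truth != positive_label)
    fn <- sum(pred != positive_label & truth == positive_label)
    tn <- sum(pred != positive_label & truth != positive_label)
    cc <- confusion_counts(tp, fp, fn, tn, positive_label)
    p <- as.numeric(precision(cc)); s <- as.numeric(sensitivity(cc))
    data.frame(fold = fi, n = length(tiles), tp = tp, fp = fp, fn = fn,
               tn = tn, precision = round(p, 2), sensitivity = round(s, 2),
               f1 = round(f1(p, s), 2))
  })
  per_fold <- do.call(rbind, per_fold)
  agg <- function(x) list(mean = round(mean(x), 2),
                          sd = round(stats::sd(x), 2),
                          median = round(stats::median(x), 2))
  structure(list(per_fold = per_fold,
                 aggregate = list(precision = agg(per_fold$precision),
                                  sensitivity = agg(per_fold$sensitivity),
                                  f1 = agg(per_fold$f1)),
                 positive_label = positive_label,
                 metric = metric,
                 sd_definition = "sample (n-1)"),
            class = "evaluation_report")
}
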