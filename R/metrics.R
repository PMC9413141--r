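#' Pixelwise confusion counts between two binary masks
#'
#' Counts true/false positives and negatives of a predicted nodule mask
#' against a reference mask. The positive class is the nodule (value 1).
#'
#' @param pred_mask,true_mask binary matrices (entries exactly 0 or 1) of
#'   identical dimensions.
#' @return An object of class `confusion_counts`: a list with integer fields
#'   `tp`, `fp`, `fn`, `tn` summing to the number of pixels.
#' @examples
#' p <- matrix(c(1, 1, 0, 0), 2, 2)
#' confusion_counts(p, p)  # fp = fn = 0
#' @seealso [compute_metrics()]
#' @export
confusion_counts <- function(pred_mask, true_mask) {
  if (!identical(dim(pred_mask), dim(true_mask)))
    stop_dim("pred_mask and true_mask must have identical dimensions")
  if (!all(pred_mask %in% c(0, 1)) || !all(true_mask %in% c(0, 1)))
    stop_valid("masks must contain only 0 and 1")
  p <- pred_mask == 1; t <- true_mask == 1
  out <- list(tp = sum(p & t), fp = sum(p & !t),
              fn = sum(!p & t), tn = sum(!p & !t))
  structure(out, class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' Computes the seven standard segmentation scores: Dice, pixel accuracy
#' (PA) and Jaccard as percentages, and precision, recall, false-positive
#' rate (FPR) and false-negative rate (FNR) as fractions. A metric whose
#' denominator is zero (e.g. precision when nothing was predicted positive)
#' is reported as `NaN` rather than raising an error, and is excluded from
#' per-image means by [aggregate_metrics()].
#'
#' @param counts a `confusion_counts` object, or a list with fields
#'   `tp`, `fp`, `fn`, `tn`.
#' @return An object of class `metrics_report`: a named list with fields
#'   `dice`, `pa`, `jaccard` (percent) and `precision`, `recall`, `fpr`,
#'   `fnr` (fractions).
#' @examples
#' m <- compute_metrics(list(tp = 6, fp = 2, fn = 2, tn = 90))
#' m$dice     # 75
#' m$pa       # 96
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  if (any(c(tp, fp, fn, tn) < 0)) stop_valid("counts must be non-negative")
  if (tp + fp + fn + tn == 0) stop_valid("no evaluated pixels")
  ratio <- function(num, den) if (den == 0) NaN else num / den
  structure(list(
    dice = 100 * ratio(2 * tp, 2 * tp + fp + fn),
    pa = 100 * ratio(tp + tn, tp + tn + fp + fn),
    jaccard = 100 * ratio(tp, tp + fp + fn),
    precision = ratio(tp, tp + fp),
    recall = ratio(tp, tp + fn),
    fpr = ratio(fp, fp + tn),
    fnr = ratio(fn, tp + fn)
  ), class = "metrics_report")
}

#' Aggregate metrics over a set of mask pairs
#'
#' Two conventions are supported: `"per-image-mean"` (default) scores each
#' image separately and averages the scores, excluding undefined (`NaN`)
#' entries; `"pooled"` sums the confusion counts over all images first and
#' scores once. The two differ whenever object sizes vary between images.
#'
#' @param pairs non-empty list; each element a list with binary matrices
#'   `pred` and `true`.
#' @param mode `"per-image-mean"` or `"pooled"`.
#' @return A `metrics_report` (see [compute_metrics()]).
#' @export
aggregate_metrics <- function(pairs, mode = c("per-image-mean", "pooled")) {
  mode <- match.arg(mode)
  if (length(pairs) == 0) stop_valid("empty sequence of mask pairs")
  counts <- lapply(pairs, function(p) confusion_counts(p$pred, p$true))
  if (mode == "pooled") {
    tot <- list(tp = sum(vapply(counts, `[[`, 0, "tp")),
                fp = sum(vapply(counts, `[[`, 0, "fp")),
                fn = sum(vapply(counts, `[[`, 0, "fn")),
                tn = sum(vapply(counts, `[[`, 0, "tn")))
    return(compute_metrics(tot))
  }
  reps <- lapply(counts, compute_metrics)
  out <- lapply(names(reps[[1]]), function(f) {
    v <- vapply(reps, `[[`, 0, f)
    mean(v[!is.nan(v)])
  })
  names(out) <- names(reps[[1]])
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Dice %.2f%%  PA %.2f%%  Jaccard %.2f%%\n", x$dice, x$pa, x$jaccard))
  cat(sprintf("precision %.4f  recall %.4f  FPR %.4f  FNR %.4f\n",
              x$precision, x$recall, x$fpr, x$fnr))
  invisible(x)
}

# per-image metrics table from lists of masks
metrics_table <- function(pred_masks, true_masks, ids = NULL) {
  if (is.null(ids)) ids <- seq_along(pred_masks)
  rows <- lapply(seq_along(pred_masks), function(i) {
    m <- compute_metrics(confusion_counts(pred_masks[[i]], true_masks[[i]]))
    data.frame(image_id = ids[i], dice = m$dice, pa = m$pa, jaccard = m$jaccard,
               precision = m$precision, recall = m$recall, fpr = m$fpr, fnr = m$fnr)
  })
  do.call(rbind, rows)
}

#' Write a per-image metrics table and a JSON summary
#'
#' @param tab data frame as produced by [evaluate()]'s `$per_image`.
#' @param csv_path,json_path output file paths; either may be `NULL` to skip.
#' @param summary a `metrics_report` to serialize as the JSON summary;
#'   defaults to the column means of `tab`.
#' @return Invisibly, the summary list.
#' @export
write_metrics_report <- function(tab, csv_path = NULL, json_path = NULL,
                                 summary = NULL) {
  if (is.null(summary)) {
    summary <- as.list(colMeans(tab[, -1, drop = FALSE], na.rm = TRUE))
  }
  if (!is.null(csv_path)) write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
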