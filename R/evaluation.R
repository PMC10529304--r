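# Voxel-wise comparison of an automatic mask against a reference (manual)
# mask. The reference labels play the role of classes (one per named
# specimen/node); predicted components are first attributed to the
# reference node they overlap most, then per-class confusion counts and the
# five metrics (precision, recall, Dice, Jaccard, accuracy) are computed
# over the full field of view, followed by micro / macro / weighted
# aggregation. True negatives are counted over the whole scanned volume,
# air included — this deliberately reproduces the inflated overall accuracy
# that class imbalance produces when the target volume is a tiny fraction
# of the field of view.

#' Voxel-wise confusion counts for one class
#'
#' @param pred,truth Logical (or 0/1) arrays/vectors of identical size.
#' @return A list of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("prediction and truth sizes differ", call. = FALSE)
  p <- as.logical(pred); t <- as.logical(truth)
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  structure(list(tp = tp, tn = length(p) - tp - fp - fn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' The five segmentation metrics from confusion counts
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN),
#' Dice = 2TP/(2TP+FP+FN), Jaccard = TP/(TP+FP+FN),
#' Accuracy = (TP+TN)/(TP+TN+FP+FN). Undefined quotients (0/0) are
#' reported as `NA`, never as 0.
#'
#' @param counts A `confusion_counts` (or list with tp/tn/fp/fn).
#' @return Named numeric vector `precision`, `recall`, `dice`, `jaccard`,
#'   `accuracy`.
#' @export
class_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  c(precision = safe_div(tp, tp + fp),
    recall    = safe_div(tp, tp + fn),
    dice      = safe_div(2 * tp, 2 * tp + fp + fn),
    jaccard   = safe_div(tp, tp + fp + fn),
    accuracy  = safe_div(tp + tn, tp + tn + fp + fn))
}

#' Dice coefficient from precision and recall, or from Jaccard
#'
#' Identities used throughout the report checks:
#' `dice = 2PR/(P+R)` and `dice = 2J/(1+J)`.
#'
#' @param precision,recall Per-class precision and recall.
#' @param jaccard Per-class Jaccard index.
#' @return Dice coefficient.
#' @export
dice_from_pr <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall),
         NA_real_)
}

#' @rdname dice_from_pr
#' @export
dice_from_jaccard <- function(jaccard) 2 * jaccard / (1 + jaccard)

#' Attribute predicted components to reference nodes
#'
#' Each predicted component is mapped to the reference label it overlaps
#' most (in voxels); ties go to the lower reference label; components with
#' no overlap map to `NA`.
#'
#' @param pred A [label_mask()] of predicted components.
#' @param truth A [label_mask()] of reference nodes, same geometry.
#' @return A data frame with columns `pred_label`, `truth_label` (`NA` =
#'   unmatched), `overlap` (voxels).
#' @export
match_components <- function(pred, truth) {
  if (!same_geometry(pred, truth))
    stop("prediction and reference geometries differ", call. = FALSE)
  plabs <- mask_labels(pred)
  if (length(plabs) == 0L)
    return(data.frame(pred_label = integer(), truth_label = integer(),
                      overlap = integer()))
  sel <- pred$labels != 0L
  pv <- pred$labels[sel]; tv <- truth$labels[sel]
  out <- data.frame(pred_label = plabs, truth_label = NA_integer_,
                    overlap = 0L)
  ov <- tv != 0L
  if (any(ov)) {
    tl <- sort(unique(tv[ov]))
    # numeric-sorted factor levels so a tie resolves to the LOWER truth label
    tab <- table(factor(pv[ov], levels = plabs),
                 factor(tv[ov], levels = tl))
    for (r in seq_len(nrow(tab))) {
      if (sum(tab[r, ]) == 0L) next
      best <- which.max(tab[r, ])  # which.max takes the first (lowest) tie
      out$truth_label[r] <- tl[best]
      out$overlap[r] <- as.integer(tab[r, best])
    }
  }
  out
}

#' Aggregate per-class metrics
#'
#' `macro` is the unweighted mean over classes; `weighted` is the
#' support-weighted mean (support = reference voxels per class); `micro`
#' recomputes the metrics from the pooled confusion counts.
#'
#' @param per_class Data frame with columns `precision`, `recall`, `dice`,
#'   `jaccard`, `accuracy`, `support`, and (for `micro`) `tp`, `tn`, `fp`,
#'   `fn`.
#' @param mode One of `"micro"`, `"macro"`, `"weighted"`.
#' @return Named numeric vector of the five metrics.
#' @export
aggregate_metrics <- function(per_class, mode = c("micro", "macro", "weighted")) {
  mode <- match.arg(mode)
  if (nrow(per_class) == 0L) stop("no classes to aggregate", call. = FALSE)
  cols <- c("precision", "recall", "dice", "jaccard", "accuracy")
  if (mode == "macro")
    return(colMeans(per_class[cols]))
  if (mode == "weighted") {
    w <- per_class$support / sum(per_class$support)
    return(vapply(cols, function(cl) sum(w * per_class[[cl]]), numeric(1)))
  }
  pooled <- list(tp = sum(per_class$tp), tn = sum(per_class$tn),
                 fp = sum(per_class$fp), fn = sum(per_class$fn))
  class_metrics(pooled)
}

#' Evaluate an automatic segmentation against a reference mask
#'
#' Predicted components are attributed to reference nodes by maximal
#' overlap ([match_components()]); each reference node then forms a class
#' whose prediction is the union of the components attributed to it, and
#' voxel-wise confusion counts and metrics are computed over the full
#' field of view. Predicted components with no reference overlap
#' contribute their voxels once as false positives to the pooled micro
#' counts (an `unmatched` pool), so spurious detections are not silently
#' ignored.
#'
#' @param pred A [label_mask()] of predicted node components.
#' @param truth A [label_mask()] of reference nodes, same geometry.
#' @return A list of class `metrics_report`: `per_class` (one row per
#'   reference label: counts, support, metrics), `aggregates` (rows
#'   micro/macro/weighted), `matching`, `unmatched_fp` (voxels).
#' @export
evaluate <- function(pred, truth) {
  if (!same_geometry(pred, truth))
    stop("prediction and reference geometries differ", call. = FALSE)
  tlabs <- mask_labels(truth)
  if (length(tlabs) == 0L)
    stop("reference mask has no labelled nodes", call. = FALSE)
  matching <- match_components(pred, truth)
  unmatched <- matching$pred_label[is.na(matching$truth_label)]
  unmatched_fp <- if (length(unmatched))
    sum(pred$labels %in% unmatched) else 0L

  rows <- lapply(tlabs, function(tl) {
    plabs <- matching$pred_label[!is.na(matching$truth_label) &
                                   matching$truth_label == tl]
    pbin <- pred$labels %in% plabs & pred$labels != 0L
    tbin <- truth$labels == tl
    cc <- confusion(pbin, tbin)
    data.frame(class = tl, support = sum(tbin),
               tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
               t(class_metrics(cc)))
  })
  per_class <- do.call(rbind, rows)

  micro_counts <- list(tp = sum(per_class$tp),
                       fp = sum(per_class$fp) + unmatched_fp,
                       fn = sum(per_class$fn), tn = 0)
  micro_counts$tn <- length(truth$labels) * length(tlabs) -
    micro_counts$tp - micro_counts$fp - micro_counts$fn
  aggregates <- rbind(
    micro = class_metrics(micro_counts),
    macro = aggregate_metrics(per_class, "macro"),
    weighted = aggregate_metrics(per_class, "weighted"))
  aggregates <- data.frame(average = rownames(aggregates), aggregates,
                           row.names = NULL)
  structure(list(per_class = per_class, aggregates = aggregates,
                 matching = matching, unmatched_fp = unmatched_fp),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat("Per-class (reference node) metrics:\n")
  pc <- x$per_class
  pc[c("precision", "recall", "dice", "jaccard", "accuracy")] <-
    lapply(pc[c("precision", "recall", "dice", "jaccard", "accuracy")],
           round_report, digits = 2)
  print(pc[c("class", "support", "precision", "recall", "dice", "jaccard",
             "accuracy")], row.names = FALSE)
  ag <- x$aggregates
  ag[-1] <- lapply(ag[-1], round_report, digits = 2)
  cat("Aggregates:\n")
  print(ag, row.names = FALSE)
  if (x$unmatched_fp > 0)
    cat(sprintf("Unmatched predicted voxels (pooled FP): %d\n", x$unmatched_fp))
  invisible(x)
}

#' Write a metrics report as CSV
#'
#' Per-class rows followed by micro/macro/weighted rows; metric columns
#' rounded to 2 decimals (half away from zero) for display, matching the
#' granularity of the tabular reports.
#'
#' @param report A `metrics_report` from [evaluate()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  cols <- c("precision", "recall", "dice", "jaccard", "accuracy")
  pc <- report$per_class
  top <- data.frame(row = as.character(pc$class), support = pc$support,
                    round_report(pc[cols], 2))
  ag <- report$aggregates
  bottom <- data.frame(row = ag$average, support = NA_integer_,
                       round_report(ag[cols], 2))
  write.csv(rbind(top, bottom), path, row.names = FALSE)
  invisible(path)
}
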