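## Clinical bookkeeping: confusion counts and the four derived metrics
## (sensitivity, specificity, PPV, NPV) at two scopes — inside the DDCRZ
## and on the whole data set, where step-1 non-members count as
## predicted-normal.

#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer cell counts (positive class =
#'   delayed).
#' @param scope `"in_zone"` or `"whole_dataset"`.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, tn, fn,
                             scope = c("in_zone", "whole_dataset")) {
  scope <- match.arg(scope)
  cnt <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(cnt >= 0), all(cnt == round(cnt)))
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn), scope = scope),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Round a proportion to a percentage with one decimal
#'
#' Half values round away from zero (76.923\% -> 76.9, 98.888\% -> 98.9),
#' matching clinical reporting conventions.
#'
#' @param p Proportion in `[0, 1]` (or `NA`).
#' @return Percentage rounded to one decimal place.
#' @export
as_percent <- function(p) {
  ifelse(is.na(p), NA_real_, sign(p) * floor(abs(p) * 1000 + 0.5) / 10)
}

metric_set <- function(counts) {
  list(sensitivity = safe_ratio(counts$tp, counts$tp + counts$fn),
       specificity = safe_ratio(counts$tn, counts$tn + counts$fp),
       ppv = safe_ratio(counts$tp, counts$tp + counts$fp),
       npv = safe_ratio(counts$tn, counts$tn + counts$fn))
}

#' Score predictions against labels
#'
#' @param predictions Predicted classes: 0/1 or `"normal"`/`"delayed"`.
#'   Subjects excluded from the analysis (`"excluded_incomplete"`) must be
#'   removed before calling; `score()` refuses them.
#' @param labels True 0/1 labels, aligned with `predictions`.
#' @param scope `"in_zone"` (predictions restricted to DDCRZ members) or
#'   `"whole_dataset"` (step-1 non-members already mapped to
#'   predicted-normal).
#' @return A `metric_report`: `counts` plus `sensitivity`, `specificity`,
#'   `ppv`, `npv` as proportions (`NA` when the denominator is zero — an
#'   undefined metric is never reported as 0 or 1 by fiat).
#' @examples
#' r <- score(c(1, 1, 0, 0), c(1, 0, 1, 0), "in_zone")
#' r$sensitivity
#' @export
score <- function(predictions, labels, scope = c("in_zone", "whole_dataset")) {
  scope <- match.arg(scope)
  if (is.character(predictions) || is.factor(predictions)) {
    predictions <- as.character(predictions)
    if (any(predictions == "excluded_incomplete"))
      stop("remove excluded_incomplete subjects before scoring")
    ok <- predictions %in% c("normal", "delayed")
    if (!all(ok)) stop("unknown prediction value: ",
                       predictions[!ok][1])
    predictions <- as.integer(predictions == "delayed")
  }
  stopifnot(length(predictions) == length(labels),
            all(predictions %in% c(0L, 1L)), all(labels %in% c(0L, 1L)))
  if (!length(predictions)) stop("empty scope: nothing to score")
  counts <- confusion_counts(tp = sum(predictions == 1 & labels == 1),
                             fp = sum(predictions == 1 & labels == 0),
                             tn = sum(predictions == 0 & labels == 0),
                             fn = sum(predictions == 0 & labels == 1),
                             scope = scope)
  report(counts)
}

#' Metric report from confusion counts
#'
#' @param counts A [confusion_counts()] object.
#' @return A `metric_report`.
#' @export
report <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  structure(c(list(counts = counts), metric_set(counts)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(p) if (is.na(p)) "n/a" else sprintf("%.1f%%", as_percent(p))
  with(x$counts, cat(sprintf(
    "Scope %s: TP %d, FP %d, TN %d, FN %d (n = %d)\n",
    scope, tp, fp, tn, fn, tp + fp + tn + fn)))
  cat("  sensitivity ", fmt(x$sensitivity),
      ", specificity ", fmt(x$specificity),
      ", PPV ", fmt(x$ppv), ", NPV ", fmt(x$npv), "\n", sep = "")
  invisible(x)
}

#' Whole-dataset counts from in-zone counts
#'
#' Step-1 non-members are classified normal, so delayed subjects missed by
#' the zone become false negatives and non-delayed subjects outside the
#' zone become true negatives.
#'
#' @param zone_counts In-zone [confusion_counts()].
#' @param missed_delayed Number of delayed subjects outside the DDCRZ.
#' @param outside_normals Number of non-delayed subjects outside the DDCRZ.
#' @return `confusion_counts` with scope `"whole_dataset"`.
#' @export
whole_from_zone <- function(zone_counts, missed_delayed, outside_normals) {
  stopifnot(inherits(zone_counts, "confusion_counts"),
            missed_delayed >= 0, outside_normals >= 0)
  confusion_counts(tp = zone_counts$tp, fp = zone_counts$fp,
                   tn = zone_counts$tn + outside_normals,
                   fn = zone_counts$fn + missed_delayed,
                   scope = "whole_dataset")
}

#' Evaluate a two-step prediction at both scopes
#'
#' @param predictions Output of [predict_two_step()].
#' @param labels True 0/1 labels aligned with `predictions`.
#' @param membership Zone membership per subject, as from
#'   [zone_membership_table()] (used to delimit the in-zone scope).
#' @return List with `in_zone` and `whole_dataset` metric reports and
#'   `n_excluded`.
#' @export
evaluate_two_step <- function(predictions, labels, membership) {
  stopifnot(length(predictions) == length(labels),
            length(membership) == length(labels))
  keep <- predictions != "excluded_incomplete"
  mem <- membership == "member" & keep
  list(in_zone = score(predictions[mem], labels[mem], "in_zone"),
       whole_dataset = score(predictions[keep], labels[keep],
                             "whole_dataset"),
       n_excluded = sum(!keep))
}
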