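## Developmental-delay common relaxed zones (DDCRZ): per-characteristic
## intervals spanning the delayed training subjects' values, dilated by a
## fraction of the pooled range. Step 1 of the predictor: a subject outside
## the zones is classified as normally developing without ever reaching the
## network stage.

#' Build the relaxed zones
#'
#' For each selected characteristic the zone is the interval
#' `[min(delayed) - relaxation * R, max(delayed) + relaxation * R]`, where
#' `R` is the characteristic's pooled range over the training subjects and
#' the min/max run over delayed training subjects with an observed value.
#'
#' @param table Training cohort table.
#' @param selection A [select_characteristics()] result; zones are built
#'   over its `selected` characteristics.
#' @param relaxation Fraction of the pooled range added on each side
#'   (default 0.10).
#' @param membership_fraction Fraction of zone characteristics a subject
#'   must satisfy to be a member (default 1, i.e. all of them).
#' @return A `relaxed_zone_set`: list with `zones` (data frame:
#'   `characteristic`, `low`, `high`, `n_delayed`, `n_train`),
#'   `relaxation`, `membership_fraction`.
#' @examples
#' # delayed values {2, 3} on a pooled range of width 10, relaxation 0.1
#' # give the zone [1, 4]
#' @export
build_ddcrz <- function(table, selection, relaxation = 0.10,
                        membership_fraction = 1.0) {
  stopifnot(inherits(selection, "selection_result"),
            is.numeric(relaxation), relaxation >= 0,
            is.numeric(membership_fraction),
            membership_fraction > 0, membership_fraction <= 1)
  ids <- selection$selected
  if (!length(ids)) stop("no zone characteristics: selection is empty")
  zones <- data.frame(characteristic = ids, low = NA_real_, high = NA_real_,
                      n_delayed = NA_integer_, n_train = NA_integer_,
                      stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    v <- table[[ids[i]]]
    if (is.null(v)) stop("training table lacks characteristic ", ids[i])
    av <- v[!is.na(v)]
    dv <- v[table$label == 1L & !is.na(v)]
    if (!length(dv))
      stop("no delayed training value for zone characteristic ", ids[i])
    R <- max(av) - min(av)
    zones$low[i] <- min(dv) - relaxation * R
    zones$high[i] <- max(dv) + relaxation * R
    zones$n_delayed[i] <- length(dv)
    zones$n_train[i] <- length(av)
  }
  structure(list(zones = zones, relaxation = relaxation,
                 membership_fraction = membership_fraction),
            class = "relaxed_zone_set")
}

#' @export
print.relaxed_zone_set <- function(x, ...) {
  cat("DDCRZ over ", nrow(x$zones), " characteristics (relaxation ",
      x$relaxation, ", membership fraction ", x$membership_fraction,
      ")\n", sep = "")
  cat(sprintf("  %-14s [%g, %g]  (%d delayed of %d training)\n",
              x$zones$characteristic, x$zones$low, x$zones$high,
              x$zones$n_delayed, x$zones$n_train), sep = "")
  invisible(x)
}

#' Step-1 zone membership
#'
#' A subject is a `member` when the fraction of zone characteristics whose
#' value lies inside its interval (closed on both ends) reaches
#' `membership_fraction`; `incomplete` when any zone characteristic is
#' missing (such subjects are excluded from the analysis set); otherwise
#' `non_member`, i.e. classified as normally developing at step 1.
#'
#' @param subject_values Named numeric vector (or one-row piece of a cohort
#'   table) holding the subject's characteristic values.
#' @param zones A [build_ddcrz()] result.
#' @return One of `"member"`, `"non_member"`, `"incomplete"`.
#' @export
zone_membership <- function(subject_values, zones) {
  stopifnot(inherits(zones, "relaxed_zone_set"))
  if (is.data.frame(subject_values)) {
    stopifnot(nrow(subject_values) == 1L)
    subject_values <- unlist(subject_values[, zones$zones$characteristic,
                                            drop = FALSE])
  }
  v <- subject_values[zones$zones$characteristic]
  if (anyNA(v)) return("incomplete")
  inside <- v >= zones$zones$low & v <= zones$zones$high
  if (mean(inside) >= zones$membership_fraction) "member" else "non_member"
}

#' Zone membership for every row of a cohort table
#'
#' @param table A cohort table.
#' @param zones A [build_ddcrz()] result.
#' @return Character vector (`member` / `non_member` / `incomplete`), one
#'   entry per subject.
#' @export
zone_membership_table <- function(table, zones) {
  stopifnot(inherits(zones, "relaxed_zone_set"))
  ids <- zones$zones$characteristic
  miss <- setdiff(ids, names(table))
  if (length(miss)) stop("table lacks zone characteristic(s): ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(table[, ids, drop = FALSE])
  inside <- sweep(m, 2, zones$zones$low, `>=`) &
            sweep(m, 2, zones$zones$high, `<=`)
  frac <- rowMeans(inside)  # NA when any value is missing
  out <- ifelse(is.na(frac), "incomplete",
                ifelse(frac >= zones$membership_fraction,
                       "member", "non_member"))
  as.character(out)
}
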