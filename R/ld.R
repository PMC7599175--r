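## Localisation degree (LD): the screening statistic of the two-step
## predictor. The pooled range of a characteristic is cut into 8 equal-width
## octiles; LD is the fraction of octiles containing at least one delayed
## subject's value. LD = 0.125 means all delayed values sit in one octile
## (strong localisation); LD = 1 means they spread over the whole range.

#' Octile index of values within a range
#'
#' Octiles are left-closed, right-open eighths of `[lo, hi]`; the eighth
#' octile is closed on the right so the pooled maximum belongs to octile 8.
#' A value exactly on an internal boundary belongs to the octile on its
#' right.
#'
#' @param v Numeric values inside `[lo, hi]`.
#' @param lo,hi Range endpoints, `lo < hi`.
#' @return Integer octile indices in 1..8.
#' @export
octile_index <- function(v, lo, hi) {
  stopifnot(is.numeric(v), lo < hi)
  w <- (hi - lo) / 8
  pmin(8L, pmax(1L, as.integer(floor((v - lo) / w)) + 1L))
}

#' Localisation degree of one characteristic
#'
#' @param all_values All subjects' values for the characteristic (the pooled
#'   sample defining the range); must contain at least two distinct finite
#'   values.
#' @param delayed_values The delayed subjects' values (non-empty, finite,
#'   inside the pooled range).
#' @param characteristic Optional identifier carried through to the result.
#' @return A `localisation_profile`: list with elements `characteristic`,
#'   `ld` (in \{1/8, ..., 1\}), `occupied` (logical octile occupancy, length
#'   8), `mask` (the same as an 8-bit integer, octile 1 = least significant
#'   bit), `range_low`, `range_high`, `n_delayed_used`.
#' @examples
#' compute_ld(0:8, c(0.5, 2.5, 4.5, 6.5))$ld  # 4 octiles of 8
#' @export
compute_ld <- function(all_values, delayed_values, characteristic = NA_character_) {
  all_values <- all_values[!is.na(all_values)]
  delayed_values <- delayed_values[!is.na(delayed_values)]
  if (!length(delayed_values))
    stop("empty delayed set: LD undefined",
         if (!is.na(characteristic)) paste0(" for ", characteristic))
  if (any(!is.finite(all_values)) || any(!is.finite(delayed_values)))
    stop("non-finite value in LD input")
  lo <- min(all_values); hi <- max(all_values)
  if (length(all_values) < 2L || hi <= lo)
    stop("degenerate characteristic",
         if (!is.na(characteristic)) paste0(" ", characteristic),
         ": pooled range has zero width")
  if (min(delayed_values) < lo || max(delayed_values) > hi)
    stop("delayed values outside the pooled range")
  occ <- tabulate(octile_index(delayed_values, lo, hi), nbins = 8L) > 0L
  structure(list(characteristic = characteristic,
                 ld = sum(occ) / 8,
                 occupied = occ,
                 mask = sum(2L^(which(occ) - 1L)),
                 range_low = lo, range_high = hi,
                 n_delayed_used = length(delayed_values)),
            class = "localisation_profile")
}

#' @export
print.localisation_profile <- function(x, ...) {
  cat("Localisation profile",
      if (!is.na(x$characteristic)) paste0("for ", x$characteristic), "\n")
  cat(sprintf("  LD = %.3f (%d of 8 octiles), range [%g, %g], %d delayed values\n",
              x$ld, sum(x$occupied), x$range_low, x$range_high,
              x$n_delayed_used))
  cat("  octiles:", paste(ifelse(x$occupied, "X", "."), collapse = ""), "\n")
  invisible(x)
}

## relative span of the occupied octiles, the first LD tie-breaker
occupied_span <- function(occupied) {
  idx <- which(occupied)
  (max(idx) - min(idx) + 1L) / 8
}

#' Screen characteristics by localisation degree
#'
#' Computes the LD of every characteristic over the delayed subgroup
#' (per-characteristic pairwise deletion of missing values), keeps those
#' with LD at or below `ld_threshold`, and nominates the `inner_size`
#' lowest-LD members as the inner subset that feeds the neural-network
#' stage. Ordering is ascending LD; ties are broken by the smaller relative
#' span of occupied octiles, then by characteristic name. Characteristics
#' with fewer than `min_delayed` delayed values or a zero-width pooled range
#' are profiled as `NA` and never selected.
#'
#' @param table A cohort table with at least one delayed subject.
#' @param ld_threshold Selection cut on LD, in `[0.125, 1]` (default 0.375,
#'   i.e. at most 3 of 8 octiles occupied).
#' @param inner_size Number of selected characteristics passed on to the
#'   network stage (default 5, the motor configuration; use 4 for the
#'   cognitive configuration).
#' @param min_delayed Minimum number of delayed values required to profile a
#'   characteristic (default 3).
#' @return A `selection_result`: list with `profiles` (data frame, one row
#'   per characteristic: `characteristic`, `ld`, `mask`, `span`,
#'   `range_low`, `range_high`, `n_delayed_used`), `selected` and
#'   `inner_subset` (ordered identifier vectors), `ld_threshold`,
#'   `inner_size`.
#' @export
select_characteristics <- function(table, ld_threshold = 0.375,
                                   inner_size = 5L, min_delayed = 3L) {
  stopifnot(ld_threshold >= 0.125, ld_threshold <= 1, inner_size >= 1L)
  if (!sum(table$label == 1L))
    stop("cohort has no delayed subjects; LD selection impossible")
  chars <- cohort_characteristics(table)
  prof <- data.frame(characteristic = chars, ld = NA_real_, mask = NA_integer_,
                     span = NA_real_, range_low = NA_real_,
                     range_high = NA_real_, n_delayed_used = NA_integer_,
                     stringsAsFactors = FALSE)
  for (i in seq_along(chars)) {
    v <- table[[chars[i]]]
    dv <- v[table$label == 1L & !is.na(v)]
    av <- v[!is.na(v)]
    if (length(dv) < min_delayed) next
    if (length(av) < 2L || max(av) <= min(av)) next
    p <- compute_ld(av, dv, chars[i])
    prof$ld[i] <- p$ld
    prof$mask[i] <- p$mask
    prof$span[i] <- occupied_span(p$occupied)
    prof$range_low[i] <- p$range_low
    prof$range_high[i] <- p$range_high
    prof$n_delayed_used[i] <- p$n_delayed_used
  }
  ok <- !is.na(prof$ld)
  ord <- order(prof$ld[ok], prof$span[ok], prof$characteristic[ok])
  ranked <- prof$characteristic[ok][ord]
  ranked_ld <- prof$ld[ok][ord]
  selected <- ranked[ranked_ld <= ld_threshold]
  if (!length(selected))
    warning("no characteristic has LD <= ", ld_threshold,
            "; selection is empty")
  if (inner_size > length(selected) && length(selected))
    warning("inner_size (", inner_size, ") exceeds the number of selected ",
            "characteristics (", length(selected), "); using all of them")
  inner <- utils::head(selected, inner_size)
  structure(list(profiles = prof, ranked = ranked, selected = selected,
                 inner_subset = inner, ld_threshold = ld_threshold,
                 inner_size = as.integer(inner_size)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("LD characteristic selection: ", length(x$selected), " selected at ",
      "LD <= ", x$ld_threshold, ", inner subset of ",
      length(x$inner_subset), "\n", sep = "")
  p <- x$profiles[match(x$selected, x$profiles$characteristic), ]
  if (nrow(p)) {
    tag <- ifelse(p$characteristic %in% x$inner_subset, "*", " ")
    cat(sprintf("  %s %-14s LD %.3f (%d delayed)\n", tag, p$characteristic,
                p$ld, p$n_delayed_used), sep = "")
    cat("  (* = inner subset, input to the network stage)\n")
  }
  invisible(x)
}
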