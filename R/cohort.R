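## Synthetic cohorts emulating a subjects x characteristics MRS/DTI feature
## table with a rare binary delay outcome. Values are drawn from
## class-conditional normals; "planted" characteristics get their delayed
## values confined to one octile of the pooled range so that downstream
## localisation-degree screening has a known answer.

.meta_cols <- c("subject_id", "label", "severe_injury")

#' Specification of a synthetic cohort
#'
#' @param n_subjects Number of infants.
#' @param prevalence Probability that an infant is delayed (Bayley-III scale
#'   score < 85); each label is an independent Bernoulli draw.
#' @param planted_localised Named integer vector mapping characteristic
#'   identifiers (see [characteristic()]) to an octile index 1..8. Delayed
#'   infants' values for a planted characteristic are redrawn uniformly
#'   inside the middle half of that octile of the pooled range, forcing its
#'   localisation degree to the minimum 0.125.
#' @param dropout_rate Per-value probability that an individual metabolite
#'   ratio is missing (a failed peak quantification). Applies to the 30 MRS
#'   columns only; DTI values are never dropped. The default 0.007 yields
#'   roughly 19% of subjects with at least one missing ratio.
#' @param severe_injury_rate Probability of the severe-cerebral-injury flag,
#'   drawn independently of everything else; the flag only feeds the
#'   exclusion toggle of the subanalysis.
#' @param seed Integer seed; identical spec + seed reproduces the table
#'   byte-for-byte through [write_cohort()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects, prevalence,
                        planted_localised = integer(),
                        dropout_rate = 0.007,
                        severe_injury_rate = 2 / 7,
                        seed = 1L) {
  stopifnot(is.numeric(n_subjects), length(n_subjects) == 1L, n_subjects >= 1,
            n_subjects == round(n_subjects),
            is.numeric(prevalence), length(prevalence) == 1L,
            prevalence > 0, prevalence < 1,
            is.numeric(dropout_rate), dropout_rate >= 0, dropout_rate < 1,
            is.numeric(severe_injury_rate), severe_injury_rate >= 0,
            severe_injury_rate < 1,
            is.numeric(seed), length(seed) == 1L)
  if (n_subjects * prevalence < 1)
    stop("expected number of delayed subjects (n_subjects * prevalence) is ",
         "below 1; nothing to localise")
  if (length(planted_localised)) {
    if (is.null(names(planted_localised)) || any(names(planted_localised) == ""))
      stop("planted_localised must be a named vector: characteristic -> octile")
    parse_characteristic(names(planted_localised))  # validates names
    oct <- as.integer(planted_localised)
    if (any(is.na(oct)) || any(oct < 1L) || any(oct > 8L))
      stop("planted octile index must be in 1..8")
    planted_localised <- stats::setNames(oct, names(planted_localised))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 prevalence = prevalence,
                 planted_localised = planted_localised,
                 dropout_rate = dropout_rate,
                 severe_injury_rate = severe_injury_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' Labels are Bernoulli(prevalence); each characteristic value is drawn from
#' the label's class-conditional normal. When the distribution carries a
#' within-region equicorrelation `rho > 0`, values of a subject within one
#' region share a common Gaussian factor with loading `sqrt(rho)`. FA draws
#' are clamped into \[0, 1\] and MD draws floored at a small positive value,
#' honouring the physical ranges of those metrics. Planted characteristics
#' are then redrawn for delayed subjects inside the designated octile of the
#' non-delayed pooled range (strictly inside, so the pooled range and hence
#' the octile grid are unchanged). Finally metabolite values are erased
#' independently at `dropout_rate`.
#'
#' @param spec A [cohort_spec()].
#' @param dist A `class_distribution` covering all 42 characteristics, see
#'   [default_class_distribution()].
#' @return A `cohort_table`: data frame with columns `subject_id`, `label`,
#'   `severe_injury` and one numeric column per characteristic (`NA` =
#'   missing value).
#' @examples
#' tab <- generate_cohort(cohort_spec(103, 0.126, seed = 7))
#' table(tab$label)
#' @export
generate_cohort <- function(spec, dist = default_class_distribution("motor")) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!inherits(dist, "class_distribution"))
    dist <- as_class_distribution(dist)
  grid <- characteristic_grid()
  miss <- setdiff(grid$characteristic, dist$characteristic)
  if (length(miss))
    stop("class distribution missing characteristic(s): ",
         paste(miss, collapse = ", "))
  rho <- attr(dist, "rho") %||% 0
  n <- spec$n_subjects
  rownames(dist) <- dist$characteristic

  set.seed(spec$seed)
  label <- stats::rbinom(n, 1L, spec$prevalence)
  severe <- stats::rbinom(n, 1L, spec$severe_injury_rate)

  ## shared within-region factors (only consumed when rho > 0)
  zreg <- if (rho > 0)
    matrix(stats::rnorm(n * length(np_regions())), n,
           dimnames = list(NULL, np_regions()))

  vals <- matrix(NA_real_, n, nrow(grid),
                 dimnames = list(NULL, grid$characteristic))
  for (j in seq_len(nrow(grid))) {
    id <- grid$characteristic[j]
    d <- dist[id, ]
    mu <- ifelse(label == 1L, d$mean_delayed, d$mean_normal)
    sd <- ifelse(label == 1L, d$sd_delayed, d$sd_normal)
    eps <- stats::rnorm(n)
    z <- if (rho > 0) sqrt(rho) * zreg[, grid$region[j]] + sqrt(1 - rho) * eps
         else eps
    v <- mu + sd * z
    if (grid$measure[j] == "FA") v <- pmin(pmax(v, 0), 1)
    if (grid$measure[j] == "MD") v <- pmax(v, 1e-6)
    vals[, j] <- v
  }

  ## plant low-LD structure: delayed values into the middle half of one
  ## octile of the non-delayed range, leaving the pooled range untouched
  for (id in names(spec$planted_localised)) {
    k <- spec$planted_localised[[id]]
    del <- label == 1L
    ref <- vals[!del, id]
    if (sum(del) == 0L) next
    if (length(ref) < 2L || max(ref) <= min(ref))
      stop("cannot plant characteristic ", id,
           ": need at least two distinct non-delayed values")
    w <- (max(ref) - min(ref)) / 8
    lo <- min(ref) + (k - 1L) * w
    vals[del, id] <- stats::runif(sum(del), lo + 0.25 * w, lo + 0.75 * w)
  }

  ## missing-peak dropout on metabolite ratios only
  if (spec$dropout_rate > 0) {
    mrs <- grid$characteristic[grid$measure %in% np_mrs_measures()]
    drop <- matrix(stats::runif(n * length(mrs)) < spec$dropout_rate,
                   n, length(mrs))
    vals[, mrs][drop] <- NA_real_
  }

  width <- max(3L, nchar(as.character(n)))
  tab <- data.frame(subject_id = sprintf(paste0("S%0", width, "d"), seq_len(n)),
                    label = label, severe_injury = severe,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(vals))
  attr(tab, "spec") <- spec
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Characteristic columns of a cohort table
#' @param table A cohort table.
#' @return Character vector of characteristic column names.
#' @export
cohort_characteristics <- function(table) {
  setdiff(names(table), .meta_cols)
}

#' Subjects with a missing value among given characteristics
#' @param table A cohort table.
#' @param characteristics Characteristic identifiers (default: all present).
#' @return Logical vector, `TRUE` where the subject lacks at least one value.
#' @export
is_incomplete <- function(table, characteristics = cohort_characteristics(table)) {
  if (!length(characteristics)) return(rep(FALSE, nrow(table)))
  rowSums(is.na(table[, characteristics, drop = FALSE])) > 0L
}

validate_cohort <- function(table, file = NULL) {
  where <- if (is.null(file)) "" else paste0(" in '", file, "'")
  if (!all(.meta_cols %in% names(table)))
    stop("cohort table", where, " must have columns ",
         paste(.meta_cols, collapse = ", "))
  chars <- setdiff(names(table), .meta_cols)
  parsed <- parse_characteristic(chars)
  if (!all(table$label %in% c(0L, 1L)))
    stop("label column", where, " must contain only 0/1 (1 = delayed)")
  if (!all(table$severe_injury %in% c(0L, 1L)))
    stop("severe_injury column", where, " must contain only 0/1")
  fa <- parsed$characteristic[parsed$measure == "FA"]
  for (id in fa) {
    v <- table[[id]]
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("FA values", where, " must lie in [0, 1] (column ", id, ")")
  }
  md <- parsed$characteristic[parsed$measure == "MD"]
  for (id in md) {
    if (any(table[[id]] <= 0, na.rm = TRUE))
      stop("MD values", where, " must be positive (column ", id, ")")
  }
  invisible(table)
}

#' Write / read a cohort table as CSV
#'
#' The on-disk format is UTF-8 CSV with header
#' `subject_id,label,severe_injury,` followed by the characteristic columns
#' named `MEASURE.REGION` (e.g. `NAA_Cho.CWMR`). Missing values are empty
#' cells. Numeric values are written with 17 significant digits so that a
#' write/read round trip is value-exact.
#'
#' @param table A cohort table.
#' @param path File path.
#' @return `read_cohort()` returns a validated `cohort_table`;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(table, path) {
  validate_cohort(table)
  chars <- cohort_characteristics(table)
  out <- data.frame(subject_id = as.character(table$subject_id),
                    label = as.integer(table$label),
                    severe_injury = as.integer(table$severe_injury),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (id in chars) {
    v <- sprintf("%.17g", table[[id]])
    v[is.na(table[[id]])] <- ""
    out[[id]] <- v
  }
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw)[1:3], .meta_cols))
    stop("cohort file '", path, "' must start with columns ",
         paste(.meta_cols, collapse = ", "))
  chars <- names(raw)[-(1:3)]
  parse_characteristic(chars)  # errors name the bad measure/region
  tab <- data.frame(subject_id = raw$subject_id,
                    label = parse_int_col(raw$label, "label", path),
                    severe_injury = parse_int_col(raw$severe_injury,
                                                  "severe_injury", path),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (id in chars) {
    x <- raw[[id]]
    v <- suppressWarnings(as.numeric(x))
    bad <- which(x != "" & is.na(v))
    if (length(bad))
      stop("non-numeric value '", x[bad[1]], "' at row ", bad[1],
           ", column '", id, "' in '", path, "'")
    v[x == ""] <- NA_real_
    tab[[id]] <- v
  }
  class(tab) <- c("cohort_table", "data.frame")
  validate_cohort(tab, file = path)
  tab
}

parse_int_col <- function(x, col, path) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) | x != as.character(v))
  if (length(bad))
    stop("invalid value '", x[bad[1]], "' at row ", bad[1], ", column '",
         col, "' in '", path, "'")
  v
}
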