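#' @keywords internal
"_PACKAGE"

## Canonical vocabulary for the 42 imaging characteristics:
## 5 metabolite ratios + 2 DTI metrics, each in 6 supraventricular
## white-matter regions. "/" in ratio names maps to "_" in column names.

#' Measure and region vocabularies
#'
#' The seven measures are the five MR-spectroscopy metabolite ratios
#' (NAA/Cho, NAA/Cr, Cho/Cr, mI/Cr, NAA/mI; unitless) and the two DTI
#' metrics MD (mean diffusivity, 10^-3 mm^2/s) and FA (fractional
#' anisotropy, unitless in \[0, 1\]). The six regions are frontal, central
#' and parietal supraventricular white matter, right and left.
#'
#' @return Character vector of valid measure / region codes.
#' @export
np_measures <- function() {
  c("NAA_Cho", "NAA_Cr", "Cho_Cr", "mI_Cr", "NAA_mI", "MD", "FA")
}

#' @rdname np_measures
#' @export
np_regions <- function() {
  c("FWMR", "FWML", "CWMR", "CWML", "PWMR", "PWML")
}

np_mrs_measures <- function() {
  c("NAA_Cho", "NAA_Cr", "Cho_Cr", "mI_Cr", "NAA_mI")
}

#' Characteristic descriptors
#'
#' A characteristic is one (measure, region) pair, e.g. the mI/Cr ratio in
#' right central white matter. Its canonical identifier, used as the CSV
#' column name, is `"MEASURE.REGION"` (e.g. `"mI_Cr.CWMR"`).
#'
#' @param measure Measure code, see [np_measures()]. `/` is accepted and
#'   mapped to `_` (`"NAA/Cho"` equals `"NAA_Cho"`).
#' @param region Region code, see [np_regions()].
#' @return `characteristic()` returns the canonical identifier string;
#'   `characteristic_grid()` returns a data frame of all 42 characteristics
#'   with columns `characteristic`, `measure`, `region`.
#' @examples
#' characteristic("NAA/Cho", "CWMR")
#' nrow(characteristic_grid())
#' @export
characteristic <- function(measure, region) {
  measure <- gsub("/", "_", measure, fixed = TRUE)
  if (!all(measure %in% np_measures()))
    stop("unknown measure: ", paste(setdiff(measure, np_measures()), collapse = ", "))
  if (!all(region %in% np_regions()))
    stop("unknown region: ", paste(setdiff(region, np_regions()), collapse = ", "))
  paste0(measure, ".", region)
}

#' @rdname characteristic
#' @export
characteristic_grid <- function() {
  g <- expand.grid(region = np_regions(), measure = np_measures(),
                   stringsAsFactors = FALSE)[, 2:1]
  g$characteristic <- paste0(g$measure, ".", g$region)
  g[, c("characteristic", "measure", "region")]
}

#' Split a characteristic id into measure and region
#'
#' @param id Character vector of `"MEASURE.REGION"` identifiers.
#' @return Data frame with columns `characteristic`, `measure`, `region`.
#'   Invalid identifiers raise an error naming the offending part.
#' @export
parse_characteristic <- function(id) {
  parts <- strsplit(id, ".", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("malformed characteristic name: ", paste(id[bad], collapse = ", "))
  measure <- vapply(parts, `[[`, "", 1L)
  region <- vapply(parts, `[[`, "", 2L)
  if (!all(measure %in% np_measures()))
    stop("unknown measure in column name: ",
         paste(unique(measure[!measure %in% np_measures()]), collapse = ", "))
  if (!all(region %in% np_regions()))
    stop("unknown region in column name: ",
         paste(unique(region[!region %in% np_regions()]), collapse = ", "))
  data.frame(characteristic = id, measure = measure, region = region,
             stringsAsFactors = FALSE)
}

#' Packaged class-conditional feature distributions
#'
#' Per-characteristic means and SDs for the delayed and non-delayed classes,
#' for either the motor or the cognitive outcome. These ship with the
#' package as plain CSV; two entries are mechanical corrections of obvious
#' typographic errors in the source tables (an FA mean greater than 1 and a
#' malformed SD). Every correction, and every entry kept despite looking
#' suspect, is listed in the provenance file
#' `system.file("extdata", "table_corrections.csv", package = "neoprog")`.
#'
#' @param outcome `"motor"` or `"cognitive"`.
#' @return A `class_distribution`: data frame with columns `characteristic`,
#'   `measure`, `region`, `mean_delayed`, `sd_delayed`, `mean_normal`,
#'   `sd_normal` (42 rows), and attribute `rho` (within-region
#'   equicorrelation, default 0).
#' @examples
#' d <- default_class_distribution("motor")
#' d[d$characteristic == "mI_Cr.CWMR", ]
#' @export
default_class_distribution <- function(outcome = c("motor", "cognitive")) {
  outcome <- match.arg(outcome)
  path <- system.file("extdata",
                      paste0("class_distribution_", outcome, ".csv"),
                      package = "neoprog", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_class_distribution(tab, rho = 0)
}

#' Build a class-distribution object
#'
#' @param tab Data frame with columns `measure`, `region`, `mean_delayed`,
#'   `sd_delayed`, `mean_normal`, `sd_normal`.
#' @param rho Within-region equicorrelation coefficient in `[0, 1)`; 0 means
#'   characteristics are conditionally independent given the class.
#' @return A `class_distribution` data frame.
#' @export
as_class_distribution <- function(tab, rho = 0) {
  need <- c("measure", "region", "mean_delayed", "sd_delayed",
            "mean_normal", "sd_normal")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("class distribution lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
    stop("rho must be a single value in [0, 1)")
  tab$characteristic <- characteristic(tab$measure, tab$region)
  if (anyDuplicated(tab$characteristic))
    stop("duplicated (measure, region) pair in class distribution")
  sds <- c(tab$sd_delayed, tab$sd_normal)
  if (any(!is.finite(sds)) || any(sds <= 0))
    stop("every class SD must be finite and > 0")
  tab <- tab[, c("characteristic", need)]
  attr(tab, "rho") <- rho
  class(tab) <- c("class_distribution", "data.frame")
  tab
}
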