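# Canonical vocabulary and metadata for the 14 NMR lipoprotein measures.
# All downstream tables (manifest, phenotype panel, GRS matrix, results)
# are keyed by these identifiers; unknown names are rejected at parse time.

NMR_PHENOTYPES <- c(
  "small_vldl", "medium_vldl", "large_vldl", "vldl_total", "vldl_diameter",
  "small_ldl", "large_ldl", "ldl_total", "ldl_diameter",
  "small_hdl", "medium_hdl", "large_hdl", "hdl_total", "hdl_diameter"
)

#' The 14 NMR lipoprotein phenotype identifiers
#'
#' Concentrations and total particle numbers are in nmol/L; the three
#' average-diameter measures (`*_diameter`) are in nm.
#'
#' @return Character vector of the 14 canonical phenotype identifiers.
#' @export
#' @examples
#' nmr_phenotypes()
nmr_phenotypes <- function() NMR_PHENOTYPES

#' NMR phenotype metadata
#'
#' Per-phenotype metadata: display label, unit, the diameter range (nm) of the
#' subclass where one is defined (averaged-diameter and total-particle measures
#' have none), and typical location/scale/response values used as simulator
#' defaults. The diameter ranges describe how NMR spectroscopy partitions
#' particles into subclasses; they are carried as metadata only and never enter
#' any computation.
#'
#' @return A data.frame with one row per phenotype.
#' @export
nmr_phenotype_info <- function() {
  data.frame(
    phenotype = NMR_PHENOTYPES,
    label = c(
      "Small VLDL concentration", "Medium VLDL concentration",
      "Large VLDL concentration", "VLDL total particles", "VLDL diameter",
      "Small LDL concentration", "Large LDL concentration",
      "LDL total particles", "LDL diameter",
      "Small HDL concentration", "Medium HDL concentration",
      "Large HDL concentration", "HDL total particles", "HDL diameter"
    ),
    unit = c(rep("nmol/L", 4L), "nm", rep("nmol/L", 3L), "nm",
             rep("nmol/L", 4L), "nm"),
    diameter_lo = c(27, 35, 60, NA, NA, 18, 21.2, NA, NA, 7.3, 8.2, 8.8, NA, NA),
    diameter_hi = c(35, 60, Inf, NA, NA, 21.2, 23, NA, NA, 8.2, 8.8, 13, NA, NA),
    # typical adult fasting values (location, spread) and mean pre/post
    # treatment ratio; simulator defaults only, not estimates from any fit
    typical_mean = c(32.93, 37.49, 3.93, 74.38, 51.39,
                     925.64, 407.11, 1375.33, 20.81,
                     21.65, 3.00, 6.32, 30.97, 8.85),
    typical_sd = c(21.89, 36.74, 7.68, 50.81, 7.86,
                   557.03, 272.91, 437.46, 0.88,
                   5.54, 3.61, 3.54, 5.63, 0.45),
    typical_response_ratio = c(1.442, 2.031, 1.880, 1.713, 0.991,
                               1.188, 1.025, 1.137, 0.996,
                               1.043, 0.507, 1.103, 0.955, 1.014),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

assert_phenotype <- function(x) {
  bad <- setdiff(unique(x), NMR_PHENOTYPES)
  if (length(bad) > 0L) {
    stop("unknown phenotype name(s): ", paste(bad, collapse = ", "),
         " (must be one of the 14 NMR measures, see nmr_phenotypes())",
         call. = FALSE)
  }
  invisible(x)
}
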