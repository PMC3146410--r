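#' Published area-level accessibility summaries for Oita Prefecture
#'
#' Area-level summary statistics for pediatric-care accessibility in the
#' six secondary medical service areas of Oita Prefecture, Japan (2005
#' census population of children aged 0-14): child population, number of
#' pediatric facilities, children per facility, geographic area, mean
#' network travel time to the nearest facility, the relative mean
#' difference D with its rank, and the CSR-standardized expectation
#' `D_bar`, ratio `R` and rank. The `Total` row pools the whole
#' prefecture (mean time and D only).
#'
#' These are published aggregate values, included as a worked reference
#' case: the underlying block-level coordinates are not public, so the
#' package cannot recompute them from raw data, but all derived columns
#' (children per facility, ratios, ranks, column means) are reproducible
#' from the table itself with this package's functions.
#'
#' @return data.frame, one row per area plus the pooled `Total` row
#' @examples
#' oita <- oita_area_summary()
#' standardized_ratio(oita$D[oita$area == "Tobu"],
#'                    oita$D_bar[oita$area == "Tobu"])
#' @export
oita_area_summary <- function() {
  utils::read.csv(system.file("extdata", "oita_area_summary.csv",
                              package = "accessineq"),
                  stringsAsFactors = FALSE)
}
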