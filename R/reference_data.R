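#' Bundled reference summary tables
#'
#' Three published summary tables from a six-winter (season years 2017--2022)
#' haze record of a tropical coastal megacity region, shipped as plain-text
#' fixtures so the table arithmetic and the ratio-comparison stage can be
#' validated against printed values:
#' \describe{
#'   \item{`"duration_frequency"`}{episode counts by duration, split by the
#'     four haze types, with the per-duration mean coefficient of variation
#'     of daily PM2.5 (the full record holds 38 episodes).}
#'   \item{`"precursor_ratios"`}{clean and episodic means of PM2.5/CO,
#'     NOx/CO and SO2/CO for the 13 episodes screened positive for
#'     secondary-aerosol influence; two episodes lack episodic SO2.}
#'   \item{`"biomass_burning"`}{the 19 episodes with at least one day whose
#'     back-trajectory crossed fire-hotspot regions, with the day counts and
#'     the low/high impact label (high when affected days reach half the
#'     episode duration).}
#' }
#'
#' @param name One of `"duration_frequency"`, `"precursor_ratios"`,
#'   `"biomass_burning"`.
#' @return The table as a data frame.
#' @export
#' @examples
#' head(reference_table("duration_frequency"))
reference_table <- function(name = c("duration_frequency",
                                     "precursor_ratios",
                                     "biomass_burning")) {
  name <- match.arg(name)
  file <- switch(name,
                 duration_frequency = "episodes_by_duration.csv",
                 precursor_ratios = "precursor_ratio_episodes.csv",
                 biomass_burning = "biomass_burning_episodes.csv")
  path <- system.file("extdata", file, package = "hazemet", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
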