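#' Native-habitat envelope reference table for Rheum tanguticum
#'
#' Per-variable summary statistics of the environmental envelope of
#' *Rheum tanguticum* (Dahuang), extracted from 206 field plots in 26 towns
#' of nine counties across Gansu, Qinghai and Sichuan — the native range of
#' this alpine rhubarb. Columns: `variable`, `unit`, `min`, `max`, `mean`,
#' `se` (standard error of the mean), `n`, `f_value` (one-way ANOVA F across
#' native habitats, all significant at p < 0.001) and `cv_pct` (the reported
#' coefficient of variation in percent). The `cv_pct` column satisfies the
#' identity `Cv = sd_from_se(se, n) / |mean| * 100` to one rendered decimal,
#' which is exercised by the test suite.
#'
#' @return data.frame with 12 rows (11 climate/terrain variables plus soil
#'   pH).
#' @export
#' @examples
#' ref <- rheum_reference()
#' coefficient_of_variation(ref$mean[1], sd_from_se(ref$se[1], ref$n[1]))
rheum_reference <- function() {
  utils::read.csv(system.file("extdata", "rheum_tanguticum_envelope.csv",
                              package = "habsim", mustWork = TRUE),
                  stringsAsFactors = FALSE, check.names = FALSE)
}
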