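#' Published dose-reduction indexes for three validated drug pairs
#'
#' Dose-reduction indexes (DRI) measured by fixed-ratio combination assays
#' for alsterpaullone + scriptaid and irinotecan + semustine in A549 lung
#' cancer cells (25/50/75% inhibition) and halofantrine + vinblastine in
#' MDA-MB-231 triple-negative breast cancer cells (50% inhibition). Together
#' with \code{\link{compute_ci}} these reproduce the corresponding published
#' combination-index values.
#'
#' @return data.frame with columns \code{pair}, \code{cell_line},
#'   \code{drug}, \code{level}, \code{dri}
#' @export
example_dri_table <- function() {
  utils::read.delim(system.file("extdata", "a549_tnbc_dri.tsv",
                                package = "comboscreen"),
                    stringsAsFactors = FALSE)
}
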