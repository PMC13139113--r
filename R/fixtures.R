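#' Paths to the packaged example inputs
#'
#' The package ships small plain-text stand-ins for the curated study
#' inputs: a peripheral-neuropathy PT set (`pns_pt_set_standin.csv`; the
#' licensed vocabulary list used in real analyses is a drop-in replacement
#' with the same columns), a brand/generic drug dictionary for the
#' antibody-drug conjugates and common neurotoxic agents
#' (`adc_drug_dictionary_standin.csv`), the default co-medication exclusion
#' list (`neurotoxic_comedications.csv`), and an illustrative synthetic
#' label map (`adc_labels_synthetic.csv`).
#'
#' @param file File name within the package's `extdata`; `NULL` lists the
#'   available files.
#' @return A file path, or a character vector of file names.
#' @export
srsignal_example <- function(file = NULL) {
  if (is.null(file))
    dir(system.file("extdata", package = "srsignal"))
  else
    system.file("extdata", file, package = "srsignal", mustWork = TRUE)
}

#' Default neurotoxic co-medication exclusion list
#'
#' The twelve classical peripheral-neurotoxicity agents (taxanes, platinum
#' compounds, vinca alkaloids, bortezomib and thalidomide) excluded in the
#' co-medication sensitivity analysis.
#'
#' @return Character vector of drug ids.
#' @export
neurotoxic_comedications <- function() {
  readr::read_csv(srsignal_example("neurotoxic_comedications.csv"),
                  show_col_types = FALSE, progress = FALSE)$drug_id
}
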