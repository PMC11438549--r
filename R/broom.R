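#' Turn peptideml objects into tidy tibbles
#'
#' `tidy()` methods return one row per element (edge, peptide, trial,
#' ensemble member); `glance()` methods return a one-row summary.
#'
#' @param x a peptideml object (`similarity_graph`, `dataset_split`,
#'   `hpo_result`, `peptide_ensemble`, `evaluation_report`,
#'   `peptide_build`).
#' @param ... unused.
#' @return a tibble.
#' @name tidy_peptideml
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
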