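#' Bundled HSA-PFAS reference tables
#'
#' Small reference tables for the binding of six per- and polyfluoroalkyl
#' substances (PFNA, HFPO-TA, PFOA, PFO3DA, PFHpA, DFSA) to human serum
#' albumin, shipped as plain CSV under `inst/extdata`. They serve as
#' worked-example inputs for the fitting, thermodynamic, competition and
#' energetics stages.
#'
#' * `hsa_pfas_binding()` - per-temperature Stern-Volmer constants (Ksv,
#'   L/mol), bimolecular quenching constants (Kq, L/mol/s), binding
#'   constants (Kb, L/mol), site numbers, and Van't Hoff `dH`/`dS`/`dG`.
#' * `hsa_pfas_competition()` - binding constants with and without the
#'   warfarin/ibuprofen/lidocaine site markers plus reported displacement
#'   percentages; the `consistent` column flags rows whose reported phi
#'   matches the constants.
#' * `hsa_pfas_gbsa()` - MM/GBSA energy decomposition (kcal/mol),
#'   validated by [validate_gbsa()].
#' * `hsa_pfas_docking()` - docking binding energies (kcal/mol).
#'
#' @return A tibble.
#' @name reference_data
NULL

read_extdata <- function(name) {
  path <- system.file("extdata", name, package = "quenchbind", mustWork = TRUE)
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference_data
#' @export
hsa_pfas_binding <- function() read_extdata("hsa_pfas_binding.csv")

#' @rdname reference_data
#' @export
hsa_pfas_competition <- function() read_extdata("hsa_pfas_competition.csv")

#' @rdname reference_data
#' @export
hsa_pfas_gbsa <- function() {
  validate_gbsa(read_extdata("hsa_pfas_gbsa.csv"))
}

#' @rdname reference_data
#' @export
hsa_pfas_docking <- function() read_extdata("hsa_pfas_docking.csv")
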