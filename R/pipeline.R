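# One deterministic pass through the whole model.

#' Run the full deterministic analysis
#'
#' PIFs from the exposure shift, case fatality from the stationary
#' illness-death identity, reference and intervention life tables, and the
#' economic summary.
#'
#' @param bundle a `tfa_bundle`.
#' @param cf optional precomputed case fatality schedule.
#' @param pifs optional precomputed PIF table.
#' @param horizons numeric years; `Inf` for lifetime.
#' @return object of class `pmslt_result`: list with `pif`, `case_fatality`,
#'   `run`, `comparison`, `economics`.
#' @export
run_analysis <- function(bundle, cf = NULL, pifs = NULL,
                         horizons = c(5, 10, Inf)) {
  if (is.null(cf)) cf <- derive_case_fatality(bundle)
  if (is.null(pifs)) pifs <- pif_table(bundle)
  run <- run_population(bundle, cf = cf, pifs = pifs)
  econ <- economics_summary(run, bundle, horizons = horizons)
  structure(list(pif = pifs, case_fatality = cf, run = run,
                 comparison = econ$comparison, economics = econ),
            class = "pmslt_result")
}
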