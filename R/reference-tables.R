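#' Reported saponin concentrations of the 32-batch two-origin study
#'
#' Contents (mg per g of raw material) of the five index saponins -
#' ginsenosides Rb1, Rg1 and Rd and notoginsenosides R1 and R2 - in 15
#' Sichuan and 17 Yunnan *Panax notoginseng* batches, as reported for the
#' two-origin study this package reanalyses. Used for the desk reanalysis
#' (summary statistics, origin difference tests) and to calibrate the
#' synthetic study generator's origin-specific saponin levels.
#'
#' @return Data frame with `sample_id`, `origin` and one numeric column per
#'   compound.
#' @export
saponin_concentration_table <- function() {
  utils::read.csv(system.file("extdata", "saponin_concentrations.csv",
                              package = "mwfp"))
}

#' Reported similarity-grading results of the 32-batch study
#'
#' The published per-sample similarity parameters (`Sm`, `Pm` in percent,
#' `alpha`) and grade for each of the three single-wavelength fingerprints
#' (203, 270, 325 nm) and the fused fingerprint.
#'
#' @return Data frame with `sample_id`, `origin` and, per channel `ch` in
#'   {203, 270, 325, fused}, columns `Sm_ch`, `Pm_ch`, `alpha_ch`,
#'   `grade_ch`.
#' @export
reported_similarity_results <- function() {
  utils::read.csv(system.file("extdata", "alqfm_reported_results.csv",
                              package = "mwfp"))
}

#' Re-apply the grade rule to the reported similarity parameters
#'
#' Applies [assign_grade()] to the reported (`Sm`, `Pm`, `alpha`) triples of
#' one channel and compares with the reported grades. Six fused-channel rows
#' (S4, S8, S9, S13, S17, S18) are known to be printed one grade worse than
#' the criteria table yields for their printed parameters; they are flagged
#' by `known_discrepant`.
#'
#' @param channel One of `"203"`, `"270"`, `"325"`, `"fused"`.
#' @param criteria Grade criteria table.
#' @return Data frame with `sample_id`, `origin`, `Sm`, `Pm`, `alpha`,
#'   `reported_grade`, `recomputed_grade`, `known_discrepant`.
#' @export
regrade_reported_results <- function(channel = "fused",
                                     criteria = default_grade_criteria()) {
  channel <- match.arg(channel, c("203", "270", "325", "fused"))
  tab <- reported_similarity_results()
  sm <- tab[[paste0("Sm_", channel)]]
  pm <- tab[[paste0("Pm_", channel)]]
  al <- tab[[paste0("alpha_", channel)]]
  data.frame(
    sample_id = tab$sample_id, origin = tab$origin,
    Sm = sm, Pm = pm, alpha = al,
    reported_grade = tab[[paste0("grade_", channel)]],
    recomputed_grade = mapply(assign_grade, sm, pm, al,
                              MoreArgs = list(criteria = criteria)),
    known_discrepant = tab$sample_id %in%
      c("S4", "S8", "S9", "S13", "S17", "S18") & channel == "fused")
}
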