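#' Reference study results for the HHNJS
#'
#' Published results of a survey of 31 home healthcare nurses from three
#' community hospitals who completed the HHNJS, bundled as plain-text
#' tables.  `hhnjs_reference_weights()` returns the dimension and
#' criterion weight table (local weights, global weights and ranks, all
#' printed to 4 decimals); `hhnjs_reference_ipa()` returns the per-item
#' importance-performance table (global-weight importance, mean Likert
#' performance, quadrant label I-IV).
#'
#' These tables serve two purposes: regression anchors for the weight
#' composition, ranking and quadrant logic, and default ground truth for
#' the synthetic generator ([default_true_weights()]).  The underlying raw
#' questionnaires are not available, so per-respondent quantities (e.g.
#' the study's leave-one-out confidence level) cannot be recomputed from
#' them.
#'
#' @return A data frame: for weights, columns `dimension, dim_weight,
#'   dim_rank, criterion, crit_weight, crit_rank, global_weight,
#'   global_rank` (30 rows); for IPA, columns `criterion, importance,
#'   performance, quadrant` (30 rows).
#' @export
hhnjs_reference_weights <- function() {
  read.delim(system.file("extdata", "hhnjs_reference_weights.tsv",
                         package = "cfpripa", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' @rdname hhnjs_reference_weights
#' @export
hhnjs_reference_ipa <- function() {
  read.delim(system.file("extdata", "hhnjs_reference_ipa.tsv",
                         package = "cfpripa", mustWork = TRUE),
             stringsAsFactors = FALSE)
}
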