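#' Label profiles of the ten-participant reference cohort
#'
#' Per-participant high/low label counts of the published ten-participant
#' emotional-EEG study the synthetic generator emulates: 200 epochs per
#' participant (100 picture-viewing trials, each contributing two epochs),
#' labelled high or low on valence and on arousal by self-assessment. The
#' counts are imbalanced for every participant except the tenth's valence
#' task; participant 1's arousal split of 146 high versus 54 low is the most
#' imbalanced (ratio 2.70).
#'
#' @return Data frame with one row per participant and columns
#'   `participant`, `n_pos_valence`, `n_neg_valence`, `n_pos_arousal`,
#'   `n_neg_arousal`.
#' @export
cohort_profiles <- function() {
  data.frame(
    participant = 1:10,
    n_pos_valence = c(76, 108, 114, 96, 112, 102, 86, 104, 112, 100),
    n_neg_valence = c(124, 92, 86, 104, 88, 98, 114, 96, 88, 100),
    n_pos_arousal = c(146, 136, 114, 116, 132, 134, 114, 126, 132, 94),
    n_neg_arousal = c(54, 64, 86, 84, 68, 66, 86, 74, 68, 106))
}

#' Published per-participant error-rate tables of the reference study
#'
#' Reference benchmark tables from the same ten-participant study:
#' `"segment"` holds the balanced error rates (percent) of the first and
#' second half-epochs of each trial, `"splithalf"` the leave-one-out error
#' rates of two trial-disjoint halves of each participant's data — both
#' obtained there with band-power features and a 3-nearest-neighbour
#' classifier. They anchor the consistency and reliability analyses.
#'
#' @param which `"segment"` or `"splithalf"`.
#' @return Data frame with a `participant` column and four error-rate
#'   columns (percent).
#' @export
reference_error_rates <- function(which = c("segment", "splithalf")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_error_rates.tsv"),
                      package = "eeger", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t")
}
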