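#' Published cross-national model summaries
#'
#' The printed regression summaries of the published cross-national
#' dopamine-by-climate study this package's methods reproduce: for each of
#' six trait-by-instrument models (Neuroticism and Extraversion measured
#' with the NEO-PI-R, OPQ and BFI), the number of nations, the R-squared
#' partition (main effects, interaction increment, full model; in percent),
#' the printed incremental F of the interaction, the full-model F and its
#' df. These printed values are arithmetically interlocked — the incremental
#' and full-model F statistics are recomputable from the R-squared triple
#' and n — which makes the table a self-contained oracle for [delta_f()] and
#' [model_f()].
#'
#' @return Data frame with columns `trait`, `instrument`, `n`,
#'   `r2_main_pct`, `r2_interaction_pct`, `r2_full_pct`, `delta_f`,
#'   `model_f`, `df1`, `df2`.
#' @export
published_model_summaries <- function() {
  path <- system.file("extdata", "published_model_summaries.csv",
                      package = "genoclim")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
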