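#' Example ablation summary
#'
#' Headline metric totals of a published staged-association pig-pen
#' tracker evaluated over three held-out farming scenes, for the four
#' variants of its ablation: the unmodified baseline, the variant adding
#' only the domain-attention module (`attention_only`), the variant adding
#' only the staged association cascade (`cascade_only`), and the full
#' model. Percent metrics are on the 0-100 scale. Useful as input for
#' [metric_deltas()].
#'
#' @return a data frame with columns `method`, `HOTA`, `MOTA`, `IDF1`,
#'   `IDS`
#' @export
example_ablation <- function() {
  utils::read.csv(system.file("extdata", "example_ablation.csv",
                              package = "pentrack"), stringsAsFactors = FALSE)
}
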