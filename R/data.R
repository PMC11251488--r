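# Published reference values shipped with the package.

#' Published component means of the presymptomatic cohort
#'
#' Mean TFC, TMS, SDMT and Stroop Word Reading scores (plus the published
#' composite) for the whole presymptomatic cohort and for the slow
#' (Low-delta) and fast (High-delta) decliner groups, as printed in the
#' source study's descriptive table. Because the composite is linear in its
#' components, [compute_cuhdrs()] applied to these means must reproduce the
#' published group means.
#'
#' @return Data frame with columns `column` (total/slow/fast), `n`, `tfc`,
#'   `tms`, `sdmt`, `swr` and the published `cuhdrs` mean.
#' @export
table1_component_means <- function() {
  utils::read.csv(system.file("extdata", "table1_reference.csv",
                              package = "hdprogress"))
}
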