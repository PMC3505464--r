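# Bundled reference tables: transcriptions of the published novel-candidate
# and stage-expression summary tables, used as worked-example inputs and in
# validation tests.

#' Published novel miRNA candidate table
#'
#' Eleven rice novel miRNA candidates (name, mature sequence, length,
#' sequencing abundance, chromosome, genomic context) as printed in the
#' source study of developing indica grains.
#'
#' @return data frame with columns `name`, `sequence` (RNA), `length`,
#'   `abundance`, `chromosome`, `context`.
#' @export
novel_mirna_table <- function() {
  read.delim(system.file("extdata", "novel_mirna_table.tsv",
                         package = "mirfill"),
             stringsAsFactors = FALSE)
}

#' Published stage-expression summary table
#'
#' The 18 miRNAs reported as differentially expressed across the three
#' grain-filling stages, with their average chip signals per stage (G1
#' milk-ripe, G2 soft-dough, G3 hard-dough), consecutive-stage fold changes
#' and t-test p-values, as printed in the source study.
#'
#' @return data frame with columns `pattern` (Up/Down), `mirna_name`,
#'   `mean_g1`, `mean_g2`, `mean_g3`, `fc_21`, `fc_32`, `p_value`.
#' @export
stage_expression_table <- function() {
  read.delim(system.file("extdata", "stage_expression_table.tsv",
                         package = "mirfill"),
             stringsAsFactors = FALSE)
}
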