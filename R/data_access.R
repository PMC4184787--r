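# Access to the packaged summary table of the 31 candidate
# neutrophil-specific genes from the ImmGen compendium screen.

#' Summary table of candidate neutrophil-specific genes
#'
#' The published screen summary for 31 candidate neutrophil-specific genes
#' profiled across the ImmGen compendium: per-neutrophil-population mean
#' intensities (bone marrow BM, blood BL, synovial fluid SF, uric-acid
#' peritonitis UA, thioglycollate peritonitis TG), the printed neutrophil
#' median and range, the non-neutrophil median and range over the 198
#' comparator populations, and the count of comparator populations with mean
#' expression above 120. This table is the input for re-running the
#' specificity criteria without the full compendium.
#'
#' @return `data.frame` with 31 rows; columns `gene_id`, `BM`, `BL`, `SF`,
#'   `UA`, `TG`, `nf_median`, `nf_min`, `nf_max`, `non_nf_median`,
#'   `non_nf_min`, `non_nf_max`, `non_nf_above`.
#' @export
specificity_summary_table <- function() {
  path <- system.file("extdata", "neutrophil_specificity_summary.tsv",
                      package = "neutract", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
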