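# Accessors for the small reference tables shipped with the package.

#' GenBank survey hit counts for copepod SL and SL-like sequences
#'
#' Reported hit counts of the CopepodSL and of five previously proposed
#' copepod SL-like sequences against public transcriptomic/genomic data
#' sets; `copepod_hits` is the subset of hits that were copepod sequences
#' (NA where the survey reported only siphonostomatoid-dominated totals).
#' Useful for summarising SL specificity across copepod lineages.
#'
#' @param path Optional path to an alternative TSV with the same columns.
#' @return data.frame with columns `sl_variant`, `hits`, `copepod_hits`.
#' @export
sl_like_survey <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sl_like_survey.tsv", package = "slsplice")
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA")
}
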