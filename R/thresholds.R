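#' Analysis thresholds
#'
#' All numeric constants of the pipeline in one place. Defaults follow the
#' published analysis: bootstrap support of at least 95% for the species
#' bipartition, within-species protein divergence below 0.4% (close to the
#' median protein divergence) for the conservation rule, a 0.1 percentage
#' point gene-level margin and a 1.0 point exon-level margin for barcode
#' selection, 25 bp primer flanks with at most 2 variable positions each,
#' at least 2 extra fixed interspecific differences per exon, a 1.5x
#' gene-family expansion factor, enrichment alpha 0.01, and the gene filter
#' requiring at least 50% coverage in at least 2 specimens of each species.
#'
#' @param support_min minimum bootstrap support (percent) for the species
#'   split, applied inclusively (support >= `support_min`).
#' @param conserved_max_intra_prot maximum within-species protein divergence
#'   (percent) for a hotspot to count as conserved (strict `<`).
#' @param barcode_gene_margin minimum excess (percentage points) of minimal
#'   interspecific over maximal intraspecific divergence for barcode genes
#'   (inclusive).
#' @param primer_flank_len primer flank length in columns.
#' @param primer_max_variable maximum variable positions per flank
#'   (inclusive).
#' @param exon_margin exon-level divergence margin in percentage points
#'   (strict `>`).
#' @param exon_min_extra_diffs minimum excess of raw interspecific over
#'   intraspecific differing positions per exon (inclusive).
#' @param expansion_factor family expansion factor (strict `>`).
#' @param enrich_alpha binomial enrichment threshold (strict `<`).
#' @param coverage_min minimum fraction of non-missing columns per
#'   haplotype (inclusive).
#' @param coverage_min_specimens minimum qualifying specimens per species.
#' @param split_count number of blocks for the random-split consensus.
#' @param consensus_threshold majority-rule retention fraction (strict `>`).
#' @param bootstrap_reps column-bootstrap replicates per gene.
#' @return a named list of class `hotspot_thresholds`.
#' @examples
#' th <- hotspotThresholds()
#' th$support_min
#' @export
hotspotThresholds <- function(support_min = 95,
                              conserved_max_intra_prot = 0.4,
                              barcode_gene_margin = 0.1,
                              primer_flank_len = 25,
                              primer_max_variable = 2,
                              exon_margin = 1.0,
                              exon_min_extra_diffs = 2,
                              expansion_factor = 1.5,
                              enrich_alpha = 0.01,
                              coverage_min = 0.5,
                              coverage_min_specimens = 2,
                              split_count = 100,
                              consensus_threshold = 0.5,
                              bootstrap_reps = 100) {
  th <- list(
    support_min = support_min,
    conserved_max_intra_prot = conserved_max_intra_prot,
    barcode_gene_margin = barcode_gene_margin,
    primer_flank_len = primer_flank_len,
    primer_max_variable = primer_max_variable,
    exon_margin = exon_margin,
    exon_min_extra_diffs = exon_min_extra_diffs,
    expansion_factor = expansion_factor,
    enrich_alpha = enrich_alpha,
    coverage_min = coverage_min,
    coverage_min_specimens = coverage_min_specimens,
    split_count = split_count,
    consensus_threshold = consensus_threshold,
    bootstrap_reps = bootstrap_reps
  )
  bad <- names(th)[!vapply(th, function(v) {
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0
  }, TRUE)]
  if (length(bad)) {
    stop("thresholds must be single positive numbers; offending: ",
         paste(bad, collapse = ", "))
  }
  structure(th, class = "hotspot_thresholds")
}
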