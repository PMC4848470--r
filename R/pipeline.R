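#' Run the full hotspot-scan pipeline
#'
#' Coverage filtering, per-gene divergence profiles, bootstrap separation
#' supports, hotspot calling, GO enrichment, barcode gene and exon
#' selection, concatenated nuclear and mitochondrial trees, and the
#' random-split consensus of the nuclear concatenation.
#'
#' @param dataset a [PhasedDataset-class].
#' @param thresholds a [hotspotThresholds()] list.
#' @param seed integer seed driving the bootstrap and the random-split
#'   consensus.
#' @param hotspotSet which hotspot call set feeds the enrichment and
#'   barcode stages: `"raw"` (support criteria only) or `"conserved"`
#'   (additionally protein-conserved within at least one species).
#' @param annotatedOnly restrict the enrichment universe to annotated
#'   genes.
#' @return named list with elements `kept_genes`, `profiles`, `supports`,
#'   `hotspots`, `enrichment`, `enriched_terms`, `barcode_genes`,
#'   `barcode_exons`, `nuclear_tree`, `mito_tree`, `split_consensus`,
#'   `nuclear_separated`, `mito_separated`.
#' @export
runPipeline <- function(dataset, thresholds = hotspotThresholds(),
                        seed = 1L, hotspotSet = c("raw", "conserved"),
                        annotatedOnly = FALSE) {
  hotspotSet <- match.arg(hotspotSet)
  sm <- specimenSpecies(dataset)
  kept <- coverageFilter(dataset, thresholds)
  mito_flag <- vapply(geneAlignments(dataset)[kept], isMito, TRUE)
  nuclear <- kept[!mito_flag]
  mito <- kept[mito_flag]
  if (length(nuclear) == 0) stop("no nuclear genes pass the coverage filter")

  profiles <- geneProfiles(dataset, nuclear)
  supports <- separationSupports(dataset, nuclear, thresholds, seed = seed)
  hotspots <- callHotspots(profiles, supports, thresholds)
  hs <- hotspots[[hotspotSet]]

  enrichment <- goEnrichment(hs, nuclear, goAnnotations(dataset),
                             thresholds, annotatedOnly = annotatedOnly)
  enriched_terms <- enrichment$term[enrichment$enriched]

  barcode_genes <- selectBarcodeGenes(profiles, enriched_terms,
                                      goAnnotations(dataset), thresholds)
  barcode_exons <- do.call(rbind, lapply(barcode_genes, function(g) {
    selectBarcodeExons(geneAlignments(dataset)[[g]], sm, thresholds)
  }))

  nuc_cat <- concatenateGenes(dataset, nuclear)
  nuclear_tree <- neighborJoining(alignmentDistance(nuc_cat))
  split_cons <- randomSplitConsensus(nuc_cat, k = thresholds$split_count,
                                     seed = seed,
                                     threshold = thresholds$consensus_threshold)
  leaf_sp <- leafSpecies(nuc_cat, sm)

  mito_tree <- NULL
  mito_separated <- NA
  if (length(mito)) {
    mito_cat <- concatenateGenes(dataset, mito)
    mito_tree <- neighborJoining(alignmentDistance(mito_cat))
    mito_separated <- speciesSeparation(mito_tree, leafSpecies(mito_cat, sm))
  }

  list(
    kept_genes = kept,
    profiles = profiles,
    supports = supports,
    hotspots = hotspots,
    enrichment = enrichment,
    enriched_terms = enriched_terms,
    barcode_genes = barcode_genes,
    barcode_exons = barcode_exons,
    nuclear_tree = nuclear_tree,
    mito_tree = mito_tree,
    split_consensus = split_cons,
    nuclear_separated = speciesSeparation(nuclear_tree, leaf_sp),
    mito_separated = mito_separated
  )
}
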