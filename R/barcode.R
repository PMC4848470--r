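#' Select candidate barcode genes
#'
#' A gene qualifies as a diagnostic nuclear-marker candidate when its
#' minimal interspecific divergence exceeds its maximal intraspecific
#' divergence by at least `barcode_gene_margin` percentage points at BOTH
#' the DNA and the protein level (inclusive: "at least 0.1%"), and it is
#' annotated with at least one GO term enriched among the speciation
#' hotspots. Genes with incomparable (NA) divergences fail selection.
#'
#' @param profiles data.frame from [geneProfiles()].
#' @param enrichedTerms character vector of enriched GO ids.
#' @param annotations named list gene id -> GO term ids.
#' @param thresholds a [hotspotThresholds()] list.
#' @return character vector of selected gene ids.
#' @export
selectBarcodeGenes <- function(profiles, enrichedTerms, annotations,
                               thresholds = hotspotThresholds()) {
  mg <- thresholds$barcode_gene_margin
  dna_ok <- !is.na(profiles$dna_min_inter) & !is.na(profiles$dna_max_intra) &
    profiles$dna_min_inter - profiles$dna_max_intra >= mg
  prot_ok <- !is.na(profiles$prot_min_inter) &
    !is.na(profiles$prot_max_intra) &
    profiles$prot_min_inter - profiles$prot_max_intra >= mg
  go_ok <- vapply(profiles$gene_id, function(g) {
    length(intersect(annotations[[g]], enrichedTerms)) > 0
  }, TRUE)
  profiles$gene_id[dna_ok & prot_ok & go_ok]
}

# variable position: >= 2 distinct states among A/C/G/T across all
# haplotypes; columns varying only through N or gaps do not count
.variableColumns <- function(m) {
  counts <- vapply(seq_len(ncol(m)), function(j) {
    length(unique(m[m[, j] %in% .DNA_STATES, j]))
  }, 0L)
  counts >= 2L
}

#' Screen the exons of a gene for barcode suitability
#'
#' Applies the three published criteria to every annotated exon of the
#' alignment: (1) each primer flank (the first and the last
#' `primer_flank_len` columns of the exon) holds at most
#' `primer_max_variable` variable positions across all haplotypes; (2) the
#' minimal interspecific DNA divergence of the exon exceeds the maximal
#' intraspecific divergence by more than `exon_margin` percentage points
#' (strict); (3) the minimal interspecific raw count of differing
#' positions exceeds the maximal intraspecific count by at least
#' `exon_min_extra_diffs` (inclusive). Criteria 2-3 are computed on the
#' exon sub-alignment over all haplotype pairs. Exons shorter than two
#' flanks auto-fail with reason `"too_short"`.
#'
#' @param aln a [PhasedAlignment-class] with exon annotation.
#' @param speciesMap named vector specimen id -> species.
#' @param thresholds a [hotspotThresholds()] list.
#' @return data.frame with one row per exon: `gene_id`, `exon_index`,
#'   `start`, `end`, `flank_left_variable`, `flank_right_variable`,
#'   `min_inter_pct`, `max_intra_pct`, `min_inter_count`,
#'   `max_intra_count`, `crit_flanks`, `crit_margin`, `crit_counts`,
#'   `passed`, `reason`.
#' @export
selectBarcodeExons <- function(aln, speciesMap,
                               thresholds = hotspotThresholds()) {
  ex <- aln@exons
  if (length(ex) == 0) {
    return(data.frame(
      gene_id = character(), exon_index = integer(), start = integer(),
      end = integer(), flank_left_variable = integer(),
      flank_right_variable = integer(), min_inter_pct = numeric(),
      max_intra_pct = numeric(), min_inter_count = integer(),
      max_intra_count = integer(), crit_flanks = logical(),
      crit_margin = logical(), crit_counts = logical(),
      passed = logical(), reason = character(), stringsAsFactors = FALSE
    ))
  }
  len <- alignmentLength(aln)
  if (any(IRanges::start(ex) < 1) || any(IRanges::end(ex) > len)) {
    stop("exon interval outside the alignment for gene '", aln@geneId, "'")
  }
  m <- alignmentMatrix(aln)
  sp <- leafSpecies(aln, speciesMap)
  flank <- thresholds$primer_flank_len
  rows <- lapply(seq_along(ex), function(i) {
    s <- IRanges::start(ex)[i]
    e <- IRanges::end(ex)[i]
    sub <- m[, s:e, drop = FALSE]
    wid <- e - s + 1L
    if (wid < 2 * flank) {
      return(data.frame(
        gene_id = aln@geneId, exon_index = i, start = s, end = e,
        flank_left_variable = NA_integer_,
        flank_right_variable = NA_integer_,
        min_inter_pct = NA_real_, max_intra_pct = NA_real_,
        min_inter_count = NA_integer_, max_intra_count = NA_integer_,
        crit_flanks = FALSE, crit_margin = FALSE, crit_counts = FALSE,
        passed = FALSE, reason = "too_short", stringsAsFactors = FALSE
      ))
    }
    varcol <- .variableColumns(sub)
    left <- sum(varcol[seq_len(flank)])
    right <- sum(varcol[seq.int(wid - flank + 1L, wid)])
    st <- .pairStats(sub, .DNA_STATES)
    n <- nrow(sub)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    inter <- sp[idx[, 1]] != sp[idx[, 2]]
    comp_ok <- st$comparable[idx] > 0
    min_inter_pct <- .naMin(st$percent[idx][inter])
    max_intra_pct <- .naMax(st$percent[idx][!inter])
    min_inter_count <- if (any(inter & comp_ok)) {
      min(st$diffs[idx][inter & comp_ok])
    } else NA_integer_
    max_intra_count <- if (any(!inter & comp_ok)) {
      max(st$diffs[idx][!inter & comp_ok])
    } else NA_integer_
    crit_flanks <- left <= thresholds$primer_max_variable &&
      right <= thresholds$primer_max_variable
    crit_margin <- !is.na(min_inter_pct) && !is.na(max_intra_pct) &&
      (min_inter_pct - max_intra_pct) > thresholds$exon_margin
    crit_counts <- !is.na(min_inter_count) && !is.na(max_intra_count) &&
      (min_inter_count - max_intra_count) >= thresholds$exon_min_extra_diffs
    passed <- crit_flanks && crit_margin && crit_counts
    reason <- if (passed) "" else paste(
      c(
        if (!crit_flanks) "variable_flank",
        if (!crit_margin) "margin",
        if (!crit_counts) "counts"
      ),
      collapse = ";"
    )
    data.frame(
      gene_id = aln@geneId, exon_index = i, start = s, end = e,
      flank_left_variable = left, flank_right_variable = right,
      min_inter_pct = min_inter_pct, max_intra_pct = max_intra_pct,
      min_inter_count = min_inter_count, max_intra_count = max_intra_count,
      crit_flanks = crit_flanks, crit_margin = crit_margin,
      crit_counts = crit_counts, passed = passed, reason = reason,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
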