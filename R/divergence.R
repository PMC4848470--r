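.DNA_STATES <- c("A", "C", "G", "T")
.AA_STATES <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# codon -> single-letter amino acid; stop codons map to X (the masking
# state), as do codons containing N or '-'
.codonMap <- local({
  code <- Biostrings::GENETIC_CODE
  code[code == "*"] <- "X"
  code
})

.encodeAln <- function(m, states) {
  out <- match(m, states, nomatch = 0L)
  dim(out) <- dim(m)
  rownames(out) <- rownames(m)
  out
}

#' p-distance between two aligned sequences
#'
#' Percentage of differing positions among pairwise-comparable columns.
#' A column is comparable when both characters are unambiguous states
#' (`A/C/G/T` for DNA, the 20 standard amino acids for protein); columns
#' with `N`, `-` or `X` in either sequence are excluded from that pair's
#' comparison (pairwise deletion). With zero comparable sites the result is
#' flagged incomparable (`percent = NA`) and must be excluded from any
#' min/max aggregation.
#'
#' @param seq1,seq2 equal-length character strings.
#' @param level `"dna"` or `"protein"`.
#' @return list with `percent`, `diffs`, `comparable`, `incomparable`.
#' @examples
#' pDistance("ACGT", "ACGA")$percent # 25
#' pDistance("AC-T", "ACGT")$comparable # 3
#' @export
pDistance <- function(seq1, seq2, level = c("dna", "protein")) {
  level <- match.arg(level)
  if (nchar(seq1) != nchar(seq2)) stop("sequences must have equal length")
  states <- if (level == "dna") .DNA_STATES else .AA_STATES
  a <- match(strsplit(toupper(seq1), "")[[1]], states, nomatch = 0L)
  b <- match(strsplit(toupper(seq2), "")[[1]], states, nomatch = 0L)
  ok <- a > 0L & b > 0L
  comparable <- sum(ok)
  diffs <- sum(a[ok] != b[ok])
  list(
    percent = if (comparable == 0) NA_real_ else 100 * diffs / comparable,
    diffs = diffs, comparable = comparable,
    incomparable = comparable == 0
  )
}

#' Translate a coding sequence
#'
#' Standard genetic code. Codons containing `N` or `-` translate to `X`;
#' stop codons also translate to `X`, with a warning when a stop occurs
#' before the final codon; a trailing partial codon is dropped. Total
#' function: never errors on sequences over `A,C,G,T,N,-`.
#'
#' @param dnaSeq character string.
#' @param frameOffset columns to skip before the first codon (0..2).
#' @return the protein sequence as a character string.
#' @examples
#' translateCds("ATGAAA") # "MK"
#' translateCds("ATGNNN") # "MX"
#' @export
translateCds <- function(dnaSeq, frameOffset = 0L) {
  m <- matrix(strsplit(toupper(dnaSeq), "")[[1]], nrow = 1)
  paste(.translateMatrix(m, frameOffset)[1, ], collapse = "")
}

# character matrix (rows = sequences) -> amino-acid character matrix
.translateMatrix <- function(m, frameOffset = 0L, geneId = NULL) {
  L <- ncol(m)
  nc <- (L - frameOffset) %/% 3
  if (nc < 1) {
    return(matrix(character(), nrow = nrow(m), ncol = 0,
                  dimnames = list(rownames(m), NULL)))
  }
  i1 <- frameOffset + seq(1L, by = 3L, length.out = nc)
  codons <- matrix(
    paste0(m[, i1, drop = FALSE], m[, i1 + 1L, drop = FALSE],
           m[, i1 + 2L, drop = FALSE]),
    nrow = nrow(m)
  )
  aa <- .codonMap[match(codons, names(.codonMap))]
  aa[is.na(aa)] <- "X"
  dim(aa) <- dim(codons)
  stops <- codons %in% c("TAA", "TAG", "TGA")
  dim(stops) <- dim(codons)
  if (nc > 1 && any(stops[, -nc, drop = FALSE])) {
    warning("internal stop codon(s) translated as X",
            if (!is.null(geneId)) paste0(" in gene '", geneId, "'") else "")
  }
  rownames(aa) <- rownames(m)
  aa
}

# pairwise percent/count matrices over the rows of an alignment matrix
.pairStats <- function(m, states) {
  x <- .encodeAln(m, states)
  pc <- cpp_pair_counts(x)
  pct <- 100 * pc$diffs / pc$comparable
  pct[pc$comparable == 0] <- NA_real_
  diag(pct) <- 0
  dimnames(pct) <- dimnames(pc$diffs) <- dimnames(pc$comparable) <-
    list(rownames(m), rownames(m))
  list(percent = pct, diffs = pc$diffs, comparable = pc$comparable)
}

.naMax <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
.naMin <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)

#' Per-gene divergence profile
#'
#' Minimal interspecific and maximal intraspecific p-distance over all
#' haplotype pairs, at the DNA and the translated-protein level, plus the
#' corresponding raw DNA difference counts. Intraspecific pairs include the
#' two haplotypes of one specimen, so heterozygosity contributes to the
#' within-species divergence. Pairs with zero comparable sites are excluded
#' from the aggregation.
#'
#' @param aln a [PhasedAlignment-class].
#' @param speciesMap named vector specimen id -> species (exactly two
#'   species must be represented in the alignment).
#' @return one-row data.frame with columns `gene_id`, `dna_min_inter`,
#'   `dna_max_intra`, `prot_min_inter`, `prot_max_intra`,
#'   `prot_intra_min_species` (the smaller of the two per-species maxima),
#'   `count_min_inter`, `count_max_intra`, `n_comparable_sites`, and
#'   list-columns `dna_max_intra_by_species`, `prot_max_intra_by_species`.
#' @export
geneProfile <- function(aln, speciesMap) {
  sp <- leafSpecies(aln, speciesMap)
  species <- sort(unique(unname(sp)))
  if (length(species) != 2L) {
    stop("gene '", aln@geneId, "': expected specimens from exactly 2 ",
         "species, found ", length(species))
  }
  m <- alignmentMatrix(aln)
  dna <- .pairStats(m, .DNA_STATES)
  prot <- .pairStats(
    .translateMatrix(m, aln@frameOffset, geneId = aln@geneId), .AA_STATES
  )
  n <- nrow(m)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  inter <- sp[idx[, 1]] != sp[idx[, 2]]
  pick <- function(mat, rows) mat[idx[rows, , drop = FALSE]]
  intra_by <- function(mat) {
    vapply(species, function(s) {
      rows <- !inter & sp[idx[, 1]] == s
      .naMax(pick(mat, rows))
    }, 0)
  }
  dna_by <- intra_by(dna$percent)
  prot_by <- intra_by(prot$percent)
  df <- data.frame(
    gene_id = aln@geneId,
    dna_min_inter = .naMin(pick(dna$percent, inter)),
    dna_max_intra = .naMax(pick(dna$percent, !inter)),
    prot_min_inter = .naMin(pick(prot$percent, inter)),
    prot_max_intra = .naMax(pick(prot$percent, !inter)),
    prot_intra_min_species = .naMin(prot_by),
    count_min_inter = {
      ok <- inter & pick(dna$comparable, seq_len(nrow(idx))) > 0
      if (!any(ok)) NA_integer_ else min(pick(dna$diffs, ok))
    },
    count_max_intra = {
      ok <- !inter & pick(dna$comparable, seq_len(nrow(idx))) > 0
      if (!any(ok)) NA_integer_ else max(pick(dna$diffs, ok))
    },
    n_comparable_sites = sum(colSums(
      matrix(m %in% .DNA_STATES, nrow = n)) == n),
    stringsAsFactors = FALSE
  )
  df$dna_max_intra_by_species <- I(list(dna_by))
  df$prot_max_intra_by_species <- I(list(prot_by))
  df
}

#' Divergence profiles for a set of genes
#'
#' @param dataset a [PhasedDataset-class].
#' @param geneIds genes to profile (default: all).
#' @return data.frame with one [geneProfile()] row per gene.
#' @export
geneProfiles <- function(dataset, geneIds = names(geneAlignments(dataset))) {
  sm <- specimenSpecies(dataset)
  do.call(rbind, lapply(geneAlignments(dataset)[geneIds], geneProfile,
                        speciesMap = sm))
}

#' Coverage filter defining the analyzable gene set
#'
#' Keeps genes for which, in each species separately, at least
#' `coverage_min_specimens` specimens have at least a `coverage_min`
#' fraction of non-missing columns (`N` is missing; gaps count as covered)
#' in both haplotypes. The boundary is inclusive ("no less than").
#'
#' @param dataset a [PhasedDataset-class].
#' @param thresholds a [hotspotThresholds()] list.
#' @return character vector of retained gene ids, in dataset order.
#' @export
coverageFilter <- function(dataset, thresholds = hotspotThresholds()) {
  sm <- specimenSpecies(dataset)
  species <- sort(unique(unname(sm)))
  keep <- vapply(geneAlignments(dataset), function(g) {
    m <- alignmentMatrix(g)
    frac <- rowMeans(m != "N")
    ok_seq <- frac >= thresholds$coverage_min
    ok_spec <- tapply(ok_seq, g@specimen, all)
    counts <- tapply(
      unname(ok_spec), unname(sm[names(ok_spec)]),
      sum
    )
    all(species %in% names(counts)) &&
      all(counts[species] >= thresholds$coverage_min_specimens)
  }, TRUE)
  names(geneAlignments(dataset))[keep]
}

#' Concatenate gene alignments
#'
#' Columns are appended in the order of `geneIds`; specimens missing from a
#' gene are padded with `N`. Per-gene column boundaries are recorded in the
#' `"boundaries"` attribute.
#'
#' @param dataset a [PhasedDataset-class].
#' @param geneIds genes to concatenate (at least one).
#' @return a [PhasedAlignment-class] named `"concat"`; mito-flagged iff all
#'   input genes are mitochondrial.
#' @export
concatenateGenes <- function(dataset, geneIds) {
  if (length(geneIds) == 0) stop("empty gene list")
  genes <- geneAlignments(dataset)[geneIds]
  if (anyNA(names(genes))) stop("unknown gene id(s)")
  specimens <- sort(unique(unlist(lapply(genes, function(g) g@specimen))))
  leaves <- as.vector(t(outer(specimens, c("_h1", "_h2"), paste0)))
  chunks <- lapply(genes, function(g) {
    s <- as.character(g@sequences)
    names(s) <- names(g@sequences)
    out <- s[leaves]
    out[is.na(out)] <- strrep("N", alignmentLength(g))
    out
  })
  lens <- vapply(genes, alignmentLength, 0L)
  cat_seq <- do.call(paste0, chunks)
  ends <- cumsum(lens)
  aln <- phasedAlignment(
    "concat", setNames(cat_seq, leaves),
    isMito = all(vapply(genes, isMito, TRUE)),
    frameOffset = 0L
  )
  attr(aln, "boundaries") <- data.frame(
    gene_id = names(genes), start = ends - lens + 1L, end = ends,
    stringsAsFactors = FALSE
  )
  aln
}
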