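#' Phased per-gene alignment
#'
#' One gene's multiple alignment of phased haplotype sequences: every
#' specimen contributes exactly two rows (its maternal and paternal copy),
#' so within-specimen heterozygosity is part of the intraspecific signal.
#' Mitochondrial genes are effectively haploid; they are carried with the
#' single sequence duplicated into both haplotype slots and flagged
#' \code{isMito}.
#'
#' @slot geneId single gene identifier.
#' @slot sequences a [Biostrings::DNAStringSet] of equal-width aligned
#'   sequences over \code{A,C,G,T,N,-}; names are \code{"<specimen>_h<1|2>"}.
#' @slot specimen character vector parallel to \code{sequences}.
#' @slot haplotype integer vector (1 or 2) parallel to \code{sequences}.
#' @slot exons an [IRanges::IRanges] of non-overlapping, sorted exon
#'   intervals in alignment-column coordinates (1-based, closed).
#' @slot isMito logical flag.
#' @slot frameOffset integer in 0..2; number of columns to skip before the
#'   first complete codon.
#'
#' @seealso [phasedAlignment()] for the user constructor.
#' @export
setClass("PhasedAlignment",
  representation(
    geneId = "character",
    sequences = "DNAStringSet",
    specimen = "character",
    haplotype = "integer",
    exons = "IRanges",
    isMito = "logical",
    frameOffset = "integer"
  )
)

setValidity("PhasedAlignment", function(object) {
  msg <- character()
  if (length(object@geneId) != 1L || !nzchar(object@geneId)) {
    msg <- c(msg, "geneId must be a single non-empty string")
  }
  n <- length(object@sequences)
  if (length(object@specimen) != n || length(object@haplotype) != n) {
    msg <- c(msg, "specimen and haplotype must parallel sequences")
  }
  if (n > 0 && length(unique(Biostrings::width(object@sequences))) > 1L) {
    msg <- c(msg, "all sequences must have equal aligned length")
  }
  if (n > 0) {
    tab <- table(object@specimen)
    bad <- names(tab)[tab != 2L]
    if (length(bad)) {
      msg <- c(msg, paste0(
        "each specimen needs exactly 2 haplotypes; violated by: ",
        paste(bad, collapse = ", ")
      ))
    }
    key <- paste(object@specimen, object@haplotype)
    if (anyDuplicated(key)) {
      msg <- c(msg, paste0(
        "duplicated (specimen, haplotype) pair for specimen(s): ",
        paste(unique(object@specimen[duplicated(key)]), collapse = ", ")
      ))
    }
    if (!all(object@haplotype %in% 1:2)) {
      msg <- c(msg, "haplotype must be 1 or 2")
    }
  }
  len <- if (n > 0) Biostrings::width(object@sequences)[1] else 0L
  ex <- object@exons
  if (length(ex)) {
    if (any(IRanges::start(ex) < 1L) || any(IRanges::end(ex) > len)) {
      msg <- c(msg, "exon intervals must lie within the alignment")
    }
    if (is.unsorted(IRanges::start(ex), strictly = TRUE) && length(ex) > 1L) {
      msg <- c(msg, "exon intervals must be sorted")
    }
    if (length(ex) > 1L &&
        any(IRanges::start(ex)[-1] <= IRanges::end(ex)[-length(ex)])) {
      msg <- c(msg, "exon intervals must not overlap")
    }
  }
  if (length(object@isMito) != 1L) msg <- c(msg, "isMito must be length 1")
  if (length(object@frameOffset) != 1L ||
      !(object@frameOffset %in% 0:2)) {
    msg <- c(msg, "frameOffset must be 0, 1 or 2")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a phased gene alignment
#'
#' @param geneId gene identifier.
#' @param sequences named character vector or [Biostrings::DNAStringSet];
#'   names \code{"<specimen>_h<1|2>"}, or supply `specimen`/`haplotype`.
#' @param specimen,haplotype optional explicit vectors parallel to
#'   `sequences`; derived from the names when omitted.
#' @param exons an [IRanges::IRanges] of exon intervals (may be empty).
#' @param isMito logical; mitochondrial gene (haploid, duplicated rows).
#' @param frameOffset integer 0..2.
#' @return a [PhasedAlignment-class] object.
#' @examples
#' aln <- phasedAlignment("g1", c(
#'   "s1_h1" = "ATGAAA", "s1_h2" = "ATGAAA",
#'   "s2_h1" = "ATGAAG", "s2_h2" = "ATGAAG"
#' ))
#' alignmentLength(aln)
#' @export
phasedAlignment <- function(geneId, sequences, specimen = NULL,
                            haplotype = NULL, exons = IRanges::IRanges(),
                            isMito = FALSE, frameOffset = 0L) {
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  nm <- names(sequences)
  if (is.null(specimen) || is.null(haplotype)) {
    if (is.null(nm)) {
      stop("sequences must be named '<specimen>_h<1|2>' or specimen/",
           "haplotype must be given")
    }
    m <- regmatches(nm, regexec("^(.*)_h([12])$", nm))
    bad <- vapply(m, length, 1L) != 3L
    if (any(bad)) {
      stop("cannot parse haplotype from sequence name(s): ",
           paste(nm[bad], collapse = ", "))
    }
    specimen <- vapply(m, `[`, "", 2L)
    haplotype <- as.integer(vapply(m, `[`, "", 3L))
  }
  names(sequences) <- paste0(specimen, "_h", haplotype)
  new("PhasedAlignment",
    geneId = as.character(geneId), sequences = sequences,
    specimen = as.character(specimen), haplotype = as.integer(haplotype),
    exons = exons, isMito = isMito, frameOffset = as.integer(frameOffset)
  )
}

#' @describeIn PhasedAlignment-class gene identifier.
#' @param x,object a `PhasedAlignment`.
#' @export
geneId <- function(x) x@geneId

#' @describeIn PhasedAlignment-class the aligned sequences.
#' @export
alignedSequences <- function(x) x@sequences

#' @describeIn PhasedAlignment-class specimen id of each sequence row.
#' @export
seqSpecimen <- function(x) x@specimen

#' @describeIn PhasedAlignment-class exon intervals.
#' @export
exons <- function(x) x@exons

#' @describeIn PhasedAlignment-class replace the exon intervals.
#' @param value an `IRanges` of exon intervals.
#' @export
`exons<-` <- function(x, value) {
  x@exons <- value
  validObject(x)
  x
}

#' @describeIn PhasedAlignment-class is this a mitochondrial gene?
#' @export
isMito <- function(x) x@isMito

#' @describeIn PhasedAlignment-class number of alignment columns.
#' @export
alignmentLength <- function(x) {
  if (length(x@sequences) == 0) 0L else Biostrings::width(x@sequences)[1]
}

#' @describeIn PhasedAlignment-class the alignment as a character matrix
#'   (rows = haplotypes, named).
#' @export
alignmentMatrix <- function(x) {
  m <- as.matrix(x@sequences)
  rownames(m) <- names(x@sequences)
  m
}

setMethod("show", "PhasedAlignment", function(object) {
  cat("PhasedAlignment '", object@geneId, "': ",
    length(unique(object@specimen)), " specimens x 2 haplotypes, ",
    alignmentLength(object), " columns, ", length(object@exons), " exons",
    if (object@isMito) " [mito]" else "", "\n",
    sep = ""
  )
})

#' Phased two-species dataset
#'
#' Container tying together the specimen metadata table, the per-gene phased
#' alignments, the gene-to-GO annotation map and an optional ortholog-group
#' table. All downstream stages (divergence profiling, tree building,
#' hotspot calling, barcode selection, specimen summaries) operate on this
#' object.
#'
#' @slot specimens data.frame with columns `specimen_id`, `species`,
#'   `latitude`, `longitude`, `is_reference`, `coverage`,
#'   `mapped_noncoding_pct`, `mapped_coding_pct`, `het_pct`,
#'   `het_coding_pct`.
#' @slot genes named list of [PhasedAlignment-class] objects.
#' @slot goAnnotations named list: gene id -> character vector of GO ids.
#' @slot orthologGroups data.frame with columns `group_id`, `species`,
#'   `gene_id`, `protein_length` (0 rows when absent).
#'
#' @seealso [phasedDataset()], [readDataset()], [simulateDataset()].
#' @export
setClass("PhasedDataset",
  representation(
    specimens = "data.frame",
    genes = "list",
    goAnnotations = "list",
    orthologGroups = "data.frame"
  )
)

.SPECIMEN_COLS <- c(
  "specimen_id", "species", "latitude", "longitude", "is_reference",
  "coverage", "mapped_noncoding_pct", "mapped_coding_pct", "het_pct",
  "het_coding_pct"
)

setValidity("PhasedDataset", function(object) {
  msg <- character()
  sp <- object@specimens
  missing_cols <- setdiff(.SPECIMEN_COLS, names(sp))
  if (length(missing_cols)) {
    msg <- c(msg, paste0(
      "specimen table lacks column(s): ", paste(missing_cols, collapse = ", ")
    ))
  } else {
    if (anyDuplicated(sp$specimen_id)) {
      msg <- c(msg, "specimen_id must be unique")
    }
    pct <- c("mapped_noncoding_pct", "mapped_coding_pct", "het_pct",
             "het_coding_pct")
    for (p in pct) {
      v <- sp[[p]]
      if (any(!is.na(v) & (v < 0 | v > 100))) {
        msg <- c(msg, paste0(p, " must be within [0, 100]"))
      }
    }
    if (any(!is.na(sp$coverage) & sp$coverage < 0)) {
      msg <- c(msg, "coverage must be non-negative")
    }
  }
  ids <- vapply(object@genes, function(g) g@geneId, "")
  if (length(ids)) {
    if (anyDuplicated(ids)) msg <- c(msg, "gene ids must be unique")
    if (!identical(unname(ids), names(object@genes))) {
      msg <- c(msg, "genes list names must equal the gene ids")
    }
    if (!length(missing_cols)) {
      known <- sp$specimen_id
      for (g in object@genes) {
        unknown <- setdiff(unique(g@specimen), known)
        if (length(unknown)) {
          msg <- c(msg, paste0(
            "gene '", g@geneId, "' references unknown specimen(s): ",
            paste(unknown, collapse = ", ")
          ))
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a phased dataset
#'
#' @param specimens specimen metadata data.frame (see
#'   [PhasedDataset-class]).
#' @param genes list of [PhasedAlignment-class] objects.
#' @param goAnnotations named list gene id -> GO term ids (optional).
#' @param orthologGroups ortholog-group data.frame (optional).
#' @return a validated [PhasedDataset-class].
#' @export
phasedDataset <- function(specimens, genes = list(),
                          goAnnotations = list(),
                          orthologGroups = emptyOrthologGroups()) {
  ids <- vapply(genes, function(g) g@geneId, "")
  names(genes) <- ids
  new("PhasedDataset",
    specimens = specimens, genes = genes,
    goAnnotations = goAnnotations, orthologGroups = orthologGroups
  )
}

#' @describeIn PhasedDataset-class empty ortholog-group table template.
#' @export
emptyOrthologGroups <- function() {
  data.frame(
    group_id = character(), species = character(), gene_id = character(),
    protein_length = numeric(), stringsAsFactors = FALSE
  )
}

#' @describeIn PhasedDataset-class the specimen metadata table.
#' @param x,object a `PhasedDataset`.
#' @export
specimenTable <- function(x) x@specimens

#' @describeIn PhasedDataset-class named list of gene alignments.
#' @export
geneAlignments <- function(x) x@genes

#' @describeIn PhasedDataset-class the gene -> GO annotation list.
#' @export
goAnnotations <- function(x) x@goAnnotations

#' @describeIn PhasedDataset-class the ortholog-group table.
#' @export
orthologGroups <- function(x) x@orthologGroups

#' @describeIn PhasedDataset-class named vector specimen id -> species.
#' @export
specimenSpecies <- function(x) {
  setNames(x@specimens$species, x@specimens$specimen_id)
}

#' Species of each haplotype leaf of an alignment
#'
#' Maps the row names of a phased alignment (\code{"<specimen>_h<k>"}) to
#' species labels, for use as the `species` argument of the tree functions.
#'
#' @param aln a [PhasedAlignment-class].
#' @param speciesMap named vector specimen id -> species, e.g. from
#'   [specimenSpecies()].
#' @return named character vector leaf label -> species.
#' @export
leafSpecies <- function(aln, speciesMap) {
  sp <- speciesMap[aln@specimen]
  if (anyNA(sp)) {
    stop("species unknown for specimen(s): ",
         paste(unique(aln@specimen[is.na(sp)]), collapse = ", "))
  }
  setNames(unname(sp), names(aln@sequences))
}

setMethod("show", "PhasedDataset", function(object) {
  nmito <- sum(vapply(object@genes, function(g) g@isMito, TRUE))
  cat("PhasedDataset: ", nrow(object@specimens), " specimens (",
    paste(names(table(object@specimens$species)), collapse = " + "),
    "), ", length(object@genes) - nmito, " nuclear + ", nmito,
    " mito genes, ", length(object@goAnnotations),
    " annotated genes\n",
    sep = ""
  )
})
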