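#' Read a phased per-gene FASTA alignment
#'
#' Headers follow the dialect \code{"<specimen>|<species>|h<1|2>"}; the pipe
#' separator is used because specimen ids themselves contain hyphens.
#' Lowercase bases are upcased on read; missing data must be encoded as
#' \code{N} (unknown site) or \code{-} (gap).
#'
#' @param file path to a FASTA file holding one gene's alignment.
#' @param geneId gene id; defaults to the file name without extension.
#' @param isMito,frameOffset,exons metadata for the alignment.
#' @return a [PhasedAlignment-class]; the per-sequence species labels are
#'   attached as attribute `"species"` (named by specimen).
#' @export
readPhasedFasta <- function(file, geneId = NULL, isMito = FALSE,
                            frameOffset = 0L, exons = IRanges::IRanges()) {
  if (is.null(geneId)) geneId <- sub("\\.[^.]*$", "", basename(file))
  seqs <- Biostrings::readDNAStringSet(file)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L |
    !grepl("^h[12]$", vapply(parts, function(p) p[length(p)], ""))
  if (any(bad)) {
    stop("FASTA header not parseable as 'specimen|species|h1' in ", file,
         ": ", paste(names(seqs)[bad], collapse = ", "))
  }
  specimen <- vapply(parts, `[`, "", 1L)
  species <- vapply(parts, `[`, "", 2L)
  haplotype <- as.integer(sub("h", "", vapply(parts, `[`, "", 3L)))
  wid <- Biostrings::width(seqs)
  if (length(unique(wid)) > 1L) {
    stop("unequal sequence lengths within gene '", geneId, "'")
  }
  names(seqs) <- NULL
  aln <- phasedAlignment(geneId, seqs,
    specimen = specimen, haplotype = haplotype,
    exons = exons, isMito = isMito, frameOffset = frameOffset
  )
  attr(aln, "species") <- setNames(species, specimen)[!duplicated(specimen)]
  aln
}

#' Write a phased gene alignment as FASTA
#'
#' @param aln a [PhasedAlignment-class].
#' @param file output path.
#' @param speciesMap named vector specimen id -> species (for the header).
#' @export
writePhasedFasta <- function(aln, file, speciesMap) {
  seqs <- aln@sequences
  names(seqs) <- paste(aln@specimen, speciesMap[aln@specimen],
    paste0("h", aln@haplotype),
    sep = "|"
  )
  Biostrings::writeXStringSet(seqs, file, width = 80L)
  invisible(file)
}

.exonsToString <- function(ex) {
  if (length(ex) == 0) return("")
  paste(paste0(IRanges::start(ex), "-", IRanges::end(ex)), collapse = ";")
}

.exonsFromString <- function(s) {
  if (is.na(s) || !nzchar(s)) return(IRanges::IRanges())
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  IRanges::IRanges(
    start = as.integer(vapply(parts, `[`, "", 1L)),
    end = as.integer(vapply(parts, `[`, "", 2L))
  )
}

#' Write a dataset to a directory
#'
#' Layout: `specimens.tsv`, `genes.tsv` (gene metadata incl. exon
#' intervals), one FASTA per gene under `genes/`, `go_annotations.tsv`
#' (gene id, comma-separated GO ids) and `ortholog_groups.tsv`.
#'
#' @param dataset a [PhasedDataset-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [readDataset()] for the inverse.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(file.path(dir, "genes"), recursive = TRUE, showWarnings = FALSE)
  write.table(dataset@specimens, file.path(dir, "specimens.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  meta <- data.frame(
    gene_id = names(dataset@genes),
    is_mito = vapply(dataset@genes, function(g) g@isMito, TRUE),
    frame_offset = vapply(dataset@genes, function(g) g@frameOffset, 1L),
    exons = vapply(dataset@genes, function(g) .exonsToString(g@exons), ""),
    stringsAsFactors = FALSE
  )
  write.table(meta, file.path(dir, "genes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  sm <- specimenSpecies(dataset)
  for (g in dataset@genes) {
    writePhasedFasta(g, file.path(dir, "genes", paste0(g@geneId, ".fasta")),
                     sm)
  }
  go <- dataset@goAnnotations
  go_df <- data.frame(
    gene_id = names(go),
    terms = vapply(go, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  write.table(go_df, file.path(dir, "go_annotations.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write.table(dataset@orthologGroups, file.path(dir, "ortholog_groups.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' Read a dataset from a directory
#'
#' Inverse of [writeDataset()]. The specimen table is required; the gene
#' alignments, GO annotations and ortholog groups are optional and yield
#' empty structures when absent. All container invariants are checked.
#'
#' @param dir dataset directory.
#' @return a validated [PhasedDataset-class].
#' @export
readDataset <- function(dir) {
  spath <- file.path(dir, "specimens.tsv")
  if (!file.exists(spath)) stop("specimen table missing in '", dir, "'")
  specimens <- read.delim(spath, stringsAsFactors = FALSE)
  specimens$is_reference <- as.logical(specimens$is_reference)
  mpath <- file.path(dir, "genes.tsv")
  genes <- list()
  if (file.exists(mpath)) {
    meta <- read.delim(mpath, stringsAsFactors = FALSE,
                       colClasses = c(exons = "character"))
    genes <- lapply(seq_len(nrow(meta)), function(i) {
      readPhasedFasta(
        file.path(dir, "genes", paste0(meta$gene_id[i], ".fasta")),
        geneId = meta$gene_id[i],
        isMito = as.logical(meta$is_mito[i]),
        frameOffset = as.integer(meta$frame_offset[i]),
        exons = .exonsFromString(meta$exons[i])
      )
    })
    names(genes) <- meta$gene_id
  }
  go <- list()
  gpath <- file.path(dir, "go_annotations.tsv")
  if (file.exists(gpath)) go <- readGoAnnotations(gpath)
  og <- emptyOrthologGroups()
  opath <- file.path(dir, "ortholog_groups.tsv")
  if (file.exists(opath)) og <- readOrthologGroups(opath)
  phasedDataset(specimens, genes, goAnnotations = go, orthologGroups = og)
}

#' Read a gene-to-GO annotation table
#'
#' Two tab-separated columns: gene id and a comma-separated list of term
#' ids. Genes absent from the file have empty annotation sets.
#'
#' @param file TSV path.
#' @return named list gene id -> character vector of term ids.
#' @export
readGoAnnotations <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE,
                   colClasses = "character")
  out <- lapply(df$terms, function(s) {
    if (is.na(s) || !nzchar(s)) character() else
      strsplit(s, ",", fixed = TRUE)[[1]]
  })
  names(out) <- df$gene_id
  out
}

#' Read an ortholog-group table
#'
#' Long format: one row per member gene with columns `group_id`, `species`,
#' `gene_id`, `protein_length`. Outgroup anchor members (used for family
#' merging) carry species `"Drosophila"`.
#'
#' @param file TSV path.
#' @return a data.frame.
#' @export
readOrthologGroups <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  needed <- c("group_id", "species", "gene_id", "protein_length")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("ortholog-group table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df[needed]
}

#' Newick IO
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] fixing the
#' conventions used throughout the package: branch lengths are preserved to
#' at least 10 significant digits and internal node labels carry bootstrap
#' or consensus support percentages.
#'
#' @param text,file Newick text or a file to read from / write to.
#' @param tree an [ape::phylo] tree.
#' @return `readNewick`: a `phylo`; `writeNewick`: the Newick string,
#'   invisibly when `file` is given.
#' @export
readNewick <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else
    ape::read.tree(file = file)
  if (is.null(tr)) stop("malformed Newick input")
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in tree")
  tr
}

#' @rdname readNewick
#' @export
writeNewick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 10)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

.FIXTURE_MD5 <- "9a72e4b24d833dac3909e4d4c21e28b9"

#' Load the packaged eight-specimen fixture
#'
#' The published quality table for the eight hairstreak genomes (three
#' *C. cecrops*, five *C. isobeon*): fold coverage, mapped fractions of
#' coding and non-coding reference positions, genome-wide and coding
#' heterozygosity, together with the collection latitudes/longitudes. The
#' reference specimen NVG-3306 is flagged `is_reference`. The file content
#' is verified against a stored digest.
#'
#' @return data.frame of 8 specimen records.
#' @examples
#' fx <- loadSpecimenFixture()
#' subset(fx, specimen_id == "NVG-3306")$het_pct
#' @export
loadSpecimenFixture <- function() {
  path <- system.file("extdata", "calycopis_specimens.tsv",
    package = "HotspotScan", mustWork = TRUE
  )
  digest <- unname(tools::md5sum(path))
  if (!identical(digest, .FIXTURE_MD5)) {
    stop("specimen fixture corrupted (checksum mismatch)")
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$is_reference <- as.logical(df$is_reference)
  df
}
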