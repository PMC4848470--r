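.SENSE_CODONS <- local({
  all_codons <- names(Biostrings::GENETIC_CODE)
  all_codons[Biostrings::GENETIC_CODE != "*"]
})

#' Simulation configuration
#'
#' Parameters of the two-species phased-genome generator. The defaults
#' mirror the study conditions: 3 + 5 specimens, ~10% hotspot genes and
#' ~10% fast-evolving unconserved genes, interspecific coding divergence
#' of 2.0% for hotspot/unconserved genes versus 0.3% background (giving a
#' genome-wide coding divergence around the observed 1.3-1.5% signal
#' concentrated in a minority of genes), per-haplotype intraspecific rates
#' that reproduce the observed 0.56-1.04% coding heterozygosity scale, 13
#' mitochondrial genes at 0.2% interspecific distance, and one
#' introgressed species-B specimen carrying a species-A mitochondrion.
#'
#' @param nGenes number of nuclear genes.
#' @param geneLenRange gene length range in codons.
#' @param nSpecimensA,nSpecimensB specimens per species.
#' @param fracHotspot,fracUnconserved fractions of nuclear genes in the
#'   hotspot / unconserved class (the rest is background).
#' @param dInter named percent per class: divergence between the two
#'   species consensus sequences.
#' @param dIntra named percent per class: per-haplotype mutation rate
#'   around the species consensus (pairwise intraspecific divergence is
#'   therefore about twice this value).
#' @param nonsynFrac fraction of substitutions placed at codon positions
#'   1-2 (approximately non-synonymous); the rest go to position 3.
#' @param nMitoGenes number of mitochondrial genes (haploid, single
#'   sequence duplicated into both haplotype slots).
#' @param mitoD interspecific mitochondrial consensus distance (percent).
#' @param mitoIntra per-specimen mitochondrial mutation rate (percent).
#' @param introgressedSpecimens species-B specimen ids carrying a
#'   species-A mitochondrion; `NULL` selects the first species-B specimen.
#' @param goTerms number of GO terms.
#' @param enrichedTerms number of designed-enriched terms.
#' @param enrichOdds odds multiplier of a designed-enriched term on
#'   hotspot-class genes.
#' @param goBaseProb baseline probability that a gene carries a given
#'   term.
#' @param seed integer seed; the generator is byte-deterministic for a
#'   fixed seed.
#' @return a validated list of class `sim_config`.
#' @export
simConfig <- function(nGenes = 300,
                      geneLenRange = c(100, 600),
                      nSpecimensA = 3, nSpecimensB = 5,
                      fracHotspot = 0.10, fracUnconserved = 0.10,
                      dInter = c(hotspot = 2.0, background = 0.3,
                                 unconserved = 2.0),
                      dIntra = c(hotspot = 0.2, background = 0.3,
                                 unconserved = 2.0),
                      nonsynFrac = 0.5,
                      nMitoGenes = 13, mitoD = 0.2, mitoIntra = 0.05,
                      introgressedSpecimens = NULL,
                      goTerms = 50, enrichedTerms = 5, enrichOdds = 8,
                      goBaseProb = 0.05,
                      seed = 1L) {
  cls <- c("hotspot", "background", "unconserved")
  if (!all(cls %in% names(dInter)) || !all(cls %in% names(dIntra))) {
    stop("dInter and dIntra must name hotspot, background, unconserved")
  }
  fr <- c(fracHotspot, fracUnconserved, nonsynFrac, goBaseProb)
  if (any(fr < 0 | fr > 1)) stop("fractions must be within [0, 1]")
  if (fracHotspot + fracUnconserved > 1) {
    stop("fracHotspot + fracUnconserved must not exceed 1")
  }
  dv <- c(dInter[cls], dIntra[cls], mitoD, mitoIntra)
  if (any(dv < 0)) stop("divergences must be non-negative")
  if (any(dv > 100)) stop("impossible configuration: divergence > 100%")
  if (geneLenRange[1] < 20 || geneLenRange[2] < geneLenRange[1]) {
    stop("geneLenRange must be increasing and at least 20 codons")
  }
  structure(list(
    nGenes = nGenes, geneLenRange = geneLenRange,
    nSpecimensA = nSpecimensA, nSpecimensB = nSpecimensB,
    fracHotspot = fracHotspot, fracUnconserved = fracUnconserved,
    dInter = dInter[cls], dIntra = dIntra[cls], nonsynFrac = nonsynFrac,
    nMitoGenes = nMitoGenes, mitoD = mitoD, mitoIntra = mitoIntra,
    introgressedSpecimens = introgressedSpecimens,
    goTerms = goTerms, enrichedTerms = enrichedTerms,
    enrichOdds = enrichOdds, goBaseProb = goBaseProb,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# mutate a character vector of bases at ~pct% of sites; a nonsynFrac
# share of the substitutions goes to codon positions 1-2, the rest to
# position 3; the replacement base is uniform among the alternatives that
# do not create a stop codon (coding sequences must stay translatable), so
# the substitution count is preserved exactly
.mutateSeq <- function(seqv, pct, nonsynFrac) {
  L <- length(seqv)
  n <- rbinom(1, L, pct / 100)
  if (n == 0) return(seqv)
  codon_pos <- (seq_len(L) - 1L) %% 3L
  pos12 <- which(codon_pos < 2L)
  pos3 <- which(codon_pos == 2L)
  n1 <- min(round(n * nonsynFrac), length(pos12))
  n2 <- min(n - n1, length(pos3))
  sites <- c(
    pos12[sample.int(length(pos12), n1)],
    pos3[sample.int(length(pos3), n2)]
  )
  for (i in sites) {
    ci <- (i - 1L) %/% 3L
    cstart <- 3L * ci + 1L
    codon <- seqv[cstart:(cstart + 2L)]
    off <- i - cstart + 1L
    alts <- setdiff(.DNA_STATES, seqv[i])
    ok <- vapply(alts, function(b) {
      codon[off] <- b
      !(paste(codon, collapse = "") %in% c("TAA", "TAG", "TGA"))
    }, TRUE)
    if (any(ok)) {
      alts <- alts[ok]
      seqv[i] <- alts[sample.int(length(alts), 1)]
    }
  }
  seqv
}

.randomExonRanges <- function(L, nExons, minLen = 60L) {
  if (L < nExons * minLen) {
    stop("alignment too short for ", nExons, " exon(s) of >= ", minLen,
         " columns")
  }
  extra <- L - nExons * minLen
  alloc <- if (extra > 0) {
    tabulate(sample.int(nExons, extra, replace = TRUE), nExons)
  } else {
    integer(nExons)
  }
  widths <- minLen + alloc
  ends <- cumsum(widths)
  IRanges::IRanges(start = ends - widths + 1L, end = ends)
}

#' Assign a random exon structure to an alignment
#'
#' Partitions the alignment columns into `nExons` consecutive
#' non-overlapping intervals of at least 60 columns each, jointly covering
#' the whole alignment. Deterministic for a fixed seed.
#'
#' @param aln a [PhasedAlignment-class].
#' @param nExons number of exons.
#' @param seed integer seed.
#' @return the alignment with its `exons` slot replaced.
#' @export
simulateExonStructure <- function(aln, nExons, seed = 1L) {
  set.seed(seed)
  exons(aln) <- .randomExonRanges(alignmentLength(aln), nExons)
  aln
}

# specimen ids follow a collection series (s01, s02, ...) with the two
# species interleaved at random, as in real voucher series -- specimen
# naming must carry no species signal because the NJ tie-break is
# lexicographic on labels
.simSpecimens <- function(config) {
  n <- config$nSpecimensA + config$nSpecimensB
  ids <- sprintf("s%02d", seq_len(n))
  species <- sample(rep(c("speciesA", "speciesB"),
                        c(config$nSpecimensA, config$nSpecimensB)))
  isA <- species == "speciesA"
  lat <- ifelse(isA, runif(n, 29, 34), runif(n, 9, 33))
  het <- pmin(pmax(2.6 - 0.04 * lat + rnorm(n, 0, 0.05), 1.0), 2.1)
  is_ref <- seq_len(n) == which(isA)[1]
  data.frame(
    specimen_id = ids,
    species = species,
    latitude = lat,
    longitude = runif(n, -98, -84),
    is_reference = is_ref,
    coverage = ifelse(is_ref, 78, runif(n, 12, 17)),
    mapped_noncoding_pct = pmin(ifelse(
      is_ref, 100,
      ifelse(isA, rnorm(n, 88.5, 0.3), rnorm(n, 83.3, 0.8))
    ), 100),
    mapped_coding_pct = pmin(ifelse(
      is_ref, 99.9,
      ifelse(isA, rnorm(n, 97.6, 0.1), rnorm(n, 97.4, 0.3))
    ), 100),
    het_pct = het,
    het_coding_pct = pmin(pmax(het * 0.5 + rnorm(n, 0, 0.03), 0.3), 1.2),
    stringsAsFactors = FALSE
  )
}

#' Simulate a two-species phased dataset with known ground truth
#'
#' For each nuclear gene an ancestral coding sequence (sense codons only)
#' is drawn, the two species consensus sequences are separated by
#' substitutions at ~`dInter`% of sites for the gene's class, and every
#' specimen receives two haplotypes independently mutated from its species
#' consensus at ~`dIntra`% of sites -- so within-specimen heterozygosity
#' and within-species divergence arise from the same process.
#' Substitutions are single-site replacements uniform over the three
#' alternative bases; a `nonsynFrac` share is placed at codon positions
#' 1-2 to induce protein-level divergence. Mitochondrial genes are haploid
#' (the single sequence is duplicated into both haplotype slots);
#' introgressed species-B specimens receive a species-A-derived
#' mitochondrial sequence, which makes species B polyphyletic in
#' mitochondrial trees while nuclear trees still separate the species. GO
#' terms are assigned at a baseline probability, with the designed
#' enriched terms multiplied by `enrichOdds` on hotspot-class genes.
#'
#' @param config a [simConfig()] list.
#' @return list with `dataset` (a [PhasedDataset-class]) and `truth` (a
#'   list with `geneClass`, `enrichedTerms`, `introgressedSpecimens`,
#'   `seed`).
#' @examples
#' sim <- simulateDataset(simConfig(nGenes = 4, nMitoGenes = 2, seed = 7))
#' table(sim$truth$geneClass)
#' @export
simulateDataset <- function(config = simConfig()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  specimens <- .simSpecimens(config)
  sm <- setNames(specimens$species, specimens$specimen_id)
  idsA <- specimens$specimen_id[specimens$species == "speciesA"]
  idsB <- specimens$specimen_id[specimens$species == "speciesB"]
  intro <- config$introgressedSpecimens
  if (is.null(intro)) intro <- idsB[1]
  if (!all(intro %in% idsB)) {
    stop("introgressed specimens must belong to species B")
  }

  n <- config$nGenes
  n_hot <- round(n * config$fracHotspot)
  n_unc <- min(round(n * config$fracUnconserved), n - n_hot)
  classes <- character(0)
  gene_ids <- character(0)
  if (n > 0) {
    classes <- sample(rep(
      c("hotspot", "unconserved", "background"),
      c(n_hot, n_unc, n - n_hot - n_unc)
    ))
    gene_ids <- sprintf("g%04d", seq_len(n))
  }

  make_gene <- function(gid, cls, d_inter, d_intra, mito = FALSE,
                        mito_source = NULL) {
    Lc <- config$geneLenRange[1] +
      sample.int(config$geneLenRange[2] - config$geneLenRange[1] + 1L, 1) - 1L
    anc <- unlist(strsplit(sample(.SENSE_CODONS, Lc, replace = TRUE), ""))
    consA <- anc
    consB <- .mutateSeq(anc, d_inter, config$nonsynFrac)
    cons <- list(speciesA = consA, speciesB = consB)
    # an introgressed mitochondrion is a recent copy of a donor lineage
    # within species A, so it coalesces inside the A clade rather than at
    # its stem: donor and carrier share a mid-branch ancestor
    donor <- idsA[1]
    mid <- if (mito && length(intro)) {
      .mutateSeq(consA, d_intra / 2, config$nonsynFrac)
    } else {
      consA
    }
    seqs <- character(0)
    for (id in c(idsA, idsB)) {
      recent <- mito && length(intro) && (id %in% intro || id == donor)
      base <- if (recent) {
        mid
      } else {
        cons[[sm[[id]]]]
      }
      rate <- if (recent) d_intra / 2 else d_intra
      if (mito) {
        s <- paste(.mutateSeq(base, rate, config$nonsynFrac),
                   collapse = "")
        seqs[paste0(id, "_h1")] <- s
        seqs[paste0(id, "_h2")] <- s
      } else {
        for (h in 1:2) {
          seqs[paste0(id, "_h", h)] <- paste(
            .mutateSeq(base, d_intra, config$nonsynFrac),
            collapse = ""
          )
        }
      }
    }
    aln <- phasedAlignment(gid, seqs, isMito = mito, frameOffset = 0L)
    if (!mito) {
      n_ex <- sample.int(3L, 1)
      exons(aln) <- .randomExonRanges(3L * Lc, n_ex)
    }
    aln
  }

  genes <- vector("list", n)
  for (i in seq_len(n)) {
    genes[[i]] <- make_gene(
      gene_ids[i], classes[i],
      d_inter = config$dInter[[classes[i]]],
      d_intra = config$dIntra[[classes[i]]]
    )
  }
  mito_ids <- sprintf("mito%02d", seq_len(config$nMitoGenes))
  mito_genes <- lapply(mito_ids, function(gid) {
    make_gene(gid, "mito", d_inter = config$mitoD,
              d_intra = config$mitoIntra, mito = TRUE)
  })

  terms <- sprintf("GO:%07d", seq_len(config$goTerms))
  enr <- if (config$enrichedTerms > 0) {
    sort(sample(terms, config$enrichedTerms))
  } else {
    character(0)
  }
  annotations <- list()
  if (n > 0) {
    p_base <- config$goBaseProb
    annotations <- lapply(seq_len(n), function(i) {
      p <- rep(p_base, config$goTerms)
      if (classes[i] == "hotspot") {
        p[terms %in% enr] <- pmin(p_base * config$enrichOdds, 1)
      }
      terms[runif(config$goTerms) < p]
    })
    names(annotations) <- gene_ids
  }

  all_genes <- c(genes, mito_genes)
  names(all_genes) <- c(gene_ids, mito_ids)
  dataset <- phasedDataset(specimens, all_genes,
                           goAnnotations = annotations)
  truth <- list(
    geneClass = setNames(
      c(classes, rep("mito", config$nMitoGenes)),
      c(gene_ids, mito_ids)
    ),
    enrichedTerms = enr,
    introgressedSpecimens = intro,
    seed = config$seed
  )
  list(dataset = dataset, truth = truth)
}
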