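#' Pairwise p-distance matrix over the haplotype leaves of an alignment
#'
#' @param aln a [PhasedAlignment-class].
#' @param level `"dna"` or `"protein"` (protein distances are computed on
#'   the translated haplotypes).
#' @return symmetric matrix of percent distances with leaf-label dimnames;
#'   `NA` marks pairs with zero comparable sites.
#' @export
alignmentDistance <- function(aln, level = c("dna", "protein")) {
  level <- match.arg(level)
  m <- alignmentMatrix(aln)
  if (level == "protein") {
    m <- .translateMatrix(m, aln@frameOffset, geneId = aln@geneId)
    .pairStats(m, .AA_STATES)$percent
  } else {
    .pairStats(m, .DNA_STATES)$percent
  }
}

.checkDistanceMatrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance input must be a square matrix or 'dist'")
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (anyNA(d)) stop("distance matrix contains incomparable (NA) entries")
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be 0")
  d
}

#' Neighbor-joining tree
#'
#' Standard agglomerative neighbor joining on a matrix of percent
#' p-distances. Ties in the Q-matrix minimisation are broken by the
#' lexicographically smallest label pair (a cluster is represented by its
#' smallest leaf label), which makes degenerate star-like inputs
#' deterministic. Negative branch lengths are clamped to zero. The result
#' is unrooted (trifurcation at the last join).
#'
#' @param d symmetric numeric matrix with zero diagonal (labels in
#'   dimnames) or a `dist` object; at least 2 labels.
#' @return an [ape::phylo] tree.
#' @examples
#' d <- matrix(c(0, 3, 8, 3, 0, 9, 8, 9, 0), 3,
#'   dimnames = list(LETTERS[1:3], LETTERS[1:3])
#' )
#' neighborJoining(d)$edge.length # (d_AB+d_AC-d_BC)/2 etc.
#' @export
neighborJoining <- function(d) {
  d <- .checkDistanceMatrix(d)
  if (nrow(d) < 2) stop("neighbor joining needs at least 2 labels")
  labels <- rownames(d)
  if (anyDuplicated(labels)) stop("duplicate leaf labels")
  txt <- cpp_nj_newick(d, labels, match(labels, sort(labels)))
  readNewick(text = txt)
}

.twoSpecies <- function(species, tips) {
  sp <- species[tips]
  if (anyNA(sp)) {
    stop("no species assigned for leaf/leaves: ",
         paste(tips[is.na(sp)], collapse = ", "))
  }
  lev <- sort(unique(unname(sp)))
  if (length(lev) != 2L) {
    stop("expected exactly 2 species with leaves, found ", length(lev))
  }
  list(sp = sp, levels = lev)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; splits are reported as the
#' side not containing the alphabetically first leaf, as a sorted
#' `"|"`-collapsed signature string.
#'
#' @param tree an [ape::phylo].
#' @return character vector of split signatures (possibly empty).
#' @export
treeSplits <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4) return(character())
  ref <- sort(tree$tip.label)[1]
  pp <- ape::prop.part(tree)
  sigs <- vapply(pp, function(ix) {
    side <- tree$tip.label[ix]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, "")
  unique(sigs[!is.na(sigs)])
}

#' Does a tree separate the two species?
#'
#' TRUE iff removing some edge bipartitions the leaves exactly into
#' all-of-species-1 versus all-of-species-2 (equivalently: both species are
#' monophyletic in the unrooted tree).
#'
#' @param tree an [ape::phylo].
#' @param species named character vector leaf label -> species; every leaf
#'   must be covered and both species must have at least one leaf.
#' @return logical.
#' @export
speciesSeparation <- function(tree, species) {
  two <- .twoSpecies(species, tree$tip.label)
  sideA <- sort(tree$tip.label[two$sp == two$levels[1]])
  # a single-leaf species is split off by its pendant edge
  if (length(sideA) == 1 ||
      length(sideA) == length(tree$tip.label) - 1) {
    return(TRUE)
  }
  sigA <- paste(sideA, collapse = "|")
  sideB <- sort(setdiff(tree$tip.label, sideA))
  sigB <- paste(sideB, collapse = "|")
  any(treeSplits(tree) %in% c(sigA, sigB))
}

.speciesCodes <- function(aln, leafSp) {
  labels <- names(aln@sequences)
  two <- .twoSpecies(leafSp, labels)
  list(
    code = as.integer(factor(two$sp, levels = two$levels)),
    rank = match(labels, sort(labels))
  )
}

#' Column-bootstrap support for the species bipartition
#'
#' For each replicate, alignment columns are resampled with replacement to
#' the original length, the p-distance matrix over all haplotype leaves is
#' recomputed, a neighbor-joining tree is built and tested with
#' [speciesSeparation()]. Support is the percentage of separating
#' replicates. Replicates containing a fully incomparable pair count as
#' non-separating (and are reported via a message). Deterministic for a
#' fixed seed.
#'
#' @param aln a [PhasedAlignment-class].
#' @param species named vector specimen id -> species (see
#'   [leafSpecies()] for the leaf-level map, which is derived internally).
#' @param reps number of replicates (>= 1).
#' @param seed integer seed, or `NULL` to continue the current RNG stream.
#' @param level `"dna"` or `"protein"`.
#' @return support percentage in [0, 100].
#' @export
bootstrapSeparationSupport <- function(aln, species, reps = 100,
                                       seed = NULL,
                                       level = c("dna", "protein")) {
  level <- match.arg(level)
  if (reps < 1) stop("reps must be >= 1")
  sp <- leafSpecies(aln, species)
  m <- alignmentMatrix(aln)
  x <- if (level == "protein") {
    .encodeAln(.translateMatrix(m, aln@frameOffset, geneId = aln@geneId),
               .AA_STATES)
  } else {
    .encodeAln(m, .DNA_STATES)
  }
  sc <- .speciesCodes(aln, sp)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_boot_support(x, sc$code, sc$rank, as.integer(reps))
  if (res$incomparable > 0) {
    message(res$incomparable, " replicate(s) with incomparable pairs ",
            "counted as non-separating for gene '", aln@geneId, "'")
  }
  100 * res$separating / reps
}

#' Per-gene species-separation supports
#'
#' DNA-level and protein-level bootstrap support for the species
#' bipartition, for each gene in `geneIds`.
#'
#' @param dataset a [PhasedDataset-class].
#' @param geneIds genes to score (default: all nuclear genes).
#' @param thresholds a [hotspotThresholds()] list (`bootstrap_reps`).
#' @param seed integer seed for the whole scan.
#' @return data.frame with `gene_id`, `dna_support`, `prot_support`.
#' @export
separationSupports <- function(dataset,
                               geneIds = NULL,
                               thresholds = hotspotThresholds(),
                               seed = 1L) {
  genes <- geneAlignments(dataset)
  if (is.null(geneIds)) {
    geneIds <- names(genes)[!vapply(genes, isMito, TRUE)]
  }
  sm <- specimenSpecies(dataset)
  set.seed(seed)
  rows <- lapply(geneIds, function(gid) {
    g <- genes[[gid]]
    data.frame(
      gene_id = gid,
      dna_support = bootstrapSeparationSupport(
        g, sm, reps = thresholds$bootstrap_reps, level = "dna"
      ),
      prot_support = bootstrapSeparationSupport(
        g, sm, reps = thresholds$bootstrap_reps, level = "protein"
      ),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Majority-rule consensus tree
#'
#' Bipartitions occurring in more than `threshold` of the input trees are
#' retained; each retained split's node is labelled with its occurrence
#' percentage. The output may be multifurcating; majority splits are
#' always pairwise compatible for `threshold >= 0.5`.
#'
#' @param trees list of [ape::phylo] trees over one common leaf set.
#' @param threshold retention fraction in `[0.5, 1]` (strict `>`).
#' @return an [ape::phylo] with `node.label` support percentages (the root
#'   pseudo-node is unlabelled).
#' @export
majorityRuleConsensus <- function(trees, threshold = 0.5) {
  if (threshold < 0.5 || threshold > 1) {
    stop("threshold must be in [0.5, 1]")
  }
  if (length(trees) == 0) stop("no trees given")
  leafsets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(leafsets)) != 1L) {
    stop("all trees must share one leaf set")
  }
  labels <- leafsets[[1]]
  k <- length(trees)
  counts <- table(unlist(lapply(trees, treeSplits)))
  keep <- counts[counts / k > threshold]
  clusters <- strsplit(names(keep), "|", fixed = TRUE)
  support <- 100 * as.numeric(keep) / k
  ord <- order(-lengths(clusters))
  clusters <- clusters[ord]
  support <- support[ord]
  node_children <- function(members, available) {
    # available: index into clusters of candidate direct children
    kids <- list()
    used <- character()
    for (i in available) {
      cl <- clusters[[i]]
      if (all(cl %in% members) && !any(cl %in% used)) {
        kids[[length(kids) + 1L]] <- i
        used <- c(used, cl)
      }
    }
    list(kids = unlist(kids), free = setdiff(members, used))
  }
  build <- function(members, available) {
    nc <- node_children(members, available)
    parts <- character()
    for (i in nc$kids) {
      inner_avail <- setdiff(available, i)
      parts <- c(parts, paste0(
        build(clusters[[i]], inner_avail), .fmtSupport(support[i])
      ))
    }
    parts <- c(parts, sort(nc$free))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(build(labels, seq_along(clusters)), ";")
  readNewick(text = txt)
}

.fmtSupport <- function(s) formatC(s, format = "g", digits = 10)

#' Support of the species bipartition in a set of trees
#'
#' @param trees list of [ape::phylo] trees.
#' @param species named vector leaf label -> species.
#' @return percentage of trees in which the species split is present.
#' @export
speciesSplitSupport <- function(trees, species) {
  100 * mean(vapply(trees, speciesSeparation, TRUE, species = species))
}

#' Random-split consensus tree
#'
#' The alignment columns are randomly permuted (seeded) and partitioned
#' into `k` near-equal blocks; a neighbor-joining tree is built per block
#' and the trees are combined with [majorityRuleConsensus()]. Reducing the
#' data this way exposes weakly supported edges that full-alignment
#' bootstrap hides.
#'
#' @param aln a [PhasedAlignment-class] (typically a concatenation).
#' @param k number of blocks (>= 2, <= alignment length).
#' @param seed integer seed.
#' @param level `"dna"` or `"protein"`.
#' @param threshold consensus retention fraction.
#' @return list with `consensus` (an [ape::phylo]) and `trees` (the `k`
#'   block trees).
#' @export
randomSplitConsensus <- function(aln, k, seed = 1L,
                                 level = c("dna", "protein"),
                                 threshold = 0.5) {
  level <- match.arg(level)
  if (k < 2) stop("k must be >= 2")
  m <- alignmentMatrix(aln)
  if (level == "protein") {
    m <- .translateMatrix(m, aln@frameOffset, geneId = aln@geneId)
  }
  L <- ncol(m)
  if (L < k) stop("alignment length must be at least k")
  states <- if (level == "protein") .AA_STATES else .DNA_STATES
  set.seed(seed)
  perm <- sample.int(L)
  block <- sort(rep_len(seq_len(k), L))
  trees <- lapply(seq_len(k), function(b) {
    sub <- m[, perm[block == b], drop = FALSE]
    pct <- .pairStats(sub, states)$percent
    if (anyNA(pct)) {
      stop("block ", b, " contains a fully incomparable leaf pair")
    }
    neighborJoining(pct)
  })
  list(consensus = majorityRuleConsensus(trees, threshold), trees = trees)
}
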