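# Independent oracles and small fixture builders. These deliberately avoid
# the package's own code paths: naive loops, strsplit, igraph components,
# lchoose summation.

DNA4 <- c("A", "C", "G", "T")
AA20 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

hapNames <- function(specimens) {
  as.vector(t(outer(specimens, c("_h1", "_h2"), paste0)))
}

# naive p-distance between two strings
oraclePdist <- function(a, b, alphabet = DNA4) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  ok <- va %in% alphabet & vb %in% alphabet
  comp <- sum(ok)
  diffs <- sum(va[ok] != vb[ok])
  list(percent = if (comp == 0) NA_real_ else 100 * diffs / comp,
       diffs = diffs, comparable = comp)
}

# exhaustive pair enumeration profile (DNA level) from named strings
oracleDnaProfile <- function(seqs, spOfLeaf) {
  nm <- names(seqs)
  pairs <- t(combn(length(seqs), 2))
  inter_pct <- c(); intra_pct <- c(); inter_cnt <- c(); intra_cnt <- c()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    pd <- oraclePdist(seqs[[i]], seqs[[j]])
    if (pd$comparable == 0) next
    if (spOfLeaf[nm[i]] != spOfLeaf[nm[j]]) {
      inter_pct <- c(inter_pct, pd$percent)
      inter_cnt <- c(inter_cnt, pd$diffs)
    } else {
      intra_pct <- c(intra_pct, pd$percent)
      intra_cnt <- c(intra_cnt, pd$diffs)
    }
  }
  list(
    dna_min_inter = min(inter_pct), dna_max_intra = max(intra_pct),
    count_min_inter = min(inter_cnt), count_max_intra = max(intra_cnt)
  )
}

# bipartitions via igraph edge deletion; signatures match treeSplits()
oracleSplits <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4) return(character())
  ref <- sort(tree$tip.label)[1]
  ed <- tree$edge
  g <- igraph::graph_from_edgelist(
    cbind(as.character(ed[, 1]), as.character(ed[, 2])),
    directed = FALSE
  )
  sigs <- character()
  for (k in seq_len(nrow(ed))) {
    g2 <- igraph::delete_edges(g, k)
    mem <- igraph::components(g2)$membership
    side <- tree$tip.label[mem[as.character(seq_len(n))] == 1]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) >= 2 && length(side) <= n - 2) {
      sigs <- c(sigs, paste(sort(side), collapse = "|"))
    }
  }
  unique(sigs)
}

oracleSeparation <- function(tree, species) {
  lev <- sort(unique(unname(species[tree$tip.label])))
  sideA <- sort(tree$tip.label[species[tree$tip.label] == lev[1]])
  n <- length(tree$tip.label)
  if (length(sideA) %in% c(1, n - 1)) return(TRUE)
  sigA <- paste(sideA, collapse = "|")
  sigB <- paste(sort(setdiff(tree$tip.label, sideA)), collapse = "|")
  any(oracleSplits(tree) %in% c(sigA, sigB))
}

# exact binomial upper tail by direct log-space summation
oracleBinomTail <- function(m, N, p) {
  if (m == 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  k <- m:N
  sum(exp(lchoose(N, k) + k * log(p) + (N - k) * log1p(-p)))
}

# naive re-evaluation of the three barcode exon criteria
oracleExon <- function(sub, spOfLeaf, flank = 25, maxVar = 2,
                       margin = 1.0, extra = 2) {
  wid <- ncol(sub)
  if (wid < 2 * flank) return(FALSE)
  nvar <- function(cols) {
    sum(vapply(cols, function(j) {
      length(unique(sub[sub[, j] %in% DNA4, j])) >= 2
    }, TRUE))
  }
  if (nvar(1:flank) > maxVar) return(FALSE)
  if (nvar((wid - flank + 1):wid) > maxVar) return(FALSE)
  seqs <- apply(sub, 1, paste, collapse = "")
  prof <- oracleDnaProfile(seqs, spOfLeaf)
  (prof$dna_min_inter - prof$dna_max_intra > margin) &&
    (prof$count_min_inter - prof$count_max_intra >= extra)
}

# tiny phased alignment from named strings
makeAln <- function(seqs, geneId = "g", exons = IRanges::IRanges(),
                    isMito = FALSE) {
  phasedAlignment(geneId, seqs, exons = exons, isMito = isMito)
}

# random additive distance matrix from a random topology with positive
# branch lengths; returns list(dist, tree)
randomAdditive <- function(nLeaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(nLeaves, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.5, 3)
  list(d = cophenetic(tr), tree = tr)
}
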