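#' Call speciation hotspots
#'
#' A gene is a raw hotspot when its DNA-level and protein-level bootstrap
#' support for the species bipartition are both at least `support_min`
#' (inclusive reading of the published ">= 95%"). A raw hotspot is a
#' conserved hotspot when additionally its within-species protein
#' divergence is below `conserved_max_intra_prot` in at least one species
#' (the smaller of the two per-species maxima is compared, strict `<`) --
#' this removes fast-evolving proteins that are unconserved in either
#' species. Genes with missing (incomparable) protein values fail the
#' conservation rule rather than erroring.
#'
#' @param profiles data.frame from [geneProfiles()].
#' @param supports data.frame from [separationSupports()].
#' @param thresholds a [hotspotThresholds()] list.
#' @return list with `raw` and `conserved` gene-id vectors and the merged
#'   per-gene `table` (supports, within-species protein divergence, flags).
#' @export
callHotspots <- function(profiles, supports,
                         thresholds = hotspotThresholds()) {
  if (!setequal(profiles$gene_id, supports$gene_id)) {
    stop("profiles and supports must cover the same gene set")
  }
  tab <- merge(
    supports,
    profiles[, c("gene_id", "prot_intra_min_species")],
    by = "gene_id", sort = FALSE
  )
  tab$raw <- !is.na(tab$dna_support) & !is.na(tab$prot_support) &
    tab$dna_support >= thresholds$support_min &
    tab$prot_support >= thresholds$support_min
  tab$conserved <- tab$raw &
    !is.na(tab$prot_intra_min_species) &
    tab$prot_intra_min_species < thresholds$conserved_max_intra_prot
  list(
    raw = tab$gene_id[tab$raw],
    conserved = tab$gene_id[tab$conserved],
    table = tab
  )
}

#' Exact binomial upper tail
#'
#' `P(X >= m)` for `X ~ Binomial(N, p)`, the p-value of the one-sided
#' enrichment test.
#'
#' @param m observed count (0..N).
#' @param N number of trials.
#' @param p success probability.
#' @return probability in (0, 1]; vectorised over `m`, `N`, `p`.
#' @examples
#' binomialUpperTail(3, 3, 0.5) # 0.125
#' binomialUpperTail(0, 10, 0.1) # 1
#' @export
binomialUpperTail <- function(m, N, p) {
  if (any(m < 0 | m > N)) stop("m must be within 0..N")
  if (any(p < 0 | p > 1)) stop("p must be within [0, 1]")
  stats::pbinom(m - 1, N, p, lower.tail = FALSE)
}

#' GO-term enrichment by exact binomial test
#'
#' For every term occurring in the gene set: `m` = members of the set
#' carrying the term, `N` = set size, `p_bg` = fraction of universe genes
#' carrying the term; p-value is the exact binomial upper tail. Terms with
#' `p < enrich_alpha` are flagged enriched; no ancestor propagation is
#' performed (terms are flat labels) and no multiple-testing correction is
#' applied to the flag -- a Benjamini-Hochberg column is included for
#' information only.
#'
#' @param geneSet character vector of gene ids (subset of `universe`).
#' @param universe character vector of gene ids; by default unannotated
#'   genes stay in the universe and dilute `p_bg`.
#' @param annotations named list gene id -> GO term ids.
#' @param thresholds a [hotspotThresholds()] list (`enrich_alpha`).
#' @param annotatedOnly drop unannotated genes from the universe first.
#' @return data.frame sorted by ascending p-value with columns `term`, `m`,
#'   `N`, `p_bg`, `p_value`, `p_adj`, `enriched`.
#' @export
goEnrichment <- function(geneSet, universe, annotations,
                         thresholds = hotspotThresholds(),
                         annotatedOnly = FALSE) {
  if (annotatedOnly) {
    annotated <- names(annotations)[lengths(annotations) > 0]
    universe <- intersect(universe, annotated)
    geneSet <- intersect(geneSet, annotated)
  }
  if (length(universe) == 0) stop("empty universe")
  if (!all(geneSet %in% universe)) {
    stop("gene set must be a subset of the universe")
  }
  ann <- annotations[intersect(universe, names(annotations))]
  term_universe <- table(unlist(ann))
  set_ann <- annotations[intersect(geneSet, names(annotations))]
  term_set <- table(unlist(set_ann))
  if (length(term_set) == 0) {
    return(data.frame(
      term = character(), m = integer(), N = integer(), p_bg = numeric(),
      p_value = numeric(), p_adj = numeric(), enriched = logical(),
      stringsAsFactors = FALSE
    ))
  }
  terms <- names(term_set)
  m <- as.integer(term_set)
  N <- length(geneSet)
  p_bg <- as.numeric(term_universe[terms]) / length(universe)
  p <- binomialUpperTail(m, N, p_bg)
  out <- data.frame(
    term = terms, m = m, N = N, p_bg = p_bg, p_value = p,
    p_adj = p.adjust(p, method = "BH"),
    enriched = p < thresholds$enrich_alpha,
    stringsAsFactors = FALSE
  )
  out[order(out$p_value, out$term), , drop = FALSE]
}

#' Cross-genus hotspot overlap test
#'
#' Given the ortholog groups shared by two genera and, per genus, the
#' groups containing that genus' speciation hotspots, tests whether the two
#' hotspot group sets overlap more than expected. Both directions are
#' computed (`N` from one genus, `p_bg` from the other's hotspot group
#' frequency among shared groups) and the larger p-value is flagged as the
#' conservative headline.
#'
#' @param sharedGroups ids of ortholog groups with members from both
#'   genera.
#' @param hotspotGroups1,hotspotGroups2 group ids containing hotspots of
#'   genus 1 / genus 2 (subsets of `sharedGroups`).
#' @return data.frame with one row per direction (`m`, `N`, `p_bg`,
#'   `p_value`, `headline`).
#' @export
overlapTest <- function(sharedGroups, hotspotGroups1, hotspotGroups2) {
  if (length(sharedGroups) == 0) stop("no shared ortholog groups")
  h1 <- intersect(unique(hotspotGroups1), sharedGroups)
  h2 <- intersect(unique(hotspotGroups2), sharedGroups)
  m <- length(intersect(h1, h2))
  dir1 <- c(m = m, N = length(h1), p_bg = length(h2) / length(sharedGroups))
  dir2 <- c(m = m, N = length(h2), p_bg = length(h1) / length(sharedGroups))
  out <- data.frame(
    direction = c("genus1_vs_genus2", "genus2_vs_genus1"),
    m = m, N = c(dir1["N"], dir2["N"]),
    p_bg = c(dir1["p_bg"], dir2["p_bg"]),
    stringsAsFactors = FALSE
  )
  out$p_value <- binomialUpperTail(out$m, out$N, out$p_bg)
  out$headline <- out$p_value == max(out$p_value)
  rownames(out) <- NULL
  out
}

#' Merge ortholog groups into families
#'
#' Groups that overlap in the Drosophila proteins they map to are merged
#' transitively (union-find over shared Drosophila member ids); groups
#' without Drosophila members stay singleton families. A non-Drosophila
#' gene assigned to two raw groups is an error naming the gene.
#'
#' @param rawGroups data.frame with columns `group_id`, `species`,
#'   `gene_id`, `protein_length`; Drosophila anchor members carry species
#'   `"Drosophila"`.
#' @return data.frame of family members: `family_id` (the smallest merged
#'   group id), `group_id`, `species`, `gene_id`, `protein_length`.
#' @export
mergeOrthologGroups <- function(rawGroups) {
  gids <- unique(rawGroups$group_id)
  non_dmel <- rawGroups[rawGroups$species != "Drosophila", , drop = FALSE]
  ug <- unique(non_dmel[, c("group_id", "gene_id")])
  dup <- unique(ug$gene_id[duplicated(ug$gene_id)])
  if (length(dup)) {
    stop("gene(s) assigned to multiple ortholog groups: ",
         paste(dup, collapse = ", "))
  }
  parent <- seq_along(gids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  dmel <- rawGroups[rawGroups$species == "Drosophila", , drop = FALSE]
  if (nrow(dmel)) {
    by_gene <- split(match(dmel$group_id, gids), dmel$gene_id)
    for (grps in by_gene) {
      grps <- unique(grps)
      if (length(grps) > 1) {
        for (g in grps[-1]) unite(grps[1], g)
      }
    }
  }
  root <- vapply(seq_along(gids), find, 1L)
  fam_of_group <- setNames(gids[root], gids)
  out <- rawGroups
  out$family_id <- unname(fam_of_group[out$group_id])
  out[, c("family_id", "group_id", "species", "gene_id", "protein_length")]
}

#' GO terms associated with each family
#'
#' A term is associated with a family when it is associated with any
#' member gene.
#'
#' @param families data.frame from [mergeOrthologGroups()].
#' @param annotations named list gene id -> GO term ids.
#' @return named list family id -> character vector of term ids.
#' @export
familyAnnotations <- function(families, annotations) {
  lapply(
    split(families$gene_id, families$family_id),
    function(genes) sort(unique(unlist(annotations[genes])))
  )
}

#' Detect expanded gene families
#'
#' A family is expanded in the focal species when both its member count and
#' its total protein length in the focal species exceed `expansion_factor`
#' times the respective averages over the background species (strict `>`;
#' the averages include background species in which the family is absent,
#' counted as zero).
#'
#' @param families data.frame from [mergeOrthologGroups()].
#' @param focalSpecies species label to test for expansion.
#' @param backgroundSpecies species to average over; defaults to every
#'   species in the table except the focal one and `"Drosophila"`.
#' @param thresholds a [hotspotThresholds()] list (`expansion_factor`).
#' @return character vector of expanded family ids.
#' @export
detectExpansions <- function(families, focalSpecies,
                             backgroundSpecies = NULL,
                             thresholds = hotspotThresholds()) {
  if (!focalSpecies %in% families$species) {
    stop("focal species '", focalSpecies, "' absent from the family table")
  }
  if (is.null(backgroundSpecies)) {
    backgroundSpecies <- setdiff(
      unique(families$species), c(focalSpecies, "Drosophila")
    )
  }
  if (length(backgroundSpecies) == 0) {
    stop("at least one background species is required")
  }
  f <- thresholds$expansion_factor
  fam_ids <- unique(families$family_id)
  expanded <- vapply(fam_ids, function(fid) {
    fam <- families[families$family_id == fid, , drop = FALSE]
    foc <- fam[fam$species == focalSpecies, , drop = FALSE]
    cnt <- vapply(backgroundSpecies, function(s) {
      sum(fam$species == s)
    }, 0)
    len <- vapply(backgroundSpecies, function(s) {
      sum(fam$protein_length[fam$species == s])
    }, 0)
    nrow(foc) > f * mean(cnt) &&
      sum(foc$protein_length) > f * mean(len)
  }, TRUE)
  fam_ids[expanded]
}
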