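mkProfiles <- function(ids, prot_intra_min) {
  data.frame(
    gene_id = ids,
    dna_min_inter = 1, dna_max_intra = 0.1,
    prot_min_inter = 1, prot_max_intra = 0.5,
    prot_intra_min_species = prot_intra_min,
    count_min_inter = 5L, count_max_intra = 1L,
    n_comparable_sites = 1000L,
    stringsAsFactors = FALSE
  )
}

test_that("hotspot calling applies both support and conservation rules", {
  ids <- c("g1", "g2", "g3", "g4")
  sup <- data.frame(
    gene_id = ids,
    dna_support = c(100, 100, 100, 90),
    prot_support = c(90, 100, 100, 100)
  )
  # g2: conserved in species A only ("at least one species");
  # g3: conserved in neither
  prof <- mkProfiles(ids, prot_intra_min = c(0, 0, 1.0, 0))
  hs <- callHotspots(prof, sup)
  expect_equal(hs$raw, c("g2", "g3"))      # g1, g4 fail one support each
  expect_equal(hs$conserved, "g2")
  # boundary: support exactly at the threshold is included
  sup95 <- transform(sup, dna_support = 95, prot_support = 95)
  expect_equal(callHotspots(prof, sup95)$raw, ids)
  # monotone: raising support_min never adds hotspots
  for (s in c(90, 95, 99, 100)) {
    hi <- callHotspots(prof, sup, hotspotThresholds(support_min = s))
    lo <- callHotspots(prof, sup, hotspotThresholds(support_min = s - 5))
    expect_true(all(hi$raw %in% lo$raw))
  }
  expect_error(callHotspots(prof[1:3, ], sup), "same gene set")
})

test_that("binomial upper tail is exact, monotone and stable", {
  expect_equal(binomialUpperTail(0, 10, 0.3), 1.0)
  expect_equal(binomialUpperTail(3, 3, 0.5), 0.125)
  expect_equal(binomialUpperTail(3, 10, 0.05), oracleBinomTail(3, 10, 0.05),
               tolerance = 1e-12)
  expect_equal(round(binomialUpperTail(3, 10, 0.05), 5), 0.0115)
  set.seed(5)
  for (i in 1:100) {
    N <- sample.int(10000, 1)
    m <- sample.int(N + 1, 1) - 1L
    p <- runif(1)
    expect_equal(binomialUpperTail(m, N, p), oracleBinomTail(m, N, p),
                 tolerance = 1e-12)
  }
  # non-increasing in m
  N <- 50; p <- 0.2
  tails <- binomialUpperTail(0:N, N, p)
  expect_true(all(diff(tails) <= 1e-15))
  expect_error(binomialUpperTail(5, 3, 0.1), "within 0..N")
})

test_that("GO enrichment computes background rates from the universe", {
  universe <- paste0("g", 1:100)
  ann <- setNames(rep(list("GO:1"), 100), universe)
  ann[paste0("g", 1:30)] <- lapply(paste0("g", 1:30), function(i) {
    c("GO:1", "GO:2")
  })
  # term carried by every universe gene: p_bg 1, p 1, never enriched
  res <- goEnrichment(paste0("g", 1:10), universe, ann)
  r1 <- res[res$term == "GO:1", ]
  expect_equal(r1$p_bg, 1)
  expect_equal(r1$p_value, 1)
  expect_false(r1$enriched)
  # GO:2 in all 10 set members vs 30% background
  r2 <- res[res$term == "GO:2", ]
  expect_equal(r2$p_bg, 0.3)
  expect_equal(r2$p_value, 0.3^10)
  expect_true(r2$enriched)
  # gene set = universe: p-values are the tail at the full count and a
  # term with p_bg >= alpha is never enriched
  full <- goEnrichment(universe, universe, ann)
  for (r in seq_len(nrow(full))) {
    expect_equal(full$p_value[r],
                 binomialUpperTail(full$m[r], 100, full$p_bg[r]))
    if (full$p_bg[r] >= 0.01) expect_false(full$enriched[r])
  }
  expect_error(goEnrichment("g1", character(), ann), "empty universe")
  expect_error(goEnrichment("zz", universe, ann), "subset")
})

test_that("designed-enriched terms are recovered on simulated annotations", {
  sim <- simulateDataset(simConfig(nGenes = 300, nMitoGenes = 0, seed = 11))
  truth <- sim$truth
  cls <- truth$geneClass
  hot <- names(cls)[cls == "hotspot"]
  universe <- names(cls)
  res <- goEnrichment(hot, universe, goAnnotations(sim$dataset))
  flagged <- res$term[res$enriched]
  expect_true(all(truth$enrichedTerms %in% flagged))
  neutral <- setdiff(res$term, truth$enrichedTerms)
  expect_lte(mean(neutral %in% flagged), 0.05)
})

test_that("overlap test reports both directions and is conservative", {
  shared <- paste0("G", 1:100)
  # disjoint hotspot sets: m = 0, p = 1 in both directions
  ot0 <- overlapTest(shared, paste0("G", 1:10), paste0("G", 51:60))
  expect_equal(ot0$p_value, c(1, 1))
  # identical sets of 10 among 100: p = p_bg^N = 1e-10
  ot1 <- overlapTest(shared, paste0("G", 1:10), paste0("G", 1:10))
  expect_equal(ot1$m[1], 10)
  expect_equal(ot1$p_bg[1], 0.1)
  expect_equal(ot1$p_value[1], 1e-10)
  expect_true(any(ot1$headline))
  expect_error(overlapTest(character(), "a", "b"), "no shared")
  # permutation null: empirical tail of the overlap statistic is not
  # exceeded by the binomial p-value beyond Monte-Carlo error, and the
  # test is conservative at alpha = 0.05
  set.seed(9)
  shared <- paste0("G", 1:200)
  h1 <- sample(shared, 25)
  nrep <- 1000
  hits <- 0
  pvals <- numeric(nrep)
  for (r in seq_len(nrep)) {
    h2 <- sample(shared, 40)
    m <- length(intersect(h1, h2))
    pvals[r] <- overlapTest(shared, h1, h2)$p_value[1]
  }
  expect_lte(mean(pvals <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / nrep))
  # empirical tail frequency of m >= 8 matches its computed p-value
  m8 <- overlapTest(shared, h1, paste0("G", sample(200, 40)))
  p_emp <- mean(vapply(seq_len(nrep), function(r) {
    length(intersect(h1, sample(shared, 40))) >= 8
  }, TRUE))
  p_cmp <- binomialUpperTail(8, 25, 40 / 200)
  expect_lt(abs(p_emp - p_cmp), 0.05)
})

test_that("family merging is the transitive closure over Drosophila anchors", {
  rg <- data.frame(
    group_id = c("g1", "g1", "g2", "g2", "g2", "g3", "g3"),
    species = c("Drosophila", "Cal", "Drosophila", "Drosophila", "Cal",
                "Drosophila", "Cal"),
    gene_id = c("dA", "c1", "dA", "dB", "c2", "dB", "c3"),
    protein_length = c(100, 200, 100, 50, 150, 50, 300)
  )
  fam <- mergeOrthologGroups(rg)
  expect_equal(length(unique(fam$family_id)), 1)
  # disjoint anchors stay separate; anchorless groups stay singleton
  rg2 <- data.frame(
    group_id = c("g1", "g1", "g2", "g2", "g3"),
    species = c("Drosophila", "Cal", "Drosophila", "Cal", "Cal"),
    gene_id = c("dA", "c1", "dB", "c2", "c3"),
    protein_length = 1
  )
  fam2 <- mergeOrthologGroups(rg2)
  expect_equal(length(unique(fam2$family_id)), 3)
  # duplicate non-anchor gene errors, naming the gene
  rg3 <- rg2
  rg3$gene_id[5] <- "c1"
  expect_error(mergeOrthologGroups(rg3), "c1")
  # random overlap graphs against igraph connected components
  set.seed(13)
  for (i in 1:10) {
    ng <- 12
    anchors <- paste0("d", 1:6)
    rows <- do.call(rbind, lapply(seq_len(ng), function(g) {
      a <- sample(anchors, sample(0:2, 1))
      rbind(
        if (length(a)) data.frame(group_id = paste0("g", g),
                                  species = "Drosophila", gene_id = a,
                                  protein_length = 1),
        data.frame(group_id = paste0("g", g), species = "Cal",
                   gene_id = paste0("c", g), protein_length = 1)
      )
    }))
    fam <- mergeOrthologGroups(rows)
    got <- split(unique(rows$group_id),
                 fam$family_id[match(unique(rows$group_id), fam$group_id)])
    got <- unname(lapply(got, sort))
    # oracle: connected components of the group-anchor incidence graph
    dmel <- rows[rows$species == "Drosophila", ]
    g <- igraph::graph_from_edgelist(
      cbind(dmel$group_id, paste0("anchor_", dmel$gene_id)),
      directed = FALSE
    )
    g <- g + igraph::vertices(setdiff(unique(rows$group_id),
                                      igraph::V(g)$name))
    mem <- igraph::components(g)$membership
    grp <- names(mem)[!startsWith(names(mem), "anchor_")]
    want <- unname(lapply(split(grp, mem[grp]), sort))
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
  }
})

test_that("expansion detection uses strict ratios on counts and lengths", {
  mk <- function(cal_n, cal_len, others) {
    rows <- data.frame(
      family_id = "f", group_id = "g",
      species = rep("Cal", cal_n), gene_id = paste0("c", seq_len(cal_n)),
      protein_length = rep(cal_len / cal_n, cal_n)
    )
    for (sp in names(others)) {
      n <- others[[sp]][1]
      len <- others[[sp]][2]
      if (n > 0) {
        rows <- rbind(rows, data.frame(
          family_id = "f", group_id = "g", species = rep(sp, n),
          gene_id = paste0(sp, seq_len(n)),
          protein_length = rep(len / n, n)
        ))
      }
    }
    rows
  }
  # 4 genes / 2000 residues vs mean 2 genes / 1200: expanded
  fam <- mk(4, 2000, list(L1 = c(2, 1200), L2 = c(2, 1200)))
  expect_equal(detectExpansions(fam, "Cal"), "f")
  # count at exactly 1.5x the mean is not an expansion (strict)
  fam2 <- mk(3, 2000, list(L1 = c(2, 800), L2 = c(2, 800)))
  expect_equal(length(detectExpansions(fam2, "Cal")), 0)
  # count passes but length fails: conjunction required
  fam3 <- mk(4, 1500, list(L1 = c(2, 1200), L2 = c(2, 1200)))
  expect_equal(length(detectExpansions(fam3, "Cal")), 0)
  # background averages include species absent from the family
  fam4 <- mk(4, 2000, list(L1 = c(2, 1200)))
  expect_equal(
    detectExpansions(fam4, "Cal", backgroundSpecies = c("L1", "L2")), "f"
  )
  expect_error(detectExpansions(fam4, "nope"), "absent")
})
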