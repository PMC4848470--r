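test_that("neighbor joining reproduces the closed forms for 2 and 3 leaves", {
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighborJoining(d2)
  expect_equal(sum(t2$edge.length), 1.0)
  d3 <- matrix(c(0, 3, 8, 3, 0, 9, 8, 9, 0), 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  t3 <- neighborJoining(d3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[["A"]], (3 + 8 - 9) / 2)
  expect_equal(bl[["B"]], (3 + 9 - 8) / 2)
  expect_equal(bl[["C"]], (8 + 9 - 3) / 2)
  expect_error(neighborJoining(matrix(0, 1, 1)), "at least 2")
})

test_that("NJ is consistent on additive matrices and agrees with ape", {
  for (i in 1:20) {
    ra <- randomAdditive(sample(6:8, 1), seed = 100 + i)
    tr <- neighborJoining(ra$d)
    expect_equal(length(tr$edge.length), 2 * length(tr$tip.label) - 3)
    expect_equal(phangorn::RF.dist(tr, ra$tree), 0)
    expect_equal(phangorn::RF.dist(tr, ape::nj(ra$d)), 0)
    # branch lengths recover the generating tree exactly on additive input
    expect_equal(sum(tr$edge.length), sum(ra$tree$edge.length),
                 tolerance = 1e-8)
  }
})

test_that("species separation agrees with edge-removal enumeration", {
  spm <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  expect_true(speciesSeparation(readNewick(text = "((A1,A2),(B1,B2));"), spm))
  expect_false(speciesSeparation(readNewick(text = "((A1,B1),(A2,B2));"), spm))
  # random labeled trees vs the igraph oracle
  set.seed(17)
  for (i in 1:30) {
    tr <- ape::rtree(10, rooted = FALSE,
                     tip.label = paste0("t", 1:10))
    species <- setNames(sample(c("X", "Y"), 10, TRUE), tr$tip.label)
    if (length(unique(species)) < 2) next
    expect_equal(speciesSeparation(tr, species),
                 oracleSeparation(tr, species))
  }
  expect_error(
    speciesSeparation(readNewick(text = "((A1,A2),(B1,B2));"),
                      c(A1 = "A", A2 = "A", B1 = "B")),
    "no species"
  )
})

test_that("bootstrap support is deterministic and pinned on degenerate input", {
  seqs <- setNames(rep(strrep("ACGT", 75), 16),
                   hapNames(sprintf("s%02d", 1:8)))
  aln <- makeAln(seqs)
  spm <- setNames(c("A", "B", "B", "A", "B", "A", "B", "B"),
                  sprintf("s%02d", 1:8))
  # zero variation: every replicate is an all-tie star; with the
  # lexicographic tie-break and species interleaved among the labels the
  # deterministic join order never isolates one species (locked value)
  expect_equal(bootstrapSeparationSupport(aln, spm, 100, seed = 1), 0)
  expect_equal(
    bootstrapSeparationSupport(aln, spm, 100, seed = 1, level = "protein"),
    0
  )
  expect_equal(bootstrapSeparationSupport(aln, spm, 100, seed = 2), 0)
})

test_that("bootstrap support separates hotspot-like from background-like genes", {
  # strongly structured gene, 900 sites
  sim <- simulateDataset(simConfig(
    nGenes = 1, geneLenRange = c(300, 300), nMitoGenes = 0,
    fracHotspot = 1, fracUnconserved = 0, seed = 7
  ))
  g <- geneAlignments(sim$dataset)[[1]]
  sm <- specimenSpecies(sim$dataset)
  expect_gte(bootstrapSeparationSupport(g, sm, 100, seed = 7), 95)
  expect_gte(
    bootstrapSeparationSupport(g, sm, 100, seed = 7, level = "protein"), 95
  )
  # weakly diverged short genes rarely reach the hotspot threshold
  simbg <- simulateDataset(simConfig(
    nGenes = 50, geneLenRange = c(100, 100), nMitoGenes = 0,
    fracHotspot = 0, fracUnconserved = 0, seed = 7
  ))
  sup <- separationSupports(simbg$dataset, seed = 7)
  expect_gte(mean(sup$dna_support < 95), 0.9)
})

test_that("majority-rule consensus retains splits by occurrence count", {
  t1 <- readNewick(text = "((A,B),(C,D),E);")
  t2 <- readNewick(text = "((A,B),C,(D,E));")
  # 10 identical trees: same splits, all supports 100
  c10 <- majorityRuleConsensus(rep(list(t1), 10))
  expect_setequal(treeSplits(c10), treeSplits(t1))
  expect_setequal(setdiff(c10$node.label, ""), "100")
  # single tree behaves identically
  c1 <- majorityRuleConsensus(list(t1))
  expect_setequal(treeSplits(c1), treeSplits(t1))
  # 6 trees with {C,D}, 4 without: retained at support 60
  cons <- majorityRuleConsensus(c(rep(list(t1), 6), rep(list(t2), 4)))
  expect_true("C|D" %in% treeSplits(cons))
  expect_false("D|E" %in% treeSplits(cons))
  expect_true("60" %in% cons$node.label)
  # random tree sets: retained splits equal the oracle count filter
  set.seed(23)
  for (i in 1:10) {
    trees <- lapply(1:7, function(j) {
      ape::rtree(7, rooted = FALSE, tip.label = paste0("t", 1:7))
    })
    cons <- majorityRuleConsensus(trees, 0.5)
    counts <- table(unlist(lapply(trees, oracleSplits)))
    expected <- names(counts)[counts / 7 > 0.5]
    expect_setequal(treeSplits(cons), expected)
  }
  expect_error(majorityRuleConsensus(list(t1), 0.4), "0.5")
  expect_error(
    majorityRuleConsensus(list(t1, readNewick(text = "((A,B),(C,D),F);"))),
    "leaf set"
  )
})

test_that("random-split consensus is reproducible and finds strong structure", {
  sim <- simulateDataset(simConfig(
    nGenes = 10, nMitoGenes = 0, fracHotspot = 1, fracUnconserved = 0,
    seed = 31
  ))
  ds <- sim$dataset
  cc <- concatenateGenes(ds, names(geneAlignments(ds)))
  spm <- leafSpecies(cc, specimenSpecies(ds))
  r1 <- randomSplitConsensus(cc, k = 2, seed = 5)
  r2 <- randomSplitConsensus(cc, k = 2, seed = 5)
  expect_equal(writeNewick(r1$consensus), writeNewick(r2$consensus))
  # both halves of a strongly structured alignment separate the species
  expect_equal(speciesSplitSupport(r1$trees, spm), 100)
  expect_true(speciesSeparation(r1$consensus, spm))
  expect_error(randomSplitConsensus(cc, k = 1, seed = 1), "k must be")
})
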