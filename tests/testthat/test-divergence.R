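test_that("pDistance counts differences over comparable columns only", {
  expect_equal(pDistance("ACGT", "ACGT")[1:3],
               list(percent = 0, diffs = 0, comparable = 4))
  expect_equal(pDistance("ACGT", "ACGA")[1:3],
               list(percent = 25, diffs = 1, comparable = 4))
  expect_equal(pDistance("AC-T", "ACGT")[1:3],
               list(percent = 0, diffs = 0, comparable = 3))
  expect_equal(pDistance("ACNT", "ACGA")$comparable, 3)
  inc <- pDistance("NNNN", "ACGT")
  expect_true(inc$incomparable)
  expect_true(is.na(inc$percent))
  expect_error(pDistance("ACG", "ACGT"), "equal length")
  # symmetry and exact scaling on random strings
  set.seed(3)
  for (i in 1:20) {
    a <- paste(sample(c(DNA4, "N", "-"), 60, TRUE), collapse = "")
    b <- paste(sample(c(DNA4, "N", "-"), 60, TRUE), collapse = "")
    ab <- pDistance(a, b)
    ba <- pDistance(b, a)
    expect_equal(ab, ba)
    expect_lte(ab$diffs, ab$comparable)
    if (!ab$incomparable) {
      expect_equal(ab$percent, 100 * ab$diffs / ab$comparable)
    }
    o <- oraclePdist(a, b)
    expect_equal(ab$diffs, o$diffs)
    expect_equal(ab$comparable, o$comparable)
  }
})

test_that("translateCds follows the masking and stop rules", {
  expect_equal(translateCds("ATGAAA"), "MK")
  expect_equal(translateCds("ATGNNN"), "MX")
  expect_equal(translateCds("ATGA-A"), "MX")
  expect_warning(out <- translateCds("ATGTAAAAA"), "internal stop")
  expect_equal(out, "MXK")
  expect_equal(translateCds("ATGAA"), "M")       # trailing partial dropped
  expect_equal(translateCds("AATGAAA", 1), "MK") # frame offset
  # terminal stop masked without an internal-stop warning
  expect_no_warning(expect_equal(translateCds("ATGTAA"), "MX"))
})

test_that("geneProfile matches exhaustive pair enumeration", {
  # constructed 2-specimen (1 per species) case over 100 sites:
  # intra diffs {1, 2}, inter diffs {3, 4, 5, 6}
  base <- strrep("A", 100)
  sub <- function(s, pos, ch) {
    v <- strsplit(s, "")[[1]]
    v[pos] <- ch
    paste(v, collapse = "")
  }
  seqs <- c(
    s1_h1 = base,
    s1_h2 = sub(base, 1, "C"),
    s2_h1 = sub(base, 2:4, "G"),
    s2_h2 = sub(sub(base, 2:4, "G"), 5:6, "T")
  )
  spm <- c(s1 = "A", s2 = "B")
  prof <- geneProfile(makeAln(seqs), spm)
  o <- oracleDnaProfile(seqs, c(s1_h1 = "A", s1_h2 = "A",
                                s2_h1 = "B", s2_h2 = "B"))
  expect_equal(prof$dna_min_inter, o$dna_min_inter)
  expect_equal(prof$dna_min_inter, 3.0)
  expect_equal(prof$dna_max_intra, o$dna_max_intra)
  expect_equal(prof$dna_max_intra, 2.0)
  expect_equal(prof$count_min_inter, 3L)
  expect_equal(prof$count_max_intra, o$count_max_intra)
  expect_equal(prof$n_comparable_sites, 100L)

  # all haplotypes identical: every divergence and count is zero
  same <- setNames(rep(base, 4), names(seqs))
  p0 <- geneProfile(makeAln(same), spm)
  expect_equal(p0$dna_min_inter, 0)
  expect_equal(p0$prot_max_intra, 0)
  expect_equal(p0$count_min_inter, 0L)

  # one B haplotype equal to an A haplotype forces min inter of zero
  seqs2 <- seqs
  seqs2[["s2_h1"]] <- seqs[["s1_h1"]]
  expect_equal(geneProfile(makeAln(seqs2), spm)$dna_min_inter, 0)

  # random alignments against the oracle
  set.seed(11)
  for (i in 1:10) {
    mat <- replicate(8, paste(sample(c(DNA4, "N"), 90,
                                     prob = c(rep(0.23, 4), 0.08),
                                     replace = TRUE), collapse = ""))
    names(mat) <- hapNames(c("s1", "s2", "s3", "s4"))
    spm4 <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
    # random sequences are not real CDS: internal-stop warnings expected
    prof <- suppressWarnings(geneProfile(makeAln(mat), spm4))
    leafsp <- setNames(rep(c("A", "A", "B", "B"), each = 2), names(mat))
    o <- oracleDnaProfile(mat, leafsp)
    expect_equal(prof$dna_min_inter, o$dna_min_inter)
    expect_equal(prof$dna_max_intra, o$dna_max_intra)
    expect_equal(prof$count_min_inter, o$count_min_inter)
    expect_equal(prof$count_max_intra, o$count_max_intra)
  }
})

test_that("profiles are invariant to specimen order", {
  set.seed(4)
  seqs <- replicate(8, paste(sample(DNA4, 60, TRUE), collapse = ""))
  names(seqs) <- hapNames(c("s1", "s2", "s3", "s4"))
  spm <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  p1 <- suppressWarnings(geneProfile(makeAln(seqs), spm))
  p2 <- suppressWarnings(geneProfile(makeAln(seqs[sample(8)]), spm))
  for (f in c("dna_min_inter", "dna_max_intra", "prot_min_inter",
              "prot_max_intra", "count_min_inter", "count_max_intra")) {
    expect_equal(p2[[f]], p1[[f]], label = f)
  }
})

test_that("coverage filter applies the inclusive 50%-in-2-specimens rule", {
  specs <- data.frame(
    specimen_id = c("a1", "a2", "b1", "b2"),
    species = c("A", "A", "B", "B"),
    latitude = 0, longitude = 0, is_reference = FALSE, coverage = 10,
    mapped_noncoding_pct = 90, mapped_coding_pct = 95,
    het_pct = 1, het_coding_pct = 0.5
  )
  L <- 40
  good <- paste(rep("A", L), collapse = "")
  halfN <- paste(c(rep("N", L / 2), rep("A", L / 2)), collapse = "")
  allN <- paste(rep("N", L), collapse = "")
  mk <- function(gid, b1seq, b2seq) {
    makeAln(setNames(
      c(good, good, good, good, b1seq, b1seq, b2seq, b2seq),
      hapNames(c("a1", "a2", "b1", "b2"))
    ), geneId = gid)
  }
  ds <- phasedDataset(specs, list(
    mk("keep_full", good, good),
    mk("keep_boundary", halfN, halfN),   # exactly 50%: "no less than"
    mk("drop_allN", allN, allN),
    mk("drop_one_specimen", good, allN)  # only 1 qualifying B specimen
  ))
  expect_equal(coverageFilter(ds),
               c("keep_full", "keep_boundary"))
})

test_that("concatenation appends columns and preserves count arithmetic", {
  s4 <- c("s1", "s2")
  spm <- c(s1 = "A", s2 = "B")
  set.seed(8)
  g1 <- makeAln(setNames(replicate(4, paste(sample(DNA4, 30, TRUE),
                                            collapse = "")),
                         hapNames(s4)), geneId = "g1")
  g2 <- makeAln(setNames(replicate(4, paste(sample(DNA4, 60, TRUE),
                                            collapse = "")),
                         hapNames(s4)), geneId = "g2")
  specs <- data.frame(
    specimen_id = s4, species = c("A", "B"), latitude = 0, longitude = 0,
    is_reference = FALSE, coverage = 10, mapped_noncoding_pct = 90,
    mapped_coding_pct = 95, het_pct = 1, het_coding_pct = 0.5
  )
  ds <- phasedDataset(specs, list(g1, g2))
  cc <- concatenateGenes(ds, c("g1", "g2"))
  expect_equal(alignmentLength(cc), 90L)
  bounds <- attr(cc, "boundaries")
  expect_equal(bounds$end, c(30L, 90L))
  # p-distance on the concatenation equals the pooled per-gene counts
  for (pair in list(c("s1_h1", "s2_h1"), c("s1_h2", "s2_h2"))) {
    d1 <- pDistance(as.character(alignedSequences(g1))[
      match(pair[1], names(alignedSequences(g1)))],
      as.character(alignedSequences(g1))[
        match(pair[2], names(alignedSequences(g1)))])
    d2 <- pDistance(as.character(alignedSequences(g2))[
      match(pair[1], names(alignedSequences(g2)))],
      as.character(alignedSequences(g2))[
        match(pair[2], names(alignedSequences(g2)))])
    dc <- pDistance(as.character(alignedSequences(cc))[
      match(pair[1], names(alignedSequences(cc)))],
      as.character(alignedSequences(cc))[
        match(pair[2], names(alignedSequences(cc)))])
    expect_equal(dc$diffs, d1$diffs + d2$diffs)
    expect_equal(dc$comparable, d1$comparable + d2$comparable)
    expect_equal(dc$percent, 100 * (d1$diffs + d2$diffs) /
                   (d1$comparable + d2$comparable))
  }
  # single gene is the identity; empty list errors
  c1 <- concatenateGenes(ds, "g1")
  expect_equal(unname(as.character(alignedSequences(c1))),
               unname(as.character(alignedSequences(g1))))
  expect_equal(names(alignedSequences(c1)), names(alignedSequences(g1)))
  expect_error(concatenateGenes(ds, character()), "empty gene list")
})

test_that("hotspot-class genes separate inter from intra divergence", {
  sim <- simulateDataset(simConfig(
    nGenes = 100, nMitoGenes = 0, fracHotspot = 1, fracUnconserved = 0,
    seed = 21
  ))
  prof <- geneProfiles(sim$dataset)
  expect_gt(mean(prof$dna_min_inter), mean(prof$dna_max_intra))
  expect_gt(mean(prof$dna_min_inter - prof$dna_max_intra), 0.5)
})
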