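# Peak filtering, promoter assignment and candidate integration.

test_that("filter boundary semantics: M inclusive, P strict", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 100, 200), width = 50))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    peak_id = c("a", "b", "c"),
    m_value = c(0.5, 0.49, 0.8),
    p_value = c(0.049, 0.001, 0.05),
    location_class = "promoter", assigned_gene = NA_character_)
  kept <- S4Vectors::mcols(filterPeaks(gr))$peak_id
  expect_identical(kept, "a")   # M=0.5 retained; M=0.49 out; P=0.05 out
})

test_that("random tables re-filter identically to the row-by-row oracle", {
  for (s in 1:5) {
    set.seed(s)
    pk <- randomPeakGR(200)
    expect_identical(S4Vectors::mcols(filterPeaks(pk))$peak_id,
                     oracleFilterIds(pk, 0.5, 0.05))
  }
})

test_that("promoter containment, distance and strand orientation", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10000, 50000), width = 1),
                                  strand = c("+", "-"))
  names(genes) <- c("gPlus", "gMinus")
  pk <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(10000 - 100, 10000 + 600, 50000 + 100, 30000),
                     width = c(150, 100, 150, 200)))
  S4Vectors::mcols(pk) <- S4Vectors::DataFrame(
    peak_id = c("inWin", "outDown", "minusUp", "far"),
    m_value = 1, p_value = 0.01,
    location_class = "non_promoter", assigned_gene = NA_character_)
  res <- assignPeaksToGenes(pk, genes, promoterWindow = c(2000L, 500L))
  mc <- S4Vectors::mcols(res)
  expect_identical(mc$assigned_gene,
                   c("gPlus", NA, "gMinus", NA))
  expect_identical(mc$location_class,
                   c("promoter", "non_promoter", "promoter", "non_promoter"))
  expect_error(assignPeaksToGenes(
    GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 10)), genes), "chrZ")
})

test_that("random layouts match the exhaustive all-pairs overlap oracle", {
  for (s in 1:6) {
    set.seed(100 + s)
    genes <- randomGeneGR(20, maxPos = 2e5)     # dense: multi-overlaps occur
    pk <- randomPeakGR(50, maxPos = 2e5)
    res <- assignPeaksToGenes(pk, genes)
    expect_identical(S4Vectors::mcols(res)$assigned_gene,
                     oracleAssign(pk, genes, 2000L, 500L))
  }
})

test_that("candidate integration takes the max M and drops peakless genes", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:4 * 100, width = 50))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    peak_id = paste0("p", 1:4),
    m_value = c(0.6, 0.9, 0.7, 1.4),
    p_value = 0.01,
    location_class = c("promoter", "promoter", "promoter", "non_promoter"),
    assigned_gene = c("gA", "gA", "gA", "gB"))
  cands <- integrateCandidates(gr, c("gA", "gB", "gC"))
  expect_identical(as.character(cands$gene_id), "gA")
  expect_equal(cands$peak_m, 0.9)               # max over gA's peaks
  expect_equal(cands$n_peaks, 3L)
  withAny <- integrateCandidates(gr, c("gA", "gB", "gC"), anyLocation = TRUE)
  expect_setequal(as.character(withAny$gene_id), c("gA", "gB"))
  expect_warning(empty <- integrateCandidates(gr, "gZ"), "no responsive")
  expect_equal(nrow(empty), 0L)
})

test_that("planted candidates equal generator truth", {
  cfg <- simulationConfig(seed = 21L)
  study <- simulateStudy(cfg)
  expr <- study$expression
  truth <- study$truth
  cl <- fuzzyCMeans(buildProfiles(expr), c = 8L, seed = 21)
  responsive <- selectResponsiveGenes(cl)
  pk <- assignPeaksToGenes(filterPeaks(study$peaks), geneAnnotation(expr))
  cands <- integrateCandidates(pk, responsive)
  # expected: responsive genes with a planted passing promoter peak
  mc <- S4Vectors::mcols(study$peaks)
  plantedProm <- mc$planted_gene[mc$planted_pass &
                                   mc$location_class == "promoter"]
  expect_setequal(as.character(cands$gene_id),
                  intersect(plantedProm, responsive))
  expect_true(truth$driver %in% cands$gene_id)
})

test_that("filtering and assignment commute; wider windows never lose candidates", {
  set.seed(31)
  genes <- randomGeneGR(30, maxPos = 2e5)
  pk <- randomPeakGR(80, maxPos = 2e5)
  a <- assignPeaksToGenes(filterPeaks(pk), genes)
  b <- filterPeaks(assignPeaksToGenes(pk, genes))
  expect_identical(S4Vectors::mcols(a)$assigned_gene,
                   S4Vectors::mcols(b)$assigned_gene)
  resp <- names(genes)
  narrow <- suppressWarnings(
    integrateCandidates(assignPeaksToGenes(filterPeaks(pk), genes,
                                           c(500L, 100L)), resp))
  wide <- integrateCandidates(assignPeaksToGenes(filterPeaks(pk), genes,
                                                 c(5000L, 2000L)), resp)
  expect_gt(nrow(wide), 0L)
  expect_true(all(narrow$gene_id %in% wide$gene_id))
})
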