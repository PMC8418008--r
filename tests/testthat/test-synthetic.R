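# Synthetic-data generator: determinism, planted structure, input checks.

test_that("generators are deterministic under a fixed seed", {
  cfg <- simulationConfig(nGenes = 60L, seed = 7L)
  e1 <- generateExpression(cfg)
  e2 <- generateExpression(cfg)
  expect_identical(SummarizedExperiment::assay(e1), SummarizedExperiment::assay(e2))
  expect_identical(generatePeaks(cfg), generatePeaks(cfg))
  expect_identical(generateEnhancerSignal(100, 5, seed = 3),
                   generateEnhancerSignal(100, 5, seed = 3))
  expect_identical(generateViability(2, seed = 11),
                   generateViability(2, seed = 11))
})

test_that("noise-free genes sharing a pattern are perfectly correlated", {
  cfg <- simulationConfig(nGenes = 40L, noiseSd = 0, seed = 3L)
  m <- SummarizedExperiment::assay(generateExpression(cfg))
  truth <- S4Vectors::metadata(generateExpression(cfg))$truth
  pat <- truth$pattern
  bg <- setdiff(names(pat), c(truth$driver, truth$companions))
  same <- bg[pat[bg] == pat[bg][1L]]
  expect_gte(length(same), 2L)
  expect_equal(cor(m[same[1L], ], m[same[2L], ]), 1.0, tolerance = 1e-12)
})

test_that("planted driver degree reaches the filter threshold (all-pairs oracle)", {
  cfg <- simulationConfig(nGenes = 200L, noiseSd = 0.05, seed = 5L,
                          driver = driverSpec(targetDegree = 25L))
  expr <- generateExpression(cfg)
  truth <- S4Vectors::metadata(expr)$truth
  m <- SummarizedExperiment::assay(expr)
  # brute-force degree of the driver over all gene pairs
  deg <- 0L
  for (g in setdiff(rownames(m), truth$driver)) {
    ct <- cor.test(m[truth$driver, ], m[g, ])
    if (abs(ct$estimate) > 0.9 && ct$p.value < 0.05) deg <- deg + 1L
  }
  expect_gte(deg, 18L)
  expect_gte(deg, cfg@driver@targetDegree)   # companions all correlate
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(doses = c(5, 1, 0)), "strictly increasing")
  expect_error(simulationConfig(noiseSd = -0.1), "noiseSd")
  expect_error(simulationConfig(nGenes = 4L, nClustersPlanted = 8L),
               "nGenes")
  expect_error(generateEnhancerSignal(10, 10, seed = 1), "smaller")
  expect_error(generateViability(-1), "positive")
  expect_error(generateViability(2, doses = c(0, 1)), "positive")
})

test_that("planted peaks respect the configured filter fate", {
  cfg <- simulationConfig(seed = 2L)
  pk <- generatePeaks(cfg)
  mc <- S4Vectors::mcols(pk)
  truth <- S4Vectors::metadata(generateExpression(cfg))$truth
  drv <- mc[mc$planted_gene == truth$driver & mc$location_class == "promoter", ]
  expect_equal(nrow(drv), 1L)
  expect_equal(drv$m_value, cfg@driver@peakM)
  kept <- S4Vectors::mcols(filterPeaks(pk))$peak_id
  expect_setequal(kept, mc$peak_id[mc$planted_pass])
  decoys <- mc$peak_id[!mc$planted_pass]
  expect_length(intersect(kept, decoys), 0L)
})

test_that("pattern templates are near-orthogonal with decreasing TRC trio", {
  pt <- patternTemplates(8, c("TRC", "parental", "normal"), c(0, 1, 5))
  cc <- cor(t(pt$templates))
  diag(cc) <- 0
  expect_lt(max(abs(cc)), 0.5)
  expect_identical(which(pt$decreasing), 1:3)
  # TRC-block trend signs match the decreasing labels
  trc <- pt$conditions$context == "TRC"
  doses <- pt$conditions$dose[trc]
  trend <- pt$templates[, trc][, doses == max(doses)] -
           pt$templates[, trc][, doses == min(doses)]
  expect_true(all(trend[pt$decreasing] < 0))
  expect_true(all(trend[!pt$decreasing] > 0))
})

test_that("noise-free viability hits 50% inhibition at the true IC50", {
  v <- generateViability(2.5, hill = 2, doses = c(0.5, 1, 2.5, 5, 10),
                         noiseSd = 0, seed = 1)
  ctl <- mean(v$od[v$role == "control"])
  blk <- mean(v$od[v$role == "blank"])
  atIc50 <- v$od[v$role == "treated" & v$dose == 2.5]
  expect_equal(inhibitionRate(ctl, mean(atIc50), blk), 50, tolerance = 1e-9)
  # saturating dose approaches the upper asymptote
  vHigh <- generateViability(0.01, hill = 3, doses = c(0.1, 1, 10, 100, 1000),
                             noiseSd = 0, seed = 1)
  ctl <- mean(vHigh$od[vHigh$role == "control"])
  blk <- mean(vHigh$od[vHigh$role == "blank"])
  top <- inhibitionRate(ctl, vHigh$od[vHigh$role == "treated" &
                                        vHigh$dose == 1000][1L], blk)
  expect_equal(top, 100, tolerance = 0.01)
})
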