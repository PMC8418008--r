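# Correlation network, degree/pathway criteria, ranking, ego networks.

test_that("perfect affine copies are connected; the |r| threshold is strict", {
  set.seed(1)
  base <- rnorm(10)
  m <- rbind(gA = base, gB = 2 * base + 3, gC = rnorm(10))
  net <- buildPccNetwork(m)
  expect_true("gA|gB" %in% edgeKeys(net))
  # a pair whose |r| equals the threshold exactly must be excluded
  r <- cor(m["gA", ], m["gC", ])
  netAt <- buildPccNetwork(m[c("gA", "gC"), ], pccMin = abs(r))
  expect_equal(nrow(networkEdges(netAt)), 0L)
  netBelow <- buildPccNetwork(m[c("gA", "gC"), ], pccMin = abs(r) - 1e-9,
                              pMax = 1)
  expect_equal(nrow(networkEdges(netBelow)), 1L)
})

test_that("edge sets equal the independent cor.test oracle on random matrices", {
  for (s in 1:5) {
    set.seed(s)
    # block-correlated structure so edges actually occur
    base <- matrix(rnorm(50), 5, 10)
    m <- base[rep(1:5, each = 6), ] + matrix(rnorm(300, 0, 0.15), 30, 10)
    rownames(m) <- sprintf("g%02d", 1:30)
    net <- buildPccNetwork(m, pccMin = 0.8)
    expect_identical(edgeKeys(net), oraclePccEdges(m, 0.8, 0.05))
    expect_equal(sum(degrees(net)), 2L * nrow(networkEdges(net)))
  }
})

test_that("zero-variance genes are isolated and raising the threshold is monotone", {
  set.seed(7)
  m <- matrix(rnorm(100), 10, 10, dimnames = list(sprintf("g%02d", 1:10), NULL))
  m[3, ] <- 5                                     # constant gene
  net <- buildPccNetwork(m, pccMin = 0.3, pMax = 1)
  expect_equal(unname(degrees(net)["g03"]), 0L)
  loose <- buildPccNetwork(m, pccMin = 0.2, pMax = 1)
  tight <- buildPccNetwork(m, pccMin = 0.6, pMax = 1)
  expect_true(all(edgeKeys(tight) %in% edgeKeys(loose)))
  expect_true(all(degrees(tight) <= degrees(loose)))
})

test_that("degree filter boundary and star-graph behavior", {
  # star: hub connected to 20 noise-free leaves
  set.seed(8)
  base <- rnorm(12)
  m <- rbind(hub = base,
             t(sapply(1:20, function(i) i * base + i)))
  rownames(m) <- c("hub", sprintf("leaf%02d", 1:20))
  net <- buildPccNetwork(m)
  expect_equal(unname(degrees(net)["hub"]), 20L)
  expect_setequal(degreeFilter(net, 18L), rownames(m))  # clique: all pass
  d <- degrees(net)
  expect_setequal(degreeFilter(net, max(d)), names(d)[d == max(d)])
  empty <- new("CorrelationNetwork", nodes = c("a", "b"),
               edges = data.frame(geneA = character(), geneB = character(),
                                  pcc = numeric(), pValue = numeric()),
               degrees = c(a = 0L, b = 0L), pccMin = 0.9, pMax = 0.05)
  expect_length(degreeFilter(empty, 18L), 0L)
  # boundary: degree exactly 18 retained, 17 dropped
  nodes <- c("hub18", "hub17", sprintf("x%02d", 1:18), sprintf("y%02d", 1:17))
  e <- rbind(data.frame(geneA = "hub18", geneB = sprintf("x%02d", 1:18)),
             data.frame(geneA = "hub17", geneB = sprintf("y%02d", 1:17)))
  e$pcc <- 0.95; e$pValue <- 0.001
  deg <- table(factor(c(e$geneA, e$geneB), levels = nodes))
  net2 <- new("CorrelationNetwork", nodes = nodes, edges = e,
              degrees = setNames(as.integer(deg), nodes),
              pccMin = 0.9, pMax = 0.05)
  expect_true("hub18" %in% degreeFilter(net2, 18L))
  expect_false("hub17" %in% degreeFilter(net2, 18L))
})

test_that("pathway burden counts match the membership-scan oracle", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("RAS_SIGNALING\td\tgA\tgB", "CELL_CYCLE\td\tgA",
               "SET_X\td\tgA\tgC", "SET_Y\td\tgB"), path)
  cat0 <- readGmt(path)
  expect_equal(unname(pathwayBurden("gA", cat0)), c(3L, 2L))
  expect_equal(unname(pathwayBurden("gZ", cat0)), c(0L, 0L))
  set.seed(9)
  genes <- sprintf("g%03d", 1:40)
  sets <- lapply(1:50, function(i) sample(genes, sample(1:8, 1)))
  names(sets) <- sprintf("P%02d", 1:50)
  cat1 <- new("PathwayCatalog", sets = sets,
              descriptions = setNames(names(sets), names(sets)),
              oncogenic = setNames(runif(50) < 0.3, names(sets)))
  for (g in sample(genes, 10))
    expect_equal(unname(pathwayBurden(g, cat1)), oracleBurden(g, cat1))
})

test_that("priority ranking is lexicographic over the four criteria", {
  cands <- S4Vectors::DataFrame(
    gene_id = c("gHi", "gMemLo", "gMemHi", "gLowDeg"),
    peak_m = c(1.2, 0.8, 0.8, 1.4), n_peaks = 1L)
  nodes <- c("gHi", "gMemLo", "gMemHi", "gLowDeg")
  deg <- c(gHi = 30L, gMemLo = 20L, gMemHi = 20L, gLowDeg = 5L)
  e <- data.frame(geneA = character(), geneB = character(),
                  pcc = numeric(), pValue = numeric())
  net <- new("CorrelationNetwork", nodes = nodes, edges = e,
             degrees = c(gHi = 0L, gMemLo = 0L, gMemHi = 0L, gLowDeg = 0L),
             pccMin = 0.9, pMax = 0.05)
  net@degrees <- deg                       # synthetic degrees for ranking
  sets <- list(S1 = c("gHi", "gMemLo", "gMemHi"))
  cat1 <- new("PathwayCatalog", sets = sets, descriptions = c(S1 = "d"),
              oncogenic = c(S1 = TRUE))
  u <- rbind(gHi = c(0.9, 0.1), gMemLo = c(0.3, 0.7),
             gMemHi = c(0.8, 0.2), gLowDeg = c(0.9, 0.1))
  cl <- new("FuzzyClustering", centroids = matrix(0, 2, 2),
            memberships = u, fuzzifier = 1.25, objective = 1,
            conditions = S4Vectors::DataFrame(context = character(),
                                              dose = numeric()),
            converged = TRUE, iterations = 1L)
  expect_warning(
    rk <- priorityRank(cands, net, cat1, cl, topN = 10L, degreeMin = 18L),
    "3 candidates")
  expect_identical(as.character(rk$gene_id), c("gHi", "gMemHi", "gMemLo"))
  expect_identical(rk$priority_rank, 1:3)  # gLowDeg filtered out
  # memberships 0.8 vs 0.7 decide between the degree/pathway/peak ties
  expect_lt(which(rk$gene_id == "gMemHi"), which(rk$gene_id == "gMemLo"))
})

test_that("ranking is stable under gene-order permutation of the candidates", {
  cfg <- simulationConfig(seed = 33L)
  study <- simulateStudy(cfg)
  res <- prioritizeTargets(study$expression, study$peaks, study$catalog)
  cands <- res$candidates
  perm <- cands[rev(seq_len(nrow(cands))), ]
  rk2 <- priorityRank(perm, res$network, study$catalog, res$clustering)
  expect_identical(as.character(res$ranked$gene_id),
                   as.character(rk2$gene_id))
})

test_that("ego subnetworks equal the adjacency-scan oracle", {
  set.seed(10)
  base <- matrix(rnorm(60), 6, 10)
  m <- base[rep(1:6, each = 5), ] + matrix(rnorm(300, 0, 0.2), 30, 10)
  rownames(m) <- sprintf("g%02d", 1:30)
  net <- buildPccNetwork(m, pccMin = 0.7)
  for (center in sample(networkNodes(net), 5)) {
    ego <- egoSubnetwork(net, center)
    expect_setequal(setdiff(networkNodes(ego), center),
                    oracleNeighbors(net, center))
    # induced edges: all edges of the full net among the ego node set
    e <- networkEdges(net)
    keep <- e$geneA %in% networkNodes(ego) & e$geneB %in% networkNodes(ego)
    expect_equal(nrow(networkEdges(ego)), sum(keep))
  }
  iso <- networkNodes(net)[degrees(net) == 0]
  if (length(iso)) {
    ego0 <- egoSubnetwork(net, iso[1L])
    expect_identical(networkNodes(ego0), iso[1L])
    expect_equal(nrow(networkEdges(ego0)), 0L)
  }
  expect_error(egoSubnetwork(net, "nope"), "not in network")
})
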