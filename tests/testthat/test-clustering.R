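# Profile construction and fuzzy c-means.

test_that("standardization follows the sample-sd convention", {
  # two conditions, replicate pairs (2,2) and (4,4): means (2,4),
  # deviations +/-1, sample sd sqrt(2) -> profile (-0.7071, +0.7071)
  e <- makeExperiment(matrix(c(2, 2, 4, 4), 1, 4),
                      contexts = "TRC", doses = c(0, 1), reps = 2L)
  p <- buildProfiles(e)
  expect_equal(as.numeric(profileMatrix(p)), c(-1, 1) / sqrt(2),
               tolerance = 1e-12)
  pPop <- buildProfiles(e, sdMethod = "population")
  expect_equal(as.numeric(profileMatrix(pPop)), c(-1, 1), tolerance = 1e-12)
})

test_that("zero-variance genes are skipped, and standardization is idempotent", {
  vals <- rbind(c(5, 5, 5, 5, 5, 5), c(1, 1, 2, 2, 6, 6))
  rownames(vals) <- c("flat", "var")
  e <- makeExperiment(vals, contexts = "TRC", doses = c(0, 1, 5), reps = 2L)
  p <- buildProfiles(e)
  expect_identical(skippedGenes(p), "flat")
  expect_identical(rownames(profileMatrix(p)), "var")
  # feed the standardized profile back as a 1-replicate experiment
  e2 <- makeExperiment(profileMatrix(p), contexts = "TRC",
                       doses = c(0, 1, 5), reps = 1L)
  expect_equal(profileMatrix(buildProfiles(e2)), profileMatrix(p),
               tolerance = 1e-12)
})

test_that("single-cluster fit gives unit memberships and the mean centroid", {
  set.seed(1)
  x <- matrix(rnorm(60), 12, 5)
  cl <- fuzzyCMeans(x, c = 1L, m = 1.25, seed = 1)
  expect_true(all(memberships(cl) == 1))
  expect_equal(as.numeric(centroids(cl)), colMeans(x), tolerance = 1e-9)
})

test_that("membership rows sum to 1 at every iteration and the objective never increases", {
  set.seed(2)
  x <- matrix(rnorm(200), 40, 5)
  for (it in 1:6) {
    cl <- fuzzyCMeans(x, c = 4L, m = 1.3, seed = 2, maxIter = it)
    expect_true(all(abs(rowSums(memberships(cl)) - 1) < 1e-9))
  }
  cl <- fuzzyCMeans(x, c = 4L, m = 1.3, seed = 2)
  expect_true(all(diff(cl@objective) <= 1e-9))
  expect_true(cl@converged)
})

test_that("near-hard fuzzifier matches the exhaustive 2-partition oracle on 12 points", {
  set.seed(3)
  x <- rbind(matrix(rnorm(12, 0, 0.3), 6, 2),
             matrix(rnorm(12, 5, 0.3), 6, 2))
  cl <- fuzzyCMeans(x, c = 2L, m = 1.05, seed = 3)
  hard <- apply(memberships(cl), 1L, which.max) - 1L
  best <- oracleBest2Partition(x)
  same <- identical(hard, best$assign) ||
    identical(hard, 1L - best$assign)       # label swap
  expect_true(same)
})

test_that("permuting genes permutes memberships; relabeling preserves selection", {
  set.seed(4)
  cfg <- simulationConfig(nGenes = 64L, seed = 4L)
  prof <- buildProfiles(generateExpression(cfg))
  cl <- fuzzyCMeans(prof, c = 8L, seed = 4)
  x <- profileMatrix(prof)
  perm <- sample(nrow(x))
  clP <- fuzzyCMeans(x[perm, ], c = 8L, seed = 4)
  # centroids may be found in a different order; compare via assignment sets
  sel1 <- sort(selectResponsiveGenes(fuzzyCMeans(prof, c = 8L, seed = 11)))
  sel2 <- sort(selectResponsiveGenes(fuzzyCMeans(prof, c = 8L, seed = 4)))
  expect_identical(sel1, sel2)              # cluster relabeling irrelevant
  expect_setequal(rownames(memberships(clP)), rownames(memberships(cl)))
})

test_that("fixed point agrees with an independent fuzzy c-means implementation", {
  skip_if_not_installed("e1071")
  set.seed(5)
  cfg <- simulationConfig(nGenes = 80L, seed = 5L)
  x <- profileMatrix(buildProfiles(generateExpression(cfg)))
  cl <- fuzzyCMeans(x, c = 8L, m = 1.25, seed = 5, tol = 1e-9)
  ref <- e1071::cmeans(x, centers = centroids(cl), m = 1.25,
                       iter.max = 200)
  expect_equal(unname(ref$centers), unname(centroids(cl)), tolerance = 1e-4)
  expect_equal(unname(ref$membership), unname(memberships(cl)),
               tolerance = 1e-4)
})

test_that("responsive-gene selection honors direction, boundary and planted labels", {
  # hand-built clustering: 6 clusters, cluster 1 decreasing in TRC
  cond <- S4Vectors::DataFrame(context = rep(c("TRC", "parental"), each = 2),
                               dose = rep(c(0, 5), 2))
  cen <- rbind(c(1, -1, 0, 0), matrix(c(-1, 1, 0, 0), 5, 4, byrow = TRUE))
  u <- rbind(atBoundary = c(0.2, rep(0.16, 5)),
             below      = c(0.19, rep(0.162, 5)),
             elsewhere  = c(0.05, 0.75, rep(0.05, 4)))
  cl <- new("FuzzyClustering", centroids = cen, memberships = u,
            fuzzifier = 1.25, objective = 1, conditions = cond,
            converged = TRUE, iterations = 1L)
  sel <- selectResponsiveGenes(cl, "down", threshold = 0.2)
  expect_equal(sel, "atBoundary", ignore_attr = TRUE)      # 0.2 inclusive
  expect_identical(attr(sel, "clusters"), 1L)
  up <- selectResponsiveGenes(cl, "up", threshold = 0.2)
  expect_true("elsewhere" %in% up)
  # all centroids increasing + direction down -> empty with warning
  clUp <- new("FuzzyClustering", centroids = cen[-1, ][1:2, ],
              memberships = matrix(0.5, 3, 2,
                                   dimnames = list(rownames(u), NULL)),
              fuzzifier = 1.25, objective = 1, conditions = cond,
              converged = TRUE, iterations = 1L)
  expect_warning(res <- selectResponsiveGenes(clUp, "down"), "no cluster")
  expect_length(res, 0L)
})

test_that("selection recovers the planted decreasing genes on the default design", {
  cfg <- simulationConfig(seed = 17L)   # noiseSd 0.05
  expr <- generateExpression(cfg)
  truth <- S4Vectors::metadata(expr)$truth
  cl <- fuzzyCMeans(buildProfiles(expr), c = 8L, seed = 17)
  sel <- selectResponsiveGenes(cl, "down", threshold = 0.2)
  planted <- names(truth$pattern)[truth$pattern %in% truth$decreasingPatterns]
  overlap <- length(intersect(sel, planted)) /
    length(union(sel, planted))
  expect_gte(overlap, 0.95)
})

test_that("degenerate clustering inputs are rejected", {
  x <- matrix(rnorm(20), 4, 5)
  expect_error(fuzzyCMeans(x, c = 5L), "at least c profiles")
  expect_error(fuzzyCMeans(x, c = 2L, m = 1), "m must be > 1")
  x[1, 1] <- NA
  expect_error(fuzzyCMeans(x, c = 2L), "finite")
})
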