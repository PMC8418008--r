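# Dose-response profile construction and fuzzy c-means clustering.
#
# Profiles are condition (context x dose) means standardized per gene; the
# soft clustering follows the classic fuzzy c-means alternating scheme used
# by the Mfuzz family of tools, with a deterministic farthest-point
# initialization so a seed fully determines the result.

#' Build standardized per-gene dose-response profiles
#'
#' Replicates are averaged per condition (context x dose, context-major
#' order), then each gene is standardized to mean 0 / sd 1 across
#' conditions. The default sd uses the n-1 (sample) denominator, the
#' convention of Mfuzz's `standardise`; set `sdMethod = "population"` for
#' the n denominator. Genes with zero variance across conditions cannot be
#' standardized; they are excluded and recorded in the skip list.
#'
#' @param x a [DoseResponseExperiment-class]
#' @param standardize logical; set FALSE to keep raw condition means.
#' @param sdMethod "sample" (default) or "population".
#' @return a [ResponseProfiles-class]
#' @export
buildProfiles <- function(x, standardize = TRUE,
                          sdMethod = c("sample", "population")) {
  stopifnot(is(x, "DoseResponseExperiment"))
  sdMethod <- match.arg(sdMethod)
  cd <- colData(x)
  ctxLevels <- if (is.factor(cd$context)) levels(cd$context)
               else unique(as.character(cd$context))
  doseLevels <- sort(unique(cd$dose))
  if (length(ctxLevels) * length(doseLevels) < 2L)
    stop("need at least 2 conditions")
  cond <- expand.grid(dose = doseLevels, context = ctxLevels,
                      KEEP.OUT.ATTRS = FALSE)[, c("context", "dose")]
  m <- assay(x, "log2expr")
  prof <- matrix(NA_real_, nrow(m), nrow(cond),
                 dimnames = list(rownames(m), NULL))
  for (j in seq_len(nrow(cond))) {
    sel <- as.character(cd$context) == as.character(cond$context[j]) &
           cd$dose == cond$dose[j]
    if (!any(sel))
      stop("no samples for condition ", cond$context[j], " dose ",
           cond$dose[j])
    prof[, j] <- rowMeans(m[, sel, drop = FALSE])
  }
  skipped <- character()
  if (standardize) {
    mu <- rowMeans(prof)
    cent <- prof - mu
    denom <- if (sdMethod == "sample") ncol(prof) - 1L else ncol(prof)
    sds <- sqrt(rowSums(cent^2) / denom)
    zero <- sds < 1e-12
    skipped <- rownames(prof)[zero]
    prof <- cent[!zero, , drop = FALSE] / sds[!zero]
  }
  new("ResponseProfiles",
      profiles = prof,
      conditions = DataFrame(context = as.character(cond$context),
                             dose = cond$dose),
      skipped = skipped,
      standardized = standardize,
      sdMethod = sdMethod)
}

# Deterministic farthest-point seeding: first centroid is a seeded random
# point, each next is the point farthest from all chosen so far (ties to the
# lowest row index).
.seedCentroids <- function(x, c, seed) {
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(x), 1L)
  for (j in seq_len(c - 1L)) {
    d2 <- vapply(seq_len(nrow(x)), function(i)
      min(colSums((t(x[idx, , drop = FALSE]) - x[i, ])^2)), numeric(1))
    idx <- c(idx, which.max(d2))     # which.max takes the lowest index on ties
  }
  x[idx, , drop = FALSE]
}

.fcmMemberships <- function(d2, m) {
  # u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1)), computed on distances divided
  # by the row minimum to keep the powers in range for small m; rows that
  # hit a centroid exactly get hard memberships.
  pow <- 1 / (m - 1)
  zero <- d2 < 1e-24
  anyZero <- rowSums(zero) > 0L
  rmin <- pmax(apply(d2, 1L, min), 1e-24)
  u <- (d2 / rmin)^(-pow)
  u <- u / rowSums(u)
  if (any(anyZero)) {
    u[anyZero, ] <- 0
    u[zero] <- 1
    u[anyZero, ] <- u[anyZero, , drop = FALSE] /
      rowSums(u[anyZero, , drop = FALSE])
  }
  u
}

#' Fuzzy c-means clustering of response profiles
#'
#' Iteratively minimizes the fuzzy c-means objective
#' \deqn{J = \sum_i \sum_j u_{ij}^m \, \lVert x_i - v_j \rVert^2}
#' with Euclidean distance, memberships
#' \eqn{u_{ij} = [\sum_k (d_{ij}/d_{ik})^{2/(m-1)}]^{-1}} and
#' membership-weighted centroid updates. Convergence is declared when the
#' largest centroid coordinate shift falls below `tol`. Membership rows sum
#' to 1 after every iteration and the recorded objective trace is
#' non-increasing.
#'
#' @param profiles a [ResponseProfiles-class] or a plain numeric matrix
#'   (rows = items).
#' @param c number of clusters (default 8, the pattern count used
#'   throughout this pipeline).
#' @param m fuzzifier (> 1; default 1.25, a common choice for standardized
#'   expression profiles).
#' @param seed integer seed for the deterministic farthest-point
#'   initialization.
#' @param maxIter,tol iteration cap and centroid-shift tolerance.
#' @return a [FuzzyClustering-class]
#' @export
fuzzyCMeans <- function(profiles, c = 8L, m = 1.25, seed = 1L,
                        maxIter = 200L, tol = 1e-6) {
  cond <- DataFrame(context = character(), dose = numeric())[integer(), ]
  if (is(profiles, "ResponseProfiles")) {
    cond <- profiles@conditions
    x <- profiles@profiles
  } else x <- as.matrix(profiles)
  if (!all(is.finite(x))) stop("profiles must be finite")
  c <- as.integer(c)
  if (c < 1L) stop("c must be >= 1")
  if (m <= 1) stop("fuzzifier m must be > 1")
  if (nrow(x) < c) stop("need at least c profiles (", c, ")")

  v <- .seedCentroids(x, c, seed)
  obj <- numeric()
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(v) +
      outer(rep(1, nrow(x)), rowSums(v^2))
    d2 <- pmax(d2, 0)
    u <- .fcmMemberships(d2, m)
    um <- u^m
    vNew <- (t(um) %*% x) / colSums(um)
    empty <- !is.finite(rowSums(vNew))
    vNew[empty, ] <- v[empty, ]
    d2New <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(vNew) +
      outer(rep(1, nrow(x)), rowSums(vNew^2))
    obj <- c(obj, sum(um * pmax(d2New, 0)))
    shift <- max(abs(vNew - v))
    v <- vNew
    if (shift < tol) { converged <- TRUE; break }
    if (iter >= maxIter) break
  }
  rownames(u) <- rownames(x)
  rownames(v) <- paste0("cluster", seq_len(c))
  new("FuzzyClustering",
      centroids = v, memberships = u, fuzzifier = m,
      objective = obj, conditions = cond,
      converged = converged, iterations = iter)
}

#' Select dose-responsive genes by cluster trend and membership
#'
#' Clusters are called "down" ("up") when the centroid at the highest dose
#' is below (above) the centroid at the zero/lowest dose within the
#' trend context block (by default the first context, i.e. the TRC block,
#' since the oncogene rationale concerns the TRC response; set
#' `trendScope = "all"` to average the trend over all contexts). A gene is
#' selected when its argmax-membership cluster is among the matching
#' clusters and that maximal membership is >= `threshold` (boundary
#' inclusive, so a membership of exactly 0.2 passes the default filter).
#'
#' @param clustering a [FuzzyClustering-class] with condition annotation.
#' @param direction "down" (default; the oncogene-oriented choice) or "up".
#' @param threshold membership threshold (default 0.2).
#' @param trendContext context label used for the trend call; default the
#'   first context present.
#' @param trendScope "context" (default) or "all".
#' @return character vector of selected gene ids, with the matching cluster
#'   indices in `attr(., "clusters")`. Empty (with a warning) when no
#'   cluster matches the direction.
#' @export
selectResponsiveGenes <- function(clustering, direction = c("down", "up"),
                                  threshold = 0.2, trendContext = NULL,
                                  trendScope = c("context", "all")) {
  direction <- match.arg(direction)
  trendScope <- match.arg(trendScope)
  cond <- clustering@conditions
  if (!nrow(cond))
    stop("clustering carries no condition annotation; cluster a ",
         "ResponseProfiles object to use trend-based selection")
  v <- clustering@centroids
  if (trendScope == "context") {
    if (is.null(trendContext)) trendContext <- cond$context[1L]
    sel <- cond$context == trendContext
    if (!any(sel)) stop("unknown trend context: ", trendContext)
  } else sel <- rep(TRUE, nrow(cond))
  doses <- cond$dose[sel]
  lo <- which(sel)[doses == min(doses)]
  hi <- which(sel)[doses == max(doses)]
  trend <- rowMeans(v[, hi, drop = FALSE]) - rowMeans(v[, lo, drop = FALSE])
  clusters <- if (direction == "down") which(trend < 0) else which(trend > 0)
  if (!length(clusters)) {
    warning("no cluster centroid matches direction '", direction, "'")
    out <- character()
    attr(out, "clusters") <- integer()
    return(out)
  }
  u <- clustering@memberships
  amax <- apply(u, 1L, which.max)
  umax <- u[cbind(seq_len(nrow(u)), amax)]
  keep <- amax %in% clusters & umax >= threshold
  out <- rownames(u)[keep]
  attr(out, "clusters") <- as.integer(clusters)
  out
}
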