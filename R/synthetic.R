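# Synthetic multi-omic study generator with planted ground truth.
#
# The generator emulates the design of a dose-escalation study in three cell
# contexts (tumor-repopulating cells, the parental cancer line, and a normal
# liver analog) treated at 0 / 1 / 5 uM of a retinoid, with RNA expression,
# factor-binding peaks, an H3K27ac enhancer landscape, a pathway catalog and
# CCK-8 style viability plates. One "driver" gene is planted with evidence on
# all four ranking criteria so the full pipeline can be validated against
# known truth.

#' Construct a planted-driver specification
#'
#' Defaults plant evidence strictly above every default pipeline threshold:
#' 25 correlated companions (degree filter is 18), 6 pathways of which 4 are
#' oncogenic, a promoter peak at M = 1.2 (filter is 0.5), and a
#' dose-decreasing expression pattern (membership filter is 0.2).
#'
#' @param targetDegree planted number of correlated companion genes.
#' @param nPathways pathways containing the driver in the generated catalog.
#' @param nOncogenic how many of those carry the oncogenic flag.
#' @param peakM M-value of the driver's promoter peak.
#' @param clusterPattern planted pattern index the driver follows; must be a
#'   decreasing pattern (the first `length(contexts)` patterns are).
#' @param membershipFloor minimum membership the design should achieve.
#' @return a [DriverSpec-class]
#' @export
driverSpec <- function(targetDegree = 25L, nPathways = 6L, nOncogenic = 4L,
                       peakM = 1.2, clusterPattern = 1L,
                       membershipFloor = 0.2) {
  new("DriverSpec",
      targetDegree    = as.integer(targetDegree),
      nPathways       = as.integer(nPathways),
      nOncogenic      = as.integer(nOncogenic),
      peakM           = as.numeric(peakM),
      clusterPattern  = as.integer(clusterPattern),
      membershipFloor = as.numeric(membershipFloor))
}

#' Construct a synthetic study configuration
#'
#' The defaults are the study conditions all recovery benchmarks in this
#' package use: 200 genes, 3 contexts x doses 0/1/5 uM x 3 replicates,
#' 8 planted expression patterns, and additive noise of 0.05 on the log2
#' scale.
#'
#' @param nGenes total number of genes.
#' @param contexts ordered context labels; the first is the TRC context.
#' @param doses strictly increasing dose levels (uM).
#' @param nReplicates replicates per condition.
#' @param nClustersPlanted number of planted expression patterns.
#' @param noiseSd SD of Gaussian noise added to each log2 measurement.
#' @param driver a [DriverSpec-class].
#' @param seed integer RNG seed.
#' @param peakFraction fraction of background genes receiving a ChIP peak.
#' @param decoyFraction fraction of those planted to fail the default filter.
#' @param promoterFraction fraction of passing peaks placed in promoters.
#' @param nPathwaysCatalog pathways in the generated catalog.
#' @return a [SimulationConfig-class]
#' @export
simulationConfig <- function(nGenes = 200L,
                             contexts = c("TRC", "parental", "normal"),
                             doses = c(0, 1, 5),
                             nReplicates = 3L,
                             nClustersPlanted = 8L,
                             noiseSd = 0.05,
                             driver = driverSpec(),
                             seed = 1L,
                             peakFraction = 0.4,
                             decoyFraction = 0.4,
                             promoterFraction = 0.75,
                             nPathwaysCatalog = 30L) {
  new("SimulationConfig",
      nGenes           = as.integer(nGenes),
      contexts         = as.character(contexts),
      doses            = as.numeric(doses),
      nReplicates      = as.integer(nReplicates),
      nClustersPlanted = as.integer(nClustersPlanted),
      noiseSd          = as.numeric(noiseSd),
      driver           = driver,
      seed             = as.integer(seed),
      peakFraction     = as.numeric(peakFraction),
      decoyFraction    = as.numeric(decoyFraction),
      promoterFraction = as.numeric(promoterFraction),
      nPathwaysCatalog = as.integer(nPathwaysCatalog))
}

# Orthonormal contrast helpers ------------------------------------------------

.unitize <- function(v) v / sqrt(sum(v^2))

# Orthonormal context contrasts: the constant direction first, then
# normalized Helmert contrasts oriented so the first (TRC) component is
# positive wherever it is nonzero - the dose-trend sign of every template
# then follows directly from its dose factor.
.contextContrasts <- function(nc) {
  out <- list(rep(1, nc) / sqrt(nc))
  if (nc > 1L) {
    h <- stats::contr.helmert(nc)
    for (j in seq_len(ncol(h))) {
      v <- .unitize(h[, j])
      nz <- which(v != 0)[1L]
      if (v[nz] < 0) v <- -v
      out[[j + 1L]] <- v
    }
  }
  out
}

#' Planted dose-response pattern templates
#'
#' Builds `k` mutually near-orthogonal (context x dose) mean-expression
#' templates on the log2 scale. The first `length(contexts)` templates are
#' strictly decreasing with dose in the TRC (first) context; the remaining
#' templates (dose-transient and context-level shapes) carry a small positive
#' dose tilt in the TRC block so that no template has an exactly flat TRC
#' trend. Orthogonality keeps between-pattern expression correlations far
#' from the network edge threshold, so planted co-expression cliques are
#' unambiguous.
#'
#' @param k number of templates.
#' @param contexts context labels (first = TRC).
#' @param doses dose levels.
#' @param amplitude multiplier applied to the unit templates (log2 units).
#' @return list with `templates` (k x (contexts*doses) matrix, columns
#'   ordered context-major then dose), `decreasing` (logical per template)
#'   and `conditions` (data.frame of context/dose per column).
#' @export
patternTemplates <- function(k, contexts, doses, amplitude = 3) {
  nc <- length(contexts)
  nd <- length(doses)
  if (nd < 2L) stop("need at least 2 dose levels")
  t01 <- (seq_len(nd) - 1) / (nd - 1)
  L <- .unitize(t01 - mean(t01))                       # linear dose trend
  Q <- NULL
  if (nd >= 3L) {
    q <- (t01 - mean(t01))^2
    q <- q - mean(q)
    q <- q - sum(q * L) * L                            # orthogonalize
    if (sum(q^2) > 1e-12) Q <- .unitize(q)
  }
  K <- rep(1, nd) / sqrt(nd)                           # dose-constant
  ctx <- .contextContrasts(nc)

  outer2 <- function(dose, context) as.vector(outer(dose, context))
  # columns context-major: value[dose, context] flattened with dose fastest
  # within each context; we build as outer(dose, context) then flatten,
  # giving (dose1ctx1, dose2ctx1, ..., dose1ctx2, ...).
  cand <- list()
  decr <- logical()
  for (j in seq_len(nc)) {                             # decreasing patterns
    cand[[length(cand) + 1L]] <- outer2(-L, ctx[[j]])
    decr <- c(decr, TRUE)
  }
  if (!is.null(Q)) {
    for (j in seq_len(nc)) {                           # transient + tilt
      cand[[length(cand) + 1L]] <- outer2(Q, ctx[[j]]) + 0.15 * outer2(L, ctx[[j]])
      decr <- c(decr, FALSE)
    }
  }
  if (nc > 1L) {
    for (j in 2:nc) {                                  # context-level + tilt
      tiltCtx <- ctx[[if (j == 2L) 1L else 2L]]
      cand[[length(cand) + 1L]] <- outer2(K, ctx[[j]]) + 0.15 * outer2(L, tiltCtx)
      decr <- c(decr, FALSE)
    }
  }
  if (k > length(cand))
    stop("cannot build ", k, " distinct patterns for this layout (max ",
         length(cand), ")")
  tmpl <- amplitude * do.call(rbind, cand[seq_len(k)])
  conditions <- data.frame(
    context = factor(rep(contexts, each = nd), levels = contexts),
    dose    = rep(doses, nc))
  list(templates = tmpl, decreasing = decr[seq_len(k)],
       conditions = conditions)
}

# Deterministic study layout shared by all generators for one config:
# gene ids, coordinates, driver/companion selection, pattern assignment.
.studyLayout <- function(config) {
  n <- config@nGenes
  geneIds <- sprintf("G%04d", seq_len(n))
  set.seed(config@seed)
  driverIdx <- sample.int(n, 1L)
  companionIdx <- sample(setdiff(seq_len(n), driverIdx),
                         config@driver@targetDegree)
  background <- setdiff(seq_len(n), c(driverIdx, companionIdx))
  pattern <- integer(n)
  pattern[background] <-
    ((seq_along(background) - 1L) %% config@nClustersPlanted) + 1L
  pattern[driverIdx] <- config@driver@clusterPattern
  pattern[companionIdx] <- config@driver@clusterPattern
  role <- rep("background", n)
  role[driverIdx] <- "driver"
  role[companionIdx] <- "companion"
  list(geneIds = geneIds, driverIdx = driverIdx,
       companionIdx = companionIdx, backgroundIdx = background,
       pattern = pattern, role = role,
       chrom = "chrS",
       tss = (seq_len(n) - 1L) * 50000L,
       strand = rep(c("+", "-"), length.out = n))
}

.derivedSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

#' Generate a synthetic dose-response expression experiment
#'
#' Every non-driver, non-companion gene follows one of the planted pattern
#' templates (round-robin assignment) plus a gene-specific baseline and
#' Gaussian noise. The driver follows its configured (decreasing) pattern,
#' and exactly `targetDegree` companion genes are noisy affine copies of the
#' driver's condition-mean profile, guaranteeing a planted co-expression
#' clique around the driver.
#'
#' Gene coordinates use a synthetic single-chromosome layout (genes tiled
#' every 50 kb, TSS at the gene start, alternating strand).
#'
#' @param config a [SimulationConfig-class]
#' @return a [DoseResponseExperiment-class]; `metadata(.)$truth` records the
#'   driver, companions, per-gene pattern and which patterns are decreasing.
#' @export
generateExpression <- function(config) {
  validObject(config)
  lay <- .studyLayout(config)            # also seeds the RNG deterministically
  n <- config@nGenes
  pats <- patternTemplates(config@nClustersPlanted, config@contexts,
                           config@doses)
  nCond <- nrow(pats$conditions)
  baseline <- stats::rnorm(n, mean = 8, sd = 1)
  mu <- matrix(0, n, nCond)
  for (g in seq_len(n))
    mu[g, ] <- baseline[g] + pats$templates[lay$pattern[g], ]
  # companions: affine copies of the driver's condition-mean profile
  for (ci in lay$companionIdx) {
    b <- stats::runif(1, 0.7, 1.3)
    a <- stats::rnorm(1, 0, 0.5)
    mu[ci, ] <- a + b * mu[lay$driverIdx, ] + (1 - b) * 8
  }
  reps <- config@nReplicates
  cond <- pats$conditions
  sampleMeta <- data.frame(
    context   = factor(rep(cond$context, each = reps),
                       levels = config@contexts),
    dose      = rep(cond$dose, each = reps),
    replicate = rep(seq_len(reps), times = nCond))
  sampleIds <- sprintf("%s_d%s_r%d", as.character(sampleMeta$context),
                       format(sampleMeta$dose, trim = TRUE),
                       sampleMeta$replicate)
  m <- mu[, rep(seq_len(nCond), each = reps), drop = FALSE]
  m <- m + matrix(stats::rnorm(length(m), 0, config@noiseSd), nrow(m))
  dimnames(m) <- list(lay$geneIds, sampleIds)
  se <- SummarizedExperiment(
    assays = list(log2expr = m),
    colData = DataFrame(sampleMeta, row.names = sampleIds),
    rowData = DataFrame(chrom = lay$chrom, tss = lay$tss,
                        strand = lay$strand, pattern = lay$pattern,
                        role = lay$role, row.names = lay$geneIds))
  out <- new("DoseResponseExperiment", se)
  metadata(out)$truth <- list(
    driver = lay$geneIds[lay$driverIdx],
    companions = lay$geneIds[lay$companionIdx],
    pattern = stats::setNames(lay$pattern, lay$geneIds),
    decreasingPatterns = which(pats$decreasing))
  validObject(out)
  out
}

#' Generate a synthetic factor-binding peak table
#'
#' The driver gene always receives a promoter peak at the configured M-value
#' with P < 0.05. A `peakFraction` of background genes receives one peak
#' each; `decoyFraction` of those are planted to fail the default
#' M >= 0.5 / P < 0.05 filter, and passing peaks are placed in the promoter
#' window with probability `promoterFraction` (otherwise in the gene body,
#' well away from any promoter). Companion genes never receive passing
#' promoter peaks, so the driver is the only gene whose planted clique also
#' carries top binding evidence.
#'
#' @param config a [SimulationConfig-class]
#' @return GRanges (0-based coordinates on disk; 1-based in R) with mcols
#'   `peak_id`, `m_value`, `p_value`, `location_class`, `assigned_gene`
#'   (NA until assignment) and planted-truth columns `planted_pass`,
#'   `planted_gene`.
#' @export
generatePeaks <- function(config) {
  validObject(config)
  lay <- .studyLayout(config)
  set.seed(.derivedSeed(config@seed, 104729))
  rows <- list()
  addPeak <- function(geneIdx, promoter, m, p, pass) {
    tss <- lay$tss[geneIdx]
    minus <- lay$strand[geneIdx] == "-"
    if (promoter) {
      off <- round(stats::runif(1, -1200, 100))
      w <- round(stats::runif(1, 200, 600))
    } else {
      off <- round(stats::runif(1, 8000, 40000))
      w <- round(stats::runif(1, 300, 1500))
    }
    start0 <- if (minus) tss - off - w else tss + off
    list(start0 = max(start0, 0), width = w,
         m = m, p = p,
         location = if (promoter) "promoter" else "non_promoter",
         gene = lay$geneIds[geneIdx], pass = pass)
  }
  rows[[1L]] <- addPeak(lay$driverIdx, TRUE, config@driver@peakM, 0.01, TRUE)
  for (gi in lay$backgroundIdx) {
    if (stats::runif(1) > config@peakFraction) next
    if (stats::runif(1) < config@decoyFraction) {
      # decoy: fails on M, on P, or both
      mode <- sample(3L, 1L)
      m <- if (mode %in% c(1L, 3L)) stats::runif(1, 0, 0.45)
           else stats::runif(1, 0.5, 1.0)
      p <- if (mode %in% c(2L, 3L)) stats::runif(1, 0.06, 0.5)
           else stats::runif(1, 0.001, 0.04)
      rows[[length(rows) + 1L]] <-
        addPeak(gi, stats::runif(1) < 0.5, m, p, FALSE)
    } else {
      m <- stats::runif(1, 0.5, 1.0)
      p <- stats::runif(1, 0.001, 0.04)
      rows[[length(rows) + 1L]] <-
        addPeak(gi, stats::runif(1) < config@promoterFraction, m, p, TRUE)
    }
  }
  start0 <- vapply(rows, `[[`, numeric(1), "start0")
  w <- vapply(rows, `[[`, numeric(1), "width")
  gr <- GRanges(lay$chrom, IRanges(start0 + 1, width = w))
  mcols(gr) <- DataFrame(
    peak_id        = sprintf("pk%04d", seq_along(rows)),
    m_value        = vapply(rows, `[[`, numeric(1), "m"),
    p_value        = vapply(rows, `[[`, numeric(1), "p"),
    location_class = vapply(rows, `[[`, character(1), "location"),
    assigned_gene  = NA_character_,
    planted_pass   = vapply(rows, `[[`, logical(1), "pass"),
    planted_gene   = vapply(rows, `[[`, character(1), "gene"))
  ord <- order(start(gr))
  gr[ord]
}

#' Generate a synthetic pathway catalog
#'
#' Four oncogenic pathways (RAS signaling, cell cycle, stemness /
#' pluripotency, ubiquitin-mediated proteolysis) plus generic pathways. The
#' driver is planted into `nOncogenic` oncogenic and `nPathways -
#' nOncogenic` generic pathways; every other gene joins each oncogenic
#' pathway with probability 0.04 and each generic pathway with probability
#' 0.10, so no background gene plausibly matches the driver's burden.
#'
#' @param config a [SimulationConfig-class]
#' @return a [PathwayCatalog-class]
#' @export
generatePathways <- function(config) {
  validObject(config)
  lay <- .studyLayout(config)
  set.seed(.derivedSeed(config@seed, 15485863))
  oncNames <- c("RAS_SIGNALING", "CELL_CYCLE", "STEMNESS_PLURIPOTENCY",
                "UBIQUITIN_PROTEOLYSIS")
  nGeneric <- max(config@nPathwaysCatalog - length(oncNames), 1L)
  ids <- c(oncNames, sprintf("PATHWAY_%02d", seq_len(nGeneric)))
  onc <- stats::setNames(ids %in% oncNames, ids)
  others <- setdiff(seq_len(config@nGenes), lay$driverIdx)
  sets <- stats::setNames(vector("list", length(ids)), ids)
  for (pid in ids) {
    pr <- if (onc[[pid]]) 0.04 else 0.10
    sets[[pid]] <- lay$geneIds[others][stats::runif(length(others)) < pr]
  }
  drv <- config@driver
  inOnc <- oncNames[seq_len(min(drv@nOncogenic, length(oncNames)))]
  nGen <- drv@nPathways - length(inOnc)
  inGen <- if (nGen > 0L)
    sprintf("PATHWAY_%02d", seq_len(min(nGen, nGeneric))) else character()
  for (pid in c(inOnc, inGen))
    sets[[pid]] <- c(lay$geneIds[lay$driverIdx], sets[[pid]])
  for (pid in ids)                                # no empty pathways
    if (!length(sets[[pid]]))
      sets[[pid]] <- sample(lay$geneIds[others], 3L)
  new("PathwayCatalog",
      sets = sets,
      descriptions = stats::setNames(paste("synthetic pathway", ids), ids),
      oncogenic = onc)
}

#' Generate a synthetic H3K27ac enhancer signal landscape
#'
#' `nRegions - nSuper` regions draw their signal from a low-mean background
#' distribution (truncated normal, mean 1) and `nSuper` regions from a
#' shifted heavy-tailed distribution (15 + exponential with mean 10), so the
#' ascending rank curve is hockey-stick shaped. Regions are spaced 20-80 kb
#' apart (stitching at the default 12.5 kb is a no-op on this layout). True
#' super labels are recorded in `planted_super`.
#'
#' @param nRegions total regions.
#' @param nSuper planted super-enhancers (must be < nRegions).
#' @param seed integer RNG seed.
#' @param chrom chromosome name.
#' @return GRanges with mcols `region_id`, `signal`, `factor_overlap` (NA),
#'   `planted_super`.
#' @export
generateEnhancerSignal <- function(nRegions, nSuper, seed, chrom = "chrE") {
  nRegions <- as.integer(nRegions); nSuper <- as.integer(nSuper)
  if (nSuper >= nRegions)
    stop("nSuper must be smaller than nRegions")
  if (nSuper < 0L) stop("nSuper must be >= 0")
  set.seed(as.integer(seed))
  gaps <- round(stats::runif(nRegions, 20000, 80000))
  widths <- round(stats::runif(nRegions, 2000, 10000))
  start0 <- cumsum(gaps + c(0, widths[-nRegions]))
  signal <- pmax(stats::rnorm(nRegions, 1, 0.3), 0.01)
  superIdx <- if (nSuper > 0L) sample.int(nRegions, nSuper) else integer()
  signal[superIdx] <- 15 + stats::rexp(nSuper, rate = 1 / 10)
  gr <- GRanges(chrom, IRanges(start0 + 1, width = widths))
  mcols(gr) <- DataFrame(
    region_id      = sprintf("enh%05d", seq_len(nRegions)),
    signal         = signal,
    factor_overlap = NA,
    planted_super  = seq_len(nRegions) %in% superIdx)
  gr
}

#' Generate synthetic CCK-8 viability plate readings
#'
#' Optical densities follow a symmetric four-parameter logistic inhibition
#' curve: inhibition(d) = bottom + (top - bottom) / (1 + (ic50/d)^hill),
#' mapped to OD via the plate's control and blank levels, plus Gaussian
#' read noise. At `noiseSd = 0` and `dose = trueIc50` the inhibition rate is
#' exactly halfway between bottom and top.
#'
#' @param trueIc50 true IC50 in uM (> 0).
#' @param hill Hill slope.
#' @param doses treated dose levels in uM (all > 0).
#' @param noiseSd read noise SD in OD units.
#' @param seed integer RNG seed.
#' @param odControl,odBlank plate control and blank OD levels.
#' @param nReplicates replicates per role/dose.
#' @param bottom,top inhibition asymptotes in percent.
#' @return data.frame with columns dose, od, role
#'   (treated/control/blank), replicate.
#' @export
generateViability <- function(trueIc50, hill = 1.5,
                              doses = c(0.3125, 0.625, 1.25, 2.5, 5, 10, 20),
                              noiseSd = 0.02, seed = 1L,
                              odControl = 1.2, odBlank = 0.1,
                              nReplicates = 3L, bottom = 0, top = 100) {
  if (trueIc50 <= 0) stop("trueIc50 must be positive")
  if (any(doses <= 0)) stop("treated doses must be positive")
  set.seed(as.integer(seed))
  reps <- as.integer(nReplicates)
  inh <- bottom + (top - bottom) / (1 + (trueIc50 / doses)^hill)
  odTreated <- odControl - inh / 100 * (odControl - odBlank)
  df <- rbind(
    data.frame(dose = 0, od = odControl, role = "control",
               replicate = seq_len(reps)),
    data.frame(dose = 0, od = odBlank, role = "blank",
               replicate = seq_len(reps)),
    data.frame(dose = rep(doses, each = reps),
               od = rep(odTreated, each = reps),
               role = "treated",
               replicate = rep(seq_len(reps), length(doses))))
  df$od <- df$od + stats::rnorm(nrow(df), 0, noiseSd)
  df
}

#' Simulate one complete synthetic study
#'
#' Convenience wrapper producing every input the pipeline consumes:
#' expression, peaks, pathway catalog, enhancer landscape (plus factor peaks
#' overlapping a fraction of the planted super-enhancers), viability plates,
#' and the combined planted truth.
#'
#' @param config a [SimulationConfig-class]
#' @param nRegions,nSuper enhancer landscape size (see
#'   [generateEnhancerSignal()]).
#' @param factorFraction fraction of planted super-enhancers (and 0.15 of
#'   typical regions) receiving an overlapping factor peak.
#' @param trueIc50,hill viability curve parameters (uM; defaults in the
#'   potency range typical of a TRC-selective retinoid).
#' @return named list: expression, peaks, catalog, enhancers,
#'   enhancerFactorPeaks, viability, truth.
#' @export
simulateStudy <- function(config = simulationConfig(), nRegions = 1000L,
                          nSuper = 50L, factorFraction = 0.75,
                          trueIc50 = 2.83, hill = 1.5) {
  expr <- generateExpression(config)
  peaks <- generatePeaks(config)
  catalog <- generatePathways(config)
  enh <- generateEnhancerSignal(nRegions, nSuper,
                                seed = .derivedSeed(config@seed, 32452843))
  set.seed(.derivedSeed(config@seed, 49979687))
  pSuper <- mcols(enh)$planted_super
  hit <- ifelse(pSuper, stats::runif(length(enh)) < factorFraction,
                stats::runif(length(enh)) < 0.15)
  fp <- enh[hit]
  inset <- pmin(width(fp) %/% 4L, 500L)
  fpk <- GRanges(seqnames(fp),
                 IRanges(start(fp) + inset, end(fp) - inset))
  mcols(fpk) <- DataFrame(
    peak_id        = sprintf("fpk%05d", seq_along(fpk)),
    m_value        = stats::runif(length(fpk), 0.6, 2.0),
    p_value        = stats::runif(length(fpk), 0.001, 0.04),
    location_class = "non_promoter",
    assigned_gene  = NA_character_)
  viab <- generateViability(trueIc50, hill,
                            seed = .derivedSeed(config@seed, 86028121))
  truth <- metadata(expr)$truth
  truth$plantedSuper <- mcols(enh)$region_id[pSuper]
  truth$passingPeaks <- mcols(peaks)$peak_id[mcols(peaks)$planted_pass]
  truth$trueIc50 <- trueIc50
  list(expression = expr, peaks = peaks, catalog = catalog,
       enhancers = enh, enhancerFactorPeaks = fpk, viability = viab,
       truth = truth)
}
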