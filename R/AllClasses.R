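#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps reduce promoters mcols mcols<-
#' @importFrom IRanges IRanges
NULL

#' Planted driver specification
#'
#' Describes the evidence planted for the single "driver" gene in a synthetic
#' study: how many correlated companion genes it gets (its guaranteed network
#' neighbourhood), how many catalog pathways contain it (and how many of those
#' are oncogenic), the M-value of its promoter binding peak, and which planted
#' expression pattern it follows. All planted evidence is chosen to exceed the
#' pipeline's default thresholds so the driver is recoverable by design.
#'
#' @slot targetDegree integer, number of planted correlated companion genes.
#' @slot nPathways integer, number of catalog pathways containing the driver.
#' @slot nOncogenic integer, how many of those pathways carry the oncogenic
#'   flag (must be <= nPathways).
#' @slot peakM numeric, planted M-value of the driver's promoter peak.
#' @slot clusterPattern integer, index of the planted expression pattern the
#'   driver follows (must point at a dose-decreasing pattern).
#' @slot membershipFloor numeric, minimum cluster membership the planted
#'   design is expected to achieve for the driver.
#' @exportClass DriverSpec
setClass("DriverSpec",
  slots = c(
    targetDegree    = "integer",
    nPathways       = "integer",
    nOncogenic      = "integer",
    peakM           = "numeric",
    clusterPattern  = "integer",
    membershipFloor = "numeric"
  )
)

setValidity("DriverSpec", function(object) {
  msg <- character()
  if (object@targetDegree < 1L)
    msg <- c(msg, "targetDegree must be >= 1")
  if (object@nPathways < 0L || object@nOncogenic < 0L)
    msg <- c(msg, "pathway counts must be non-negative")
  if (object@nOncogenic > object@nPathways)
    msg <- c(msg, "nOncogenic cannot exceed nPathways")
  if (!is.finite(object@peakM))
    msg <- c(msg, "peakM must be finite")
  if (object@clusterPattern < 1L)
    msg <- c(msg, "clusterPattern must be a positive pattern index")
  if (object@membershipFloor < 0 || object@membershipFloor > 1)
    msg <- c(msg, "membershipFloor must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic study configuration
#'
#' Full parameterization of one synthetic multi-omic study: the sample layout
#' (cell contexts x doses x replicates), the number of genes and planted
#' expression patterns, the noise level on log2 expression, peak-table
#' composition, and the planted driver.
#'
#' @slot nGenes integer, total genes (>= nClustersPlanted).
#' @slot contexts character, ordered cell-context labels; the first is the
#'   tumor-repopulating-cell (TRC) context used for dose-trend calls.
#' @slot doses numeric, strictly increasing dose levels in uM (0 = vehicle).
#' @slot nReplicates integer, replicates per context x dose.
#' @slot nClustersPlanted integer, number of planted expression patterns.
#' @slot noiseSd numeric, SD of additive Gaussian noise on log2 expression.
#' @slot driver [DriverSpec-class] for the planted driver gene.
#' @slot seed integer RNG seed; identical seeds give bit-identical output.
#' @slot peakFraction numeric, fraction of background genes receiving a peak.
#' @slot decoyFraction numeric, fraction of those peaks planted to fail the
#'   default M/P filter.
#' @slot promoterFraction numeric, fraction of passing peaks placed in the
#'   promoter window of their gene.
#' @slot nPathwaysCatalog integer, total pathways in the generated catalog.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(
    nGenes           = "integer",
    contexts         = "character",
    doses            = "numeric",
    nReplicates      = "integer",
    nClustersPlanted = "integer",
    noiseSd          = "numeric",
    driver           = "DriverSpec",
    seed             = "integer",
    peakFraction     = "numeric",
    decoyFraction    = "numeric",
    promoterFraction = "numeric",
    nPathwaysCatalog = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nGenes < object@nClustersPlanted)
    msg <- c(msg, "nGenes must be >= nClustersPlanted")
  if (length(object@doses) < 2L || any(diff(object@doses) <= 0))
    msg <- c(msg, "doses must be strictly increasing with >= 2 levels")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (object@nReplicates < 1L)
    msg <- c(msg, "nReplicates must be >= 1")
  if (length(object@contexts) < 1L || anyDuplicated(object@contexts))
    msg <- c(msg, "contexts must be a non-empty set of unique labels")
  if (object@driver@clusterPattern > object@nClustersPlanted)
    msg <- c(msg, "driver clusterPattern exceeds nClustersPlanted")
  frac <- c(object@peakFraction, object@decoyFraction, object@promoterFraction)
  if (any(frac < 0 | frac > 1))
    msg <- c(msg, "peak/decoy/promoter fractions must lie in [0, 1]")
  # the driver's planted companions plus itself must fit among the genes
  if (object@driver@targetDegree + 1L > object@nGenes)
    msg <- c(msg, "targetDegree + 1 cannot exceed nGenes")
  if (length(msg)) msg else TRUE
})

#' Dose-response expression experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying one `log2expr`
#' assay (genes x samples) whose `colData` fully annotates every sample with
#' `context`, `dose` (uM) and `replicate`, and whose `rowData` may carry the
#' synthetic gene annotation (`chrom`, `tss`, `strand`).
#'
#' Validity requires unique, non-missing gene and sample names, finite assay
#' values, complete sample metadata, and identical dose sets in every context.
#'
#' @exportClass DoseResponseExperiment
setClass("DoseResponseExperiment", contains = "SummarizedExperiment")

setValidity("DoseResponseExperiment", function(object) {
  msg <- character()
  if (!"log2expr" %in% SummarizedExperiment::assayNames(object))
    return("assay 'log2expr' is required")
  m <- assay(object, "log2expr")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene names must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample names must be present and unique")
  if (!all(is.finite(m)))
    msg <- c(msg, "all log2 expression values must be finite")
  cd <- colData(object)
  need <- c("context", "dose", "replicate")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain:", paste(need, collapse = ", ")))
  if (anyNA(cd$context) || anyNA(cd$dose) || anyNA(cd$replicate))
    msg <- c(msg, "sample metadata must be complete (no NA)")
  dosesBy <- split(cd$dose, cd$context)
  doseSets <- lapply(dosesBy, function(d) sort(unique(d)))
  if (length(doseSets) > 1L &&
      !all(vapply(doseSets[-1], identical, logical(1), doseSets[[1]])))
    msg <- c(msg, "dose levels must be identical across contexts")
  if (length(msg)) msg else TRUE
})

#' Per-gene dose-response profiles
#'
#' Condition-level (context x dose) mean profiles, optionally standardized
#' per gene to mean 0 / sd 1 across conditions. Zero-variance genes are
#' excluded from the profile matrix and recorded in `skipped`.
#'
#' @slot profiles numeric matrix, genes x conditions.
#' @slot conditions DataFrame with one row per profile column (`context`,
#'   `dose`).
#' @slot skipped character, gene ids excluded for zero variance.
#' @slot standardized logical flag.
#' @slot sdMethod character, "sample" (n-1 denominator, the Mfuzz
#'   convention) or "population" (n denominator).
#' @exportClass ResponseProfiles
setClass("ResponseProfiles",
  slots = c(
    profiles     = "matrix",
    conditions   = "DataFrame",
    skipped      = "character",
    standardized = "logical",
    sdMethod     = "character"
  )
)

setValidity("ResponseProfiles", function(object) {
  msg <- character()
  if (nrow(object@conditions) != ncol(object@profiles))
    msg <- c(msg, "conditions must have one row per profile column")
  if (!all(c("context", "dose") %in% colnames(object@conditions)))
    msg <- c(msg, "conditions must carry 'context' and 'dose'")
  if (!all(is.finite(object@profiles)))
    msg <- c(msg, "profiles must be finite")
  if (length(msg)) msg else TRUE
})

#' Fuzzy c-means clustering result
#'
#' Soft partition of standardized dose-response profiles: cluster centroids,
#' the genes x clusters membership matrix (rows sum to 1), the fuzzifier m,
#' and the per-iteration objective trace (non-increasing).
#'
#' @slot centroids numeric matrix, clusters x conditions.
#' @slot memberships numeric matrix, genes x clusters, rows sum to 1.
#' @slot fuzzifier numeric > 1.
#' @slot objective numeric, objective value after each iteration.
#' @slot conditions DataFrame describing centroid columns (may have 0 cols
#'   for plain-matrix input).
#' @slot converged logical.
#' @slot iterations integer.
#' @exportClass FuzzyClustering
setClass("FuzzyClustering",
  slots = c(
    centroids   = "matrix",
    memberships = "matrix",
    fuzzifier   = "numeric",
    objective   = "numeric",
    conditions  = "DataFrame",
    converged   = "logical",
    iterations  = "integer"
  )
)

setValidity("FuzzyClustering", function(object) {
  msg <- character()
  if (ncol(object@memberships) != nrow(object@centroids))
    msg <- c(msg, "memberships columns must match centroid rows")
  if (any(object@memberships < -1e-9 | object@memberships > 1 + 1e-9))
    msg <- c(msg, "memberships must lie in [0, 1]")
  rs <- rowSums(object@memberships)
  if (any(abs(rs - 1) > 1e-9))
    msg <- c(msg, "membership rows must sum to 1 within 1e-9")
  if (!all(is.finite(object@centroids)))
    msg <- c(msg, "centroids must be finite")
  if (object@fuzzifier <= 1)
    msg <- c(msg, "fuzzifier must be > 1")
  if (length(msg)) msg else TRUE
})

#' Thresholded Pearson co-expression network
#'
#' Undirected graph over genes with an edge wherever |Pearson r| exceeds the
#' construction threshold with P below the cap. Edges are stored
#' symmetric-unique (geneA < geneB); `degrees` covers every node, isolated
#' nodes included.
#'
#' @slot nodes character, gene ids.
#' @slot edges data.frame with columns geneA, geneB, pcc, pValue.
#' @slot degrees named integer, incident-edge count per node.
#' @slot pccMin,pMax numeric, the construction thresholds.
#' @exportClass CorrelationNetwork
setClass("CorrelationNetwork",
  slots = c(
    nodes   = "character",
    edges   = "data.frame",
    degrees = "integer",
    pccMin  = "numeric",
    pMax    = "numeric"
  )
)

setValidity("CorrelationNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("geneA", "geneB", "pcc", "pValue") %in% colnames(e)))
    return("edges must have columns geneA, geneB, pcc, pValue")
  if (nrow(e)) {
    if (any(e$geneA == e$geneB))
      msg <- c(msg, "self-edges are not allowed")
    if (any(e$geneA >= e$geneB))
      msg <- c(msg, "edges must be stored with geneA < geneB")
    if (anyDuplicated(paste(e$geneA, e$geneB)))
      msg <- c(msg, "duplicate edges are not allowed")
    if (any(abs(e$pcc) > 1 + 1e-12))
      msg <- c(msg, "pcc must lie in [-1, 1]")
  }
  tab <- table(factor(c(e$geneA, e$geneB), levels = object@nodes))
  if (!identical(as.integer(tab), as.integer(object@degrees[object@nodes])))
    msg <- c(msg, "degrees must equal incident-edge counts")
  if (length(msg)) msg else TRUE
})

#' Super-enhancer call result
#'
#' Regions ranked by ascending H3K27ac signal with both axes scaled to
#' [0, 1]; the super-enhancer cutoff is taken where the scaled rank curve is
#' farthest below the diagonal (the slope-1 tangent construction) and regions
#' with signal strictly above the cutoff signal are super-enhancers.
#'
#' @slot regions GRanges with mcols `region_id`, `signal`, `rank`,
#'   `scaled_x`, `scaled_y`, `is_super`, `factor_overlap`.
#' @slot cutoffSignal numeric.
#' @slot nSuper integer.
#' @slot nSuperWithFactor integer (NA until factor annotation is applied).
#' @exportClass EnhancerCalls
setClass("EnhancerCalls",
  slots = c(
    regions          = "GRanges",
    cutoffSignal     = "numeric",
    nSuper           = "integer",
    nSuperWithFactor = "integer"
  )
)

setValidity("EnhancerCalls", function(object) {
  msg <- character()
  mc <- mcols(object@regions)
  need <- c("region_id", "signal", "rank", "scaled_x", "scaled_y", "is_super")
  if (!all(need %in% colnames(mc)))
    return(paste("regions must carry mcols:", paste(need, collapse = ", ")))
  if (length(object@regions)) {
    if (!identical(sort(as.integer(mc$rank)), seq_along(object@regions)))
      msg <- c(msg, "ranks must be a permutation of 1..n")
    if (any(mc$scaled_x < -1e-12 | mc$scaled_x > 1 + 1e-12) ||
        any(mc$scaled_y < -1e-12 | mc$scaled_y > 1 + 1e-12))
      msg <- c(msg, "scaled axes must lie in [0, 1]")
    if (!identical(as.logical(mc$is_super),
                   as.logical(mc$signal > object@cutoffSignal)))
      msg <- c(msg, "is_super must equal signal > cutoffSignal")
  }
  if (length(msg)) msg else TRUE
})

#' Four-parameter logistic dose-response fit
#'
#' Least-squares fit of inhibition(\%) = bottom + (top - bottom) /
#' (1 + (ic50/dose)^hill). The IC50 is the curve midpoint between bottom and
#' top.
#'
#' @slot coefficients named numeric: bottom, top, ic50, hill.
#' @slot sse numeric residual sum of squares.
#' @slot converged logical.
#' @slot data data.frame with dose (uM) and response (inhibition \%) used in
#'   the fit (replicate-averaged).
#' @exportClass DoseResponseFit
setClass("DoseResponseFit",
  slots = c(
    coefficients = "numeric",
    sse          = "numeric",
    converged    = "logical",
    data         = "data.frame"
  )
)

setValidity("DoseResponseFit", function(object) {
  if (object@converged) {
    cf <- object@coefficients
    if (!all(is.finite(cf)))
      return("converged fits must have finite coefficients")
    if (cf[["ic50"]] <= 0)
      return("ic50 must be positive")
    if (cf[["bottom"]] > cf[["top"]])
      return("bottom must be <= top")
  }
  TRUE
})

#' Chou-Talalay combination index result
#'
#' Median-effect fits for the two single agents and the fixed-ratio
#' combination, plus the combination index CI = dA/DxA + dB/DxB at the stated
#' effect level (fraction affected fa). CI < 1 synergy, = 1 additivity,
#' > 1 antagonism.
#'
#' @slot fits list of three median-effect fits (`a`, `b`, `combo`), each a
#'   list with Dm, h, r2.
#' @slot ci numeric combination index (> 0).
#' @slot effectLevel numeric fa in (0, 1).
#' @slot componentDoses named numeric, combo component doses (dA, dB)
#'   achieving fa.
#' @exportClass CombinationResult
setClass("CombinationResult",
  slots = c(
    fits           = "list",
    ci             = "numeric",
    effectLevel    = "numeric",
    componentDoses = "numeric"
  )
)

setValidity("CombinationResult", function(object) {
  msg <- character()
  if (object@ci <= 0)
    msg <- c(msg, "ci must be positive")
  if (object@effectLevel <= 0 || object@effectLevel >= 1)
    msg <- c(msg, "effectLevel must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Pathway catalog
#'
#' Named gene sets (GMT-style) with an oncogenic flag per pathway. By default
#' the flag is assigned by name-matching the tumorigenesis-associated
#' families emphasized in the ranking scheme (RAS signaling, cell cycle,
#' stemness/pluripotency, ubiquitin-mediated proteolysis).
#'
#' @slot sets named list of character vectors (member gene ids; non-empty).
#' @slot descriptions named character.
#' @slot oncogenic named logical.
#' @exportClass PathwayCatalog
setClass("PathwayCatalog",
  slots = c(
    sets         = "list",
    descriptions = "character",
    oncogenic    = "logical"
  )
)

setValidity("PathwayCatalog", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "pathway ids must be present and unique")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "empty pathways are not allowed")
  if (!identical(names(object@sets), names(object@oncogenic)))
    msg <- c(msg, "oncogenic flags must be named per pathway")
  if (length(msg)) msg else TRUE
})
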