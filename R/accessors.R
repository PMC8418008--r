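# Accessors and show() methods.

#' Extract the genes x clusters membership matrix
#' @param object a [FuzzyClustering-class]
#' @return numeric matrix; rows sum to 1.
#' @export
setMethod("memberships", "FuzzyClustering", function(object) object@memberships)

#' Extract the clusters x conditions centroid matrix
#' @param object a [FuzzyClustering-class]
#' @export
setMethod("centroids", "FuzzyClustering", function(object) object@centroids)

#' Hard cluster assignment (argmax membership)
#'
#' Ties are broken toward the lowest cluster index.
#' @param object a [FuzzyClustering-class]
#' @return named integer vector of cluster indices per gene.
#' @export
setMethod("clusterAssignments", "FuzzyClustering", function(object) {
  a <- apply(object@memberships, 1L, which.max)
  stats::setNames(as.integer(a), rownames(object@memberships))
})

#' Per-node degree of a correlation network
#' @param object a [CorrelationNetwork-class]
#' @return named integer vector over all nodes (isolated nodes have 0).
#' @export
setMethod("degrees", "CorrelationNetwork", function(object) object@degrees)

#' Edge list of a correlation network
#' @param object a [CorrelationNetwork-class]
#' @return data.frame with geneA, geneB, pcc, pValue (geneA < geneB).
#' @export
setMethod("networkEdges", "CorrelationNetwork", function(object) object@edges)

#' Node set of a correlation network
#' @param object a [CorrelationNetwork-class]
#' @export
setMethod("networkNodes", "CorrelationNetwork", function(object) object@nodes)

#' Ranked regions of a super-enhancer call
#' @param object an [EnhancerCalls-class]
#' @return GRanges with rank, scaled axes, is_super and factor_overlap mcols.
#' @export
setMethod("enhancerRegions", "EnhancerCalls", function(object) object@regions)

#' Super-enhancer cutoff signal
#' @param object an [EnhancerCalls-class]
#' @export
setMethod("cutoffSignal", "EnhancerCalls", function(object) object@cutoffSignal)

#' Logical super-enhancer flags in rank order of the stored regions
#' @param object an [EnhancerCalls-class]
#' @export
setMethod("isSuper", "EnhancerCalls", function(object)
  as.logical(mcols(object@regions)$is_super))

#' Fitted IC50 (curve midpoint) in uM
#' @param object a [DoseResponseFit-class]
#' @export
setMethod("ic50", "DoseResponseFit", function(object)
  unname(object@coefficients["ic50"]))

#' Fitted 4PL coefficients
#' @param object a [DoseResponseFit-class]
#' @return named numeric: bottom, top, ic50, hill.
#' @export
setMethod("coef", "DoseResponseFit", function(object) object@coefficients)

#' Combination index value
#' @param object a [CombinationResult-class]
#' @export
setMethod("combinationIndexValue", "CombinationResult",
          function(object) object@ci)

#' Gene sets of a pathway catalog
#' @param object a [PathwayCatalog-class]
#' @export
setMethod("pathwaySets", "PathwayCatalog", function(object) object@sets)

#' Oncogenic flags of a pathway catalog
#' @param object a [PathwayCatalog-class]
#' @export
setMethod("oncogenicFlags", "PathwayCatalog", function(object) object@oncogenic)

#' Profile matrix (genes x conditions)
#' @param object a [ResponseProfiles-class]
#' @export
setMethod("profileMatrix", "ResponseProfiles", function(object) object@profiles)

#' Genes skipped for zero variance
#' @param object a [ResponseProfiles-class]
#' @export
setMethod("skippedGenes", "ResponseProfiles", function(object) object@skipped)

#' Gene annotation as a TSS-anchored GRanges
#'
#' Builds a width-1 GRanges at each gene's transcription start site from the
#' `chrom`, `tss` (0-based bp) and `strand` columns of `rowData`.
#' @param object a [DoseResponseExperiment-class]
#' @return GRanges named by gene id.
#' @export
setMethod("geneAnnotation", "DoseResponseExperiment", function(object) {
  rd <- rowData(object)
  need <- c("chrom", "tss", "strand")
  if (!all(need %in% colnames(rd)))
    stop("rowData lacks gene annotation columns (chrom, tss, strand)")
  gr <- GRanges(rd$chrom, IRanges(rd$tss + 1L, width = 1L),
                strand = rd$strand)
  names(gr) <- rownames(object)
  gr
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes,",
      length(object@contexts), "contexts x", length(object@doses),
      "doses x", object@nReplicates, "replicates\n")
  cat("  doses (uM):", paste(object@doses, collapse = ", "),
      "| noiseSd:", object@noiseSd, "| seed:", object@seed, "\n")
  cat("  driver: degree", object@driver@targetDegree,
      "| pathways", object@driver@nPathways,
      paste0("(", object@driver@nOncogenic, " oncogenic)"),
      "| peak M", object@driver@peakM,
      "| pattern", object@driver@clusterPattern, "\n")
})

setMethod("show", "FuzzyClustering", function(object) {
  cat("FuzzyClustering:", nrow(object@memberships), "genes in",
      nrow(object@centroids), "clusters (m =", object@fuzzifier, ")\n")
  cat("  ", object@iterations, "iterations;",
      if (object@converged) "converged;" else "NOT converged;",
      "final objective", format(utils::tail(object@objective, 1L)), "\n")
})

setMethod("show", "CorrelationNetwork", function(object) {
  cat("CorrelationNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges (|r| >", object@pccMin,
      ", P <", object@pMax, ")\n")
  if (length(object@degrees))
    cat("  max degree:", max(object@degrees), "\n")
})

setMethod("show", "EnhancerCalls", function(object) {
  cat("EnhancerCalls:", length(object@regions), "regions;",
      object@nSuper, "super-enhancers above cutoff signal",
      format(object@cutoffSignal, digits = 4), "\n")
  if (!is.na(object@nSuperWithFactor))
    cat("  super-enhancers with factor overlap:",
        object@nSuperWithFactor, "\n")
})

setMethod("show", "DoseResponseFit", function(object) {
  if (object@converged) {
    cf <- object@coefficients
    cat(sprintf(
      "DoseResponseFit (4PL): IC50 = %.4g uM, hill = %.3g, span [%.3g, %.3g], SSE = %.4g\n",
      cf[["ic50"]], cf[["hill"]], cf[["bottom"]], cf[["top"]], object@sse))
  } else {
    cat("DoseResponseFit (4PL): not converged\n")
  }
})

setMethod("show", "CombinationResult", function(object) {
  cat(sprintf("CombinationResult: CI = %.4g at fa = %.3g (%s)\n",
              object@ci, object@effectLevel,
              if (object@ci < 1) "synergy" else if (object@ci > 1)
                "antagonism" else "additivity"))
})

setMethod("show", "PathwayCatalog", function(object) {
  cat("PathwayCatalog:", length(object@sets), "pathways,",
      sum(object@oncogenic), "flagged oncogenic\n")
})
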