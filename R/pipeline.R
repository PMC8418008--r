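# End-to-end target prioritization.

#' Run the full integrative prioritization pipeline
#'
#' Chains the analysis stages on one study: build and standardize
#' dose-response profiles, fuzzy-cluster them, select dose-down-regulated
#' genes by membership, filter and promoter-assign the factor peaks,
#' intersect into candidates, build the all-gene Pearson network, and rank
#' the degree-filter survivors by the four priority criteria.
#'
#' @param expression a [DoseResponseExperiment-class]
#' @param peaks GRanges peak table (unfiltered).
#' @param catalog a [PathwayCatalog-class]
#' @param genes optional TSS annotation GRanges; defaults to
#'   [geneAnnotation()] of `expression`.
#' @param nClusters,fuzzifier,clusterSeed fuzzy c-means settings.
#' @param membershipThreshold membership filter (default 0.2).
#' @param mMin,pMaxPeaks peak filter thresholds (defaults 0.5 / 0.05).
#' @param promoterWindow c(upstream, downstream) bp (default 2000/500).
#' @param anyLocation accept non-promoter peak assignments (default FALSE).
#' @param pccMin,pMaxEdges network thresholds (defaults 0.9 / 0.05).
#' @param degreeMin degree filter (default 18).
#' @param topN ranked rows returned (default 10).
#' @return list with ranked (DataFrame), network, clustering, profiles,
#'   responsiveGenes, candidates.
#' @export
prioritizeTargets <- function(expression, peaks, catalog, genes = NULL,
                              nClusters = 8L, fuzzifier = 1.25,
                              clusterSeed = 1L,
                              membershipThreshold = 0.2,
                              mMin = 0.5, pMaxPeaks = 0.05,
                              promoterWindow = c(2000L, 500L),
                              anyLocation = FALSE,
                              pccMin = 0.9, pMaxEdges = 0.05,
                              degreeMin = 18L, topN = 10L) {
  if (is.null(genes)) genes <- geneAnnotation(expression)
  profiles <- buildProfiles(expression)
  clustering <- fuzzyCMeans(profiles, c = nClusters, m = fuzzifier,
                            seed = clusterSeed)
  responsive <- selectResponsiveGenes(clustering, direction = "down",
                                      threshold = membershipThreshold)
  kept <- filterPeaks(peaks, mMin = mMin, pMax = pMaxPeaks)
  assigned <- assignPeaksToGenes(kept, genes, promoterWindow = promoterWindow)
  candidates <- integrateCandidates(assigned, responsive,
                                    anyLocation = anyLocation)
  network <- buildPccNetwork(expression, pccMin = pccMin, pMax = pMaxEdges)
  ranked <- priorityRank(candidates, network, catalog, clustering,
                         topN = topN, degreeMin = degreeMin)
  list(ranked = ranked, network = network, clustering = clustering,
       profiles = profiles, responsiveGenes = responsive,
       candidates = candidates)
}
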