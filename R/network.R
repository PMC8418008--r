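# Pearson co-expression network, pathway burden and the four-criterion
# priority ranking.

#' Build a thresholded Pearson co-expression network
#'
#' An edge joins genes a and b iff |Pearson r across samples| is strictly
#' greater than `pccMin` (so r = 0.9 exactly is excluded at the default)
#' and the two-sided P-value from the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n-2 df is below `pMax`. No
#' multiple-testing correction is applied, matching the raw-threshold
#' construction this ranking scheme uses. Zero-variance genes stay in the
#' node set with degree 0.
#'
#' @param x a [DoseResponseExperiment-class] or a genes x samples numeric
#'   matrix of log2 expression.
#' @param genes optional subset of gene ids to build the network on
#'   (default: all genes in `x`).
#' @param pccMin absolute-correlation threshold (strict >; default 0.9).
#' @param pMax edge P-value cap (default 0.05).
#' @param useConditionMeans logical; correlate condition means instead of
#'   all samples (default FALSE: all samples, maximizing n for the
#'   P-value).
#' @return a [CorrelationNetwork-class]
#' @export
buildPccNetwork <- function(x, genes = NULL, pccMin = 0.9, pMax = 0.05,
                            useConditionMeans = FALSE) {
  if (is(x, "DoseResponseExperiment")) {
    m <- if (useConditionMeans)
      buildProfiles(x, standardize = FALSE)@profiles
    else assay(x, "log2expr")
  } else m <- as.matrix(x)
  if (is.null(genes)) genes <- rownames(m)
  unknown <- setdiff(genes, rownames(m))
  if (length(unknown))
    stop("genes absent from the expression matrix: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  m <- m[genes, , drop = FALSE]
  n <- ncol(m)
  if (n < 3L) stop("need at least 3 samples for edge P-values")
  r <- suppressWarnings(stats::cor(t(m)))
  r[!is.finite(r)] <- 0                      # zero-variance genes: isolated
  df <- n - 2L
  r2 <- pmin(r^2, 1)
  tstat <- abs(r) * sqrt(df / pmax(1 - r2, 1e-300))
  p <- 2 * stats::pt(tstat, df, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  keep <- abs(r) > pccMin & p < pMax
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(
    geneA = genes[pmin(idx[, 1L], idx[, 2L])],
    geneB = genes[pmax(idx[, 1L], idx[, 2L])],
    pcc = r[idx], pValue = p[idx],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$geneA, edges$geneB), , drop = FALSE]
  rownames(edges) <- NULL
  deg <- table(factor(c(edges$geneA, edges$geneB), levels = genes))
  net <- new("CorrelationNetwork",
             nodes = genes, edges = edges,
             degrees = stats::setNames(as.integer(deg), genes),
             pccMin = pccMin, pMax = pMax)
  validObject(net)
  net
}

#' Genes passing the degree filter
#'
#' @param network a [CorrelationNetwork-class]
#' @param degreeMin minimum degree, boundary inclusive (default 18, so a
#'   degree of exactly 18 is retained).
#' @param genes optional subset to filter within (default all nodes).
#' @return character vector of gene ids with degree >= degreeMin.
#' @export
degreeFilter <- function(network, degreeMin = 18L, genes = NULL) {
  d <- network@degrees
  if (!is.null(genes)) d <- d[intersect(genes, names(d))]
  names(d)[d >= degreeMin]
}

#' Pathway burden of one gene
#'
#' @param gene gene id.
#' @param catalog a [PathwayCatalog-class]
#' @return named integer c(n_pathways, oncogenic_pathways); c(0, 0) for a
#'   gene absent from every pathway.
#' @export
pathwayBurden <- function(gene, catalog) {
  inSet <- vapply(catalog@sets, function(s) gene %in% s, logical(1))
  c(n_pathways = sum(inSet),
    oncogenic_pathways = sum(inSet & catalog@oncogenic))
}

#' Four-criterion priority ranking of candidate genes
#'
#' Candidates (already peak-supported and responsive) are restricted to the
#' degree-filter survivors, then ordered lexicographically by the four
#' priority criteria: (1) network degree, descending; (2) oncogenic pathway
#' count then total pathway count, descending (tumorigenesis-related
#' pathways outrank raw burden); (3) best peak M-value, descending;
#' (4) cluster membership, descending. Residual ties break on gene id,
#' ascending. Ranks are assigned over all survivors and the top `topN` rows
#' are returned with full evidence columns.
#'
#' @param candidates DataFrame from [integrateCandidates()].
#' @param network a [CorrelationNetwork-class]
#' @param catalog a [PathwayCatalog-class]
#' @param clustering a [FuzzyClustering-class] (membership = the gene's
#'   maximal membership, i.e. at its assigned cluster).
#' @param topN rows to return (default 10); if fewer candidates survive,
#'   all are returned with a warning.
#' @param degreeMin degree filter applied to the candidates (default 18).
#' @return DataFrame with gene_id, degree, n_pathways, oncogenic_pathways,
#'   peak_m, membership, priority_rank.
#' @export
priorityRank <- function(candidates, network, catalog, clustering,
                         topN = 10L, degreeMin = 18L) {
  ids <- as.character(candidates$gene_id)
  surv <- ids %in% degreeFilter(network, degreeMin, genes = ids)
  ids <- ids[surv]
  if (!length(ids)) {
    warning("no candidate survives the degree filter")
    return(DataFrame(gene_id = character(), degree = integer(),
                     n_pathways = integer(), oncogenic_pathways = integer(),
                     peak_m = numeric(), membership = numeric(),
                     priority_rank = integer()))
  }
  burden <- t(vapply(ids, pathwayBurden, integer(2), catalog = catalog))
  u <- clustering@memberships[ids, , drop = FALSE]
  membership <- apply(u, 1L, max)
  tab <- DataFrame(
    gene_id = ids,
    degree = unname(network@degrees[ids]),
    n_pathways = unname(burden[, "n_pathways"]),
    oncogenic_pathways = unname(burden[, "oncogenic_pathways"]),
    peak_m = unname(candidates$peak_m[match(ids, candidates$gene_id)]),
    membership = unname(membership))
  ord <- order(-tab$degree, -tab$oncogenic_pathways, -tab$n_pathways,
               -tab$peak_m, -tab$membership, tab$gene_id)
  tab <- tab[ord, , drop = FALSE]
  tab$priority_rank <- seq_len(nrow(tab))
  if (nrow(tab) < topN)
    warning("only ", nrow(tab), " candidates available for topN = ", topN)
  utils::head(tab, topN)
}

#' Ego subnetwork around a center gene
#'
#' The induced subnetwork on the center and its direct neighbors (all edges
#' among that node set are kept; degrees are recomputed within the
#' subnetwork).
#'
#' @param network a [CorrelationNetwork-class]
#' @param center gene id (must be a node).
#' @return a [CorrelationNetwork-class]; the neighbor count is reported in
#'   `attr(., "nNeighbors")`.
#' @export
egoSubnetwork <- function(network, center) {
  if (!center %in% network@nodes)
    stop("center gene not in network: ", center)
  e <- network@edges
  nb <- unique(c(e$geneB[e$geneA == center], e$geneA[e$geneB == center]))
  nodes <- c(center, sort(setdiff(nb, center)))
  keep <- e$geneA %in% nodes & e$geneB %in% nodes
  sub <- e[keep, , drop = FALSE]
  rownames(sub) <- NULL
  deg <- table(factor(c(sub$geneA, sub$geneB), levels = nodes))
  out <- new("CorrelationNetwork",
             nodes = nodes, edges = sub,
             degrees = stats::setNames(as.integer(deg), nodes),
             pccMin = network@pccMin, pMax = network@pMax)
  attr(out, "nNeighbors") <- length(nodes) - 1L
  out
}
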