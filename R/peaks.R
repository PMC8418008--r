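# Peak filtering, promoter assignment and candidate integration.

#' Filter factor-binding peaks on M-value and P-value
#'
#' A peak is retained iff `m_value >= mMin` and `p_value < pMax` (boundary
#' semantics: M inclusive, P strictly below, following the ranking scheme's
#' stated thresholds; M exactly 0.5 is retained). Row order is preserved.
#'
#' @param peaks GRanges with `m_value` and `p_value` mcols.
#' @param mMin M-value threshold (default 0.5).
#' @param pMax P-value cap (default 0.05).
#' @return the retained subset, same class and order.
#' @export
filterPeaks <- function(peaks, mMin = 0.5, pMax = 0.05) {
  mc <- mcols(peaks)
  peaks[mc$m_value >= mMin & mc$p_value < pMax]
}

.tssDistance <- function(peakStart, peakEnd, tss) {
  # distance from a 1-based closed interval to a point; 0 when covered
  pmax(0, pmax(peakStart - tss, tss - peakEnd))
}

#' Assign peaks to genes by strand-oriented promoter windows
#'
#' A peak is assigned to a gene when it overlaps the gene's promoter window
#' `[tss - upstream, tss + downstream)` oriented by strand (the
#' `GenomicRanges::promoters` construction). Peaks overlapping several
#' promoter windows go to the gene with the nearest TSS; exact distance ties
#' break toward the lexicographically smaller gene id. Assigned peaks get
#' `location_class = "promoter"`; unassigned peaks keep/get
#' `"non_promoter"` and an NA gene.
#'
#' @param peaks GRanges peak table.
#' @param genes named width-1 GRanges of TSS positions (see
#'   [geneAnnotation()] / [readGeneAnnotation()]).
#' @param promoterWindow integer vector c(upstream, downstream) in bp;
#'   default c(2000, 500), a common regulatory-genomics convention.
#' @return `peaks` with `assigned_gene` and `location_class` filled in.
#' @export
assignPeaksToGenes <- function(peaks, genes, promoterWindow = c(2000L, 500L)) {
  if (is.null(names(genes)) || anyDuplicated(names(genes)))
    stop("genes must be uniquely named by gene id")
  unknown <- setdiff(as.character(unique(seqnames(peaks))),
                     as.character(unique(seqnames(genes))))
  if (length(unknown))
    stop("peaks on chromosomes with no annotated gene: ",
         paste(unknown, collapse = ", "))
  prom <- suppressWarnings(
    promoters(genes, upstream = promoterWindow[1L],
              downstream = promoterWindow[2L]))
  prom <- GenomicRanges::trim(prom)
  hits <- findOverlaps(peaks, prom, ignore.strand = TRUE)
  assigned <- rep(NA_character_, length(peaks))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    dist <- .tssDistance(start(peaks)[qh], end(peaks)[qh], start(genes)[sh])
    gene <- names(genes)[sh]
    ord <- order(qh, dist, gene)        # nearest TSS, then smaller gene id
    first <- !duplicated(qh[ord])
    assigned[qh[ord][first]] <- gene[ord][first]
  }
  mc <- mcols(peaks)
  mc$assigned_gene <- assigned
  mc$location_class <- ifelse(is.na(assigned), "non_promoter", "promoter")
  mcols(peaks) <- mc
  peaks
}

#' Integrate peak-supported candidates with responsive genes
#'
#' Candidate genes are responsive genes carrying at least one retained,
#' assigned peak (promoter-class by default; set `anyLocation = TRUE` to
#' accept any assigned peak). Per-gene binding evidence is the maximum
#' M-value over the gene's peaks; the number of contributing peaks is
#' reported alongside.
#'
#' @param peaks GRanges, already filtered ([filterPeaks()]) and assigned
#'   ([assignPeaksToGenes()]).
#' @param responsiveGenes character vector of responsive gene ids.
#' @param anyLocation logical; if FALSE (default) only promoter-class peaks
#'   count.
#' @return DataFrame with columns gene_id, peak_m (max M), n_peaks; empty
#'   (with a warning) when the intersection is empty.
#' @export
integrateCandidates <- function(peaks, responsiveGenes, anyLocation = FALSE) {
  mc <- mcols(peaks)
  ok <- !is.na(mc$assigned_gene)
  if (!anyLocation) ok <- ok & mc$location_class == "promoter"
  g <- mc$assigned_gene[ok]
  m <- mc$m_value[ok]
  keep <- g %in% responsiveGenes
  g <- g[keep]; m <- m[keep]
  if (!length(g)) {
    warning("no responsive gene carries a retained assigned peak")
    return(DataFrame(gene_id = character(), peak_m = numeric(),
                     n_peaks = integer()))
  }
  bestM <- vapply(split(m, g), max, numeric(1))
  nPk <- vapply(split(m, g), length, integer(1))
  ids <- sort(unique(g))
  DataFrame(gene_id = ids, peak_m = unname(bestM[ids]),
            n_peaks = unname(nPk[ids]))
}
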