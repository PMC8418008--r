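# Super-enhancer calling by rank-curve cutoff.

#' Stitch nearby enhancer regions
#'
#' Regions on the same chromosome whose gap is smaller than
#' `stitchDistance` are merged; the merged signal is the sum of member
#' signals and the merged region id concatenates member ids with "|".
#' Unsorted input is sorted internally (with a message).
#'
#' @param regions GRanges with `region_id` and `signal` mcols.
#' @param stitchDistance gap threshold in bp (default 12500, the community
#'   convention); merging happens for gaps strictly below it. Use 0 to
#'   disable stitching.
#' @return stitched GRanges with the same mcols (plus `planted_super`
#'   propagated by any() if present).
#' @export
stitchRegions <- function(regions, stitchDistance = 12500L) {
  if (!length(regions)) return(regions)
  ord <- order(as.integer(seqnames(regions)), start(regions), end(regions))
  if (!identical(ord, seq_along(regions))) {
    message("stitchRegions: input not sorted per chromosome; sorting")
    regions <- regions[ord]
  }
  if (stitchDistance <= 0) return(regions)
  red <- reduce(regions, min.gapwidth = stitchDistance, with.revmap = TRUE)
  rv <- mcols(red)$revmap
  mc <- mcols(regions)
  newMc <- DataFrame(
    region_id = vapply(rv, function(i)
      paste(mc$region_id[i], collapse = "|"), character(1)),
    signal = vapply(rv, function(i) sum(mc$signal[i]), numeric(1)))
  if ("factor_overlap" %in% colnames(mc))
    newMc$factor_overlap <- NA
  if ("planted_super" %in% colnames(mc))
    newMc$planted_super <- vapply(rv, function(i)
      any(mc$planted_super[i]), logical(1))
  mcols(red) <- newMc
  red
}

#' Call super-enhancers by rank-curve cutoff
#'
#' Regions are sorted by ascending signal; rank and signal are scaled to
#' [0, 1]. The cutoff is the point on the scaled curve farthest below the
#' diagonal (maximal x - y, the slope-1 tangent construction of the classic
#' rank-ordering method; the last such point on ties). Regions with signal
#' strictly greater than the cutoff signal are super-enhancers, so ties at
#' the cutoff are typical enhancers and every super-enhancer's signal
#' strictly exceeds every typical enhancer's. A constant signal (degenerate
#' flat curve) yields zero super-enhancers with a warning, as does an
#' exactly linear scaled curve.
#'
#' @param regions GRanges with `region_id` and `signal` mcols (>= 3
#'   regions, signals >= 0).
#' @return an [EnhancerCalls-class]; regions are returned in ascending
#'   signal order with rank/scaled axes/is_super annotations.
#' @export
callSuperEnhancers <- function(regions) {
  if (length(regions) < 3L) stop("need at least 3 regions")
  mc <- mcols(regions)
  sig <- mc$signal
  if (any(sig < 0)) stop("signals must be >= 0")
  ord <- order(sig, mc$region_id)
  regions <- regions[ord]
  sig <- sig[ord]
  n <- length(sig)
  x <- (seq_len(n) - 1) / (n - 1)
  rangeS <- max(sig) - min(sig)
  degenerate <- rangeS < 1e-12
  y <- if (degenerate) rep(0, n) else (sig - min(sig)) / rangeS
  gap <- x - y
  maxGap <- max(gap)
  if (degenerate || maxGap <= 1e-12) {
    if (degenerate)
      warning("constant signal: degenerate rank curve, no super-enhancers")
    cutoff <- max(sig)
  } else {
    iCut <- max(which(gap == maxGap))
    cutoff <- sig[iCut]
  }
  isSuper <- sig > cutoff
  mc <- mcols(regions)
  mc$rank <- seq_len(n)
  mc$scaled_x <- x
  mc$scaled_y <- y
  mc$is_super <- isSuper
  if (!"factor_overlap" %in% colnames(mc)) mc$factor_overlap <- NA
  mcols(regions) <- mc
  new("EnhancerCalls",
      regions = regions, cutoffSignal = cutoff,
      nSuper = sum(isSuper), nSuperWithFactor = NA_integer_)
}

#' Annotate enhancer calls with factor co-occupancy
#'
#' A region is factor-associated iff it overlaps at least one retained
#' factor-binding peak by >= 1 bp (pass the peaks through [filterPeaks()]
#' first if thresholding is wanted). Recomputes the count of
#' factor-associated super-enhancers.
#'
#' @param result an [EnhancerCalls-class]
#' @param factorPeaks GRanges of factor peaks in the same coordinate
#'   system.
#' @return the updated [EnhancerCalls-class]
#' @export
annotateFactorOverlap <- function(result, factorPeaks) {
  reg <- result@regions
  ov <- findOverlaps(reg, factorPeaks, ignore.strand = TRUE)
  flag <- seq_along(reg) %in% S4Vectors::queryHits(ov)
  mc <- mcols(reg)
  mc$factor_overlap <- flag
  mcols(reg) <- mc
  result@regions <- reg
  result@nSuperWithFactor <- sum(flag & mc$is_super)
  result
}
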