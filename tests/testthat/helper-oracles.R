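# Independent brute-force oracles and fixture builders. Every oracle is a
# direct, unoptimized restatement of the operation's definition, sharing no
# code with the implementation it checks.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# -- fixtures -----------------------------------------------------------------

makeExperiment <- function(values, contexts, doses, reps) {
  nCond <- length(contexts) * length(doses)
  meta <- data.frame(
    context = factor(rep(contexts, each = length(doses) * reps),
                     levels = contexts),
    dose = rep(rep(doses, each = reps), length(contexts)),
    replicate = rep(seq_len(reps), nCond))
  ids <- sprintf("%s_d%s_r%d", meta$context, format(meta$dose, trim = TRUE),
                 meta$replicate)
  stopifnot(ncol(values) == nrow(meta))
  dimnames(values) <- list(
    if (is.null(rownames(values))) sprintf("g%03d", seq_len(nrow(values)))
    else rownames(values), ids)
  new("DoseResponseExperiment", SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = values),
    colData = DataFrame(meta, row.names = ids)))
}

randomPeakGR <- function(n, chrom = "chr1", maxPos = 5e6) {
  s <- sort(sample.int(maxPos, n))
  w <- sample(100:2000, n, replace = TRUE)
  gr <- GRanges(chrom, IRanges(s, width = w))
  mcols(gr) <- DataFrame(
    peak_id = sprintf("pk%03d", seq_len(n)),
    m_value = round(runif(n, 0, 1.5), 3),
    p_value = round(runif(n, 0, 0.2), 4),
    location_class = sample(c("promoter", "non_promoter"), n, TRUE),
    assigned_gene = NA_character_)
  gr
}

randomGeneGR <- function(n, chrom = "chr1", maxPos = 5e6) {
  tss <- sample(5000:maxPos, n)
  gr <- GRanges(chrom, IRanges(tss, width = 1L),
                strand = sample(c("+", "-"), n, TRUE))
  names(gr) <- sprintf("gene%03d", seq_len(n))
  gr
}

# -- oracles ------------------------------------------------------------------

# all-pairs Pearson network via cor.test (independent of the t-transform code)
oraclePccEdges <- function(mat, pccMin, pMax) {
  genes <- rownames(mat)
  out <- list()
  for (i in seq_len(nrow(mat) - 1L)) {
    for (j in (i + 1L):nrow(mat)) {
      ct <- suppressWarnings(cor.test(mat[i, ], mat[j, ]))
      if (!is.na(ct$estimate) && abs(ct$estimate) > pccMin &&
          ct$p.value < pMax)
        out[[length(out) + 1L]] <- c(genes[i], genes[j])
    }
  }
  if (!length(out)) return(character())
  sort(vapply(out, function(p) paste(sort(p), collapse = "|"), character(1)))
}

edgeKeys <- function(net) {
  e <- networkEdges(net)
  sort(paste(e$geneA, e$geneB, sep = "|"))
}

# row-by-row peak re-filter
oracleFilterIds <- function(peaks, mMin, pMax) {
  mc <- mcols(peaks)
  keep <- character()
  for (i in seq_along(peaks))
    if (mc$m_value[i] >= mMin && mc$p_value[i] < pMax)
      keep <- c(keep, mc$peak_id[i])
  keep
}

# exhaustive peak -> promoter assignment; replicates the strand-oriented
# window arithmetic of GenomicRanges::promoters() directly
oracleAssign <- function(peaks, genes, up, down) {
  assigned <- rep(NA_character_, length(peaks))
  for (i in seq_along(peaks)) {
    ps <- start(peaks)[i]; pe <- end(peaks)[i]
    pc <- as.character(seqnames(peaks))[i]
    best <- NULL; bestDist <- Inf
    for (g in seq_along(genes)) {
      if (as.character(seqnames(genes))[g] != pc) next
      tss <- start(genes)[g]
      if (as.character(strand(genes))[g] == "+") {
        ws <- tss - up; we <- tss + down - 1L
      } else {
        ws <- tss - down + 1L; we <- tss + up
      }
      if (ps <= we && pe >= ws) {
        d <- max(0L, ps - tss, tss - pe)
        gid <- names(genes)[g]
        if (d < bestDist || (d == bestDist && gid < best)) {
          best <- gid; bestDist <- d
        }
      }
    }
    if (!is.null(best)) assigned[i] <- best
  }
  assigned
}

# membership scan for pathway burden
oracleBurden <- function(gene, catalog) {
  n <- 0L; onc <- 0L
  sets <- pathwaySets(catalog); flags <- oncogenicFlags(catalog)
  for (pid in names(sets)) {
    if (gene %in% sets[[pid]]) {
      n <- n + 1L
      if (flags[[pid]]) onc <- onc + 1L
    }
  }
  c(n, onc)
}

# one-pass interval merge on 0-based half-open coordinates
oracleStitch <- function(regions, dist) {
  df <- data.frame(chrom = as.character(seqnames(regions)),
                   start0 = start(regions) - 1L, end0 = end(regions),
                   signal = mcols(regions)$signal)
  df <- df[order(df$chrom, df$start0, df$end0), ]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (is.null(cur) || r$chrom != cur$chrom ||
        r$start0 - cur$end0 >= dist) {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- r
    } else {
      cur$end0 <- max(cur$end0, r$end0)
      cur$signal <- cur$signal + r$signal
    }
  }
  out[[length(out) + 1L]] <- cur
  do.call(rbind, out)
}

# adjacency scan for the ego network
oracleNeighbors <- function(net, center) {
  e <- networkEdges(net)
  nb <- character()
  for (i in seq_len(nrow(e))) {
    if (e$geneA[i] == center) nb <- c(nb, e$geneB[i])
    if (e$geneB[i] == center) nb <- c(nb, e$geneA[i])
  }
  sort(unique(nb))
}

# exhaustive best 2-partition (k-means objective) of a small point set
oracleBest2Partition <- function(x) {
  n <- nrow(x)
  bestObj <- Inf; bestAssign <- NULL
  for (code in 1:(2^(n - 1L) - 1L)) {      # fix point 1 in group 0
    bits <- as.integer(intToBits(code))[seq_len(n)]
    if (all(bits == 0L) || all(bits == 1L)) next
    obj <- 0
    for (g in 0:1) {
      pts <- x[bits == g, , drop = FALSE]
      ctr <- colMeans(pts)
      obj <- obj + sum(sweep(pts, 2L, ctr)^2)
    }
    if (obj < bestObj) { bestObj <- obj; bestAssign <- bits }
  }
  list(assign = bestAssign, objective = bestObj)
}
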