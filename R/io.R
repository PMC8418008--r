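# Readers and writers for every on-disk format the pipeline touches.
#
# Conventions: tab-separated tables; BED-style files use 0-based half-open
# coordinates (converted to 1-based GRanges in memory); numeric values are
# serialized with 10 significant digits so write/read round-trips are
# lossless at printed precision. Readers validate strictly and report the
# file, line and field of the first offending record rather than coercing.

.fmtNum <- function(x) sprintf("%.10g", x)

.ioStop <- function(path, line, field, msg) {
  stop(sprintf("%s (file '%s', line %d, field '%s')", msg, path,
               as.integer(line), field), call. = FALSE)
}

.sampleIdPattern <- "^(.+)_d([0-9.]+(?:[eE][+-]?[0-9]+)?)_r([0-9]+)$"

#' Write / read an expression matrix as TSV
#'
#' Genes as rows; the header carries sample ids of the form
#' `<context>_d<dose>_r<replicate>` from which the sample metadata is
#' reconstructed on read. `writeExpression` also returns the path invisibly.
#'
#' @param x a [DoseResponseExperiment-class]
#' @param path file path.
#' @return `readExpression` returns a [DoseResponseExperiment-class].
#' @export
writeExpression <- function(x, path) {
  stopifnot(is(x, "DoseResponseExperiment"))
  m <- assay(x, "log2expr")
  lines <- c(paste(c("gene_id", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], .fmtNum(m[i, ])), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeExpression
#' @export
readExpression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty expression file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[1L] != "gene_id")
    .ioStop(path, 1L, "header", "malformed header: first field must be 'gene_id'")
  sampleIds <- header[-1L]
  if (anyDuplicated(sampleIds))
    .ioStop(path, 1L, "header",
            paste("duplicate sample id:", sampleIds[duplicated(sampleIds)][1L]))
  mm <- regmatches(sampleIds, regexec(.sampleIdPattern, sampleIds))
  bad <- which(lengths(mm) != 4L)
  if (length(bad))
    .ioStop(path, 1L, sampleIds[bad[1L]],
            "sample id lacks context/dose/replicate tokens")
  meta <- data.frame(
    context   = vapply(mm, `[`, character(1), 2L),
    dose      = as.numeric(vapply(mm, `[`, character(1), 3L)),
    replicate = as.integer(vapply(mm, `[`, character(1), 4L)))
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  geneIds <- vapply(body, `[`, character(1), 1L)
  dup <- which(duplicated(geneIds))
  if (length(dup))
    .ioStop(path, dup[1L] + 1L, "gene_id",
            paste("duplicated gene row:", geneIds[dup[1L]]))
  vals <- matrix(NA_real_, length(body), length(sampleIds))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != length(sampleIds) + 1L)
      .ioStop(path, i + 1L, "row", "wrong number of fields")
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v) || any(!is.finite(v)))
      .ioStop(path, i + 1L, sampleIds[which(!is.finite(v))[1L]],
              "expression value is not a finite number")
    vals[i, ] <- v
  }
  dimnames(vals) <- list(geneIds, sampleIds)
  meta$context <- factor(meta$context, levels = unique(meta$context))
  out <- new("DoseResponseExperiment", SummarizedExperiment(
    assays = list(log2expr = vals),
    colData = DataFrame(meta, row.names = sampleIds)))
  validObject(out)
  out
}

#' Write / read a gene annotation table (TSV)
#'
#' Columns: gene_id, chrom, tss (0-based bp), strand.
#'
#' @param genes GRanges as returned by [geneAnnotation()], or a
#'   [DoseResponseExperiment-class].
#' @param path file path.
#' @return `readGeneAnnotation` returns a named GRanges of width-1 TSS
#'   positions.
#' @export
writeGeneAnnotation <- function(genes, path) {
  if (is(genes, "DoseResponseExperiment")) genes <- geneAnnotation(genes)
  lines <- c("gene_id\tchrom\ttss\tstrand",
             sprintf("%s\t%s\t%d\t%s", names(genes),
                     as.character(seqnames(genes)), start(genes) - 1L,
                     as.character(strand(genes))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGeneAnnotation
#' @export
readGeneAnnotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% colnames(df)))
    .ioStop(path, 1L, "header", "gene annotation needs gene_id/chrom/tss/strand")
  if (anyDuplicated(df$gene_id))
    .ioStop(path, which(duplicated(df$gene_id))[1L] + 1L, "gene_id",
            "duplicate gene id")
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    .ioStop(path, bad[1L] + 1L, "strand", "strand must be '+' or '-'")
  gr <- GRanges(df$chrom, IRanges(df$tss + 1L, width = 1L),
                strand = df$strand)
  names(gr) <- df$gene_id
  gr
}

#' Write / read a factor-binding peak table (BED6+3)
#'
#' Canonical six BED columns (chrom, start, end, name, score, strand; score
#' and strand written as ".") followed by `m_value`, `p_value` and
#' `location_class` (promoter / non_promoter). Coordinates on disk are
#' 0-based half-open.
#'
#' @param peaks GRanges with mcols peak_id, m_value, p_value,
#'   location_class (and optionally assigned_gene).
#' @param path file path.
#' @return `readPeaks` returns such a GRanges (assigned_gene set to NA).
#' @export
writePeaks <- function(peaks, path) {
  mc <- mcols(peaks)
  lines <- sprintf("%s\t%d\t%d\t%s\t.\t.\t%s\t%s\t%s",
                   as.character(seqnames(peaks)), start(peaks) - 1L,
                   end(peaks), mc$peak_id, .fmtNum(mc$m_value),
                   .fmtNum(mc$p_value), mc$location_class)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writePeaks
#' @export
readPeaks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(fields)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 9L)
      .ioStop(path, i, "row", "BED6+3 peak row needs 9 tab-separated fields")
    s <- suppressWarnings(as.numeric(f[2L])); e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e))
      .ioStop(path, i, "start/end", "coordinates must be numeric")
    if (s >= e)
      .ioStop(path, i, "start/end", "start must be < end (0-based half-open)")
    m <- suppressWarnings(as.numeric(f[7L]))
    p <- suppressWarnings(as.numeric(f[8L]))
    if (is.na(m)) .ioStop(path, i, "m_value", "M-value must be numeric")
    if (is.na(p) || p < 0 || p > 1)
      .ioStop(path, i, "p_value", "P-value must lie in [0, 1]")
    if (!f[9L] %in% c("promoter", "non_promoter"))
      .ioStop(path, i, "location_class",
              "location_class must be 'promoter' or 'non_promoter'")
    out[[i]] <- list(chrom = f[1L], start0 = s, end0 = e, id = f[4L],
                     m = m, p = p, loc = f[9L])
  }
  gr <- GRanges(vapply(out, `[[`, character(1), "chrom"),
                IRanges(vapply(out, `[[`, numeric(1), "start0") + 1,
                        vapply(out, `[[`, numeric(1), "end0")))
  mcols(gr) <- DataFrame(
    peak_id        = vapply(out, `[[`, character(1), "id"),
    m_value        = vapply(out, `[[`, numeric(1), "m"),
    p_value        = vapply(out, `[[`, numeric(1), "p"),
    location_class = vapply(out, `[[`, character(1), "loc"),
    assigned_gene  = NA_character_)
  gr
}

#' Write / read an enhancer signal table (BED4+1)
#'
#' Columns: chrom, start, end (0-based half-open), region_id, signal.
#'
#' @param regions GRanges with mcols region_id and signal.
#' @param path file path.
#' @return `readEnhancerSignal` returns such a GRanges with
#'   `factor_overlap` initialized to NA.
#' @export
writeEnhancerSignal <- function(regions, path) {
  mc <- mcols(regions)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s",
                   as.character(seqnames(regions)), start(regions) - 1L,
                   end(regions), mc$region_id, .fmtNum(mc$signal))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeEnhancerSignal
#' @export
readEnhancerSignal <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 5L)
      .ioStop(path, i, "row", "BED4+1 enhancer row needs 5 fields")
    s <- suppressWarnings(as.numeric(f[2L])); e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e) || s >= e)
      .ioStop(path, i, "start/end", "need numeric start < end")
    sig <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(sig) || sig < 0)
      .ioStop(path, i, "signal", "signal must be a non-negative number")
  }
  gr <- GRanges(vapply(fields, `[`, character(1), 1L),
                IRanges(as.numeric(vapply(fields, `[`, character(1), 2L)) + 1,
                        as.numeric(vapply(fields, `[`, character(1), 3L))))
  mcols(gr) <- DataFrame(
    region_id      = vapply(fields, `[`, character(1), 4L),
    signal         = as.numeric(vapply(fields, `[`, character(1), 5L)),
    factor_overlap = NA)
  gr
}

#' Write / read a pathway catalog (GMT)
#'
#' Standard GMT: one pathway per line, tab-separated
#' `id<TAB>description<TAB>gene1<TAB>gene2...`. Oncogenic flags are not part
#' of GMT; on read they default to name-matching the tumorigenesis-related
#' families used by the ranking (RAS / cell cycle / pluripotency-stemness /
#' ubiquitin), or can be supplied explicitly as a character vector of
#' pathway ids.
#'
#' @param catalog a [PathwayCatalog-class]
#' @param path file path.
#' @param oncogenic NULL (name-matching default) or character vector of
#'   pathway ids to flag.
#' @return `readGmt` returns a [PathwayCatalog-class].
#' @export
writeGmt <- function(catalog, path) {
  ids <- names(catalog@sets)
  lines <- vapply(ids, function(id)
    paste(c(id, catalog@descriptions[[id]], catalog@sets[[id]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

.defaultOncogenicRegex <- "RAS|CELL.?CYCLE|PLURIPOTEN|STEM|UBIQUITIN"

#' @rdname writeGmt
#' @export
readGmt <- function(path, oncogenic = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    .ioStop(path, short[1L], "row",
            "GMT line needs at least 3 tab-separated fields")
  ids <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    .ioStop(path, which(duplicated(ids))[1L], "id", "duplicate pathway id")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- ids
  desc <- stats::setNames(vapply(fields, `[`, character(1), 2L), ids)
  flags <- if (is.null(oncogenic))
    grepl(.defaultOncogenicRegex, ids, ignore.case = TRUE)
  else ids %in% oncogenic
  new("PathwayCatalog", sets = sets, descriptions = desc,
      oncogenic = stats::setNames(flags, ids))
}

#' Write / read a viability plate table (CSV)
#'
#' Columns: dose (uM; 0 for control/blank), od, role
#' (treated/control/blank), replicate. At least one control and one blank
#' row are required.
#'
#' @param viability data.frame as produced by [generateViability()].
#' @param path file path.
#' @return `readViability` returns the validated data.frame.
#' @export
writeViability <- function(viability, path) {
  lines <- c("dose,od,role,replicate",
             sprintf("%s,%s,%s,%d", .fmtNum(viability$dose),
                     .fmtNum(viability$od), viability$role,
                     as.integer(viability$replicate)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeViability
#' @export
readViability <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dose", "od", "role", "replicate")
  if (!all(need %in% colnames(df)))
    .ioStop(path, 1L, "header", "viability CSV needs dose,od,role,replicate")
  bad <- which(!df$role %in% c("treated", "control", "blank"))
  if (length(bad))
    .ioStop(path, bad[1L] + 1L, "role",
            "role must be treated, control or blank")
  if (!any(df$role == "control") || !any(df$role == "blank"))
    stop("viability table needs at least one control and one blank row (",
         path, ")", call. = FALSE)
  nf <- which(!is.finite(df$od))
  if (length(nf))
    .ioStop(path, nf[1L] + 1L, "od", "OD must be finite")
  df
}

#' Read a simulation configuration from a YAML file
#'
#' Recognized keys mirror the [simulationConfig()] arguments (snake_case
#' accepted); `driver:` may nest [driverSpec()] arguments. Unknown keys are
#' an error.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's value.
#' @return a [SimulationConfig-class]
#' @export
readSimulationConfig <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  toCamel <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
  names(y) <- toCamel(names(y))
  drvArgs <- list()
  if (!is.null(y$driver)) {
    drvArgs <- y$driver
    names(drvArgs) <- toCamel(names(drvArgs))
    y$driver <- NULL
  }
  known <- names(formals(simulationConfig))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  unknownD <- setdiff(names(drvArgs), names(formals(driverSpec)))
  if (length(unknownD))
    stop("unknown driver keys: ", paste(unknownD, collapse = ", "))
  y$driver <- do.call(driverSpec, drvArgs)
  if (!is.null(seed)) y$seed <- as.integer(seed)
  do.call(simulationConfig, y)
}
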