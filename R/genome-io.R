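#' Read a UCSC-style chrom.sizes table
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path file path.
#' @param species species identifier to attach to the assembly; defaults to
#'   the file name without the `.chrom.sizes` / extension suffix.
#' @return A [GenomeAssembly-class] whose `genomeSize()` is the sum of the
#'   lengths.
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1\t1000", "chr2\t500"), f)
#' genomeSize(readChromSizes(f, "toy"))  # 1500
#' @export
readChromSizes <- function(path, species = NULL) {
  if (is.null(species))
    species <- sub("\\.chrom\\.sizes$|\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) stop("empty chrom.sizes file: ", path)
  nm <- character(length(keep)); len <- numeric(length(keep))
  for (i in seq_along(keep)) {
    fields <- strsplit(trimws(lines[keep[i]]), "[ \t]+")[[1]]
    if (length(fields) < 2L || is.na(suppressWarnings(as.numeric(fields[2]))))
      stop(sprintf("malformed chrom.sizes line %d in %s", keep[i], path))
    nm[i] <- fields[1]
    len[i] <- as.numeric(fields[2])
    if (len[i] <= 0)
      stop(sprintf("non-positive chromosome length at line %d in %s",
                   keep[i], path))
  }
  if (anyDuplicated(nm))
    stop("duplicate chromosome name in ", path)
  names(len) <- nm
  GenomeAssembly(species, len)
}

#' Write a chrom.sizes table
#'
#' @param assembly a [GenomeAssembly-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeChromSizes <- function(assembly, path) {
  len <- chromLengths(assembly)
  writeLines(paste(names(len), format(len, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

#' Read an anchor table (7-column TSV)
#'
#' Columns: `chrom_a start_a end_a chrom_b start_b end_b strand`, 0-based
#' half-open coordinates; lines starting with `#` are ignored. Source-side
#' overlapping blocks are resolved by [AnchorSet()] (longer block kept, with
#' a warning).
#'
#' @param path file path.
#' @param source_assembly,target_assembly [GenomeAssembly-class]s used to
#'   validate coordinates.
#' @return An [AnchorSet-class].
#' @export
readAnchorTable <- function(path, source_assembly, target_assembly) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = .anchor_cols,
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "numeric", "numeric",
                                         "character"))
  AnchorSet(df, source_assembly, target_assembly)
}

#' Write an anchor table
#'
#' Inverse of [readAnchorTable()]; emits a commented header line followed by
#' the seven tab-separated columns.
#'
#' @param anchor_set an [AnchorSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAnchorTable <- function(anchor_set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(.anchor_cols, collapse = "\t")), con)
  b <- anchorBlocks(anchor_set)
  if (nrow(b)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s",
                     b$chrom_a, as.integer(b$start_a), as.integer(b$end_a),
                     b$chrom_b, as.integer(b$start_b), as.integer(b$end_b),
                     b$strand)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a UCSC chain file into an AnchorSet
#'
#' Every ungapped segment of every chain becomes one [AnchorSet-class]
#' block. The chain's `tName` side is taken as the source assembly and the
#' `qName` side as the target; minus-strand query coordinates are converted
#' to forward-strand 0-based half-open coordinates
#' (`start' = qSize - end`).
#'
#' @param path chain file path.
#' @param source_assembly,target_assembly [GenomeAssembly-class]s for the
#'   `tName` and `qName` sides respectively.
#' @return An [AnchorSet-class] with one block per ungapped segment.
#' @export
readChain <- function(path, source_assembly, target_assembly) {
  lines <- readLines(path)
  rows <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) { i <- i + 1L; next }
    fields <- strsplit(line, "[ \t]+")[[1]]
    if (fields[1] != "chain" || length(fields) < 12L)
      stop(sprintf("expected chain header at line %d of %s", i, path))
    tName <- fields[3];  tSize <- as.numeric(fields[4])
    tStart <- as.numeric(fields[6]); tEnd <- as.numeric(fields[7])
    qName <- fields[8];  qSize <- as.numeric(fields[9])
    qStrand <- fields[10]
    qStart <- as.numeric(fields[11]); qEnd <- as.numeric(fields[12])
    chain_id <- if (length(fields) >= 13L) fields[13] else NA_character_
    if (fields[5] != "+")
      stop(sprintf("chain %s: target strand must be '+'", chain_id))
    tpos <- tStart; qpos <- qStart
    i <- i + 1L
    repeat {
      if (i > length(lines)) stop(sprintf("chain %s: truncated", chain_id))
      fl <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      size <- as.numeric(fl[1])
      if (size > 0) {
        # query block on its native strand; flip '-' to forward coordinates
        qs <- qpos; qe <- qpos + size
        if (qStrand == "-") { tmp <- qs; qs <- qSize - qe; qe <- qSize - tmp }
        rows[[length(rows) + 1L]] <- data.frame(
          chrom_a = tName, start_a = tpos, end_a = tpos + size,
          chrom_b = qName, start_b = qs, end_b = qe,
          strand = qStrand, stringsAsFactors = FALSE)
      }
      if (length(fl) == 1L) { tpos <- tpos + size; qpos <- qpos + size; i <- i + 1L; break }
      tpos <- tpos + size + as.numeric(fl[2])
      qpos <- qpos + size + as.numeric(fl[3])
      i <- i + 1L
    }
    if (tpos != tEnd || qpos != qEnd)
      stop(sprintf("chain %s: declared extents do not match consumed block lengths",
                   chain_id))
  }
  blocks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom_a = character(), start_a = numeric(), end_a = numeric(),
               chrom_b = character(), start_b = numeric(), end_b = numeric(),
               strand = character())
  AnchorSet(blocks, source_assembly, target_assembly)
}

#' Read a bedGraph signal track
#'
#' Uncovered positions take value 0; overlapping records and negative
#' values are errors.
#'
#' @param path bedGraph file path.
#' @param assembly the [GenomeAssembly-class] the signal lives on.
#' @return A [SignalTrack-class].
#' @export
readSignalBedGraph <- function(path, assembly) {
  lines <- readLines(path, n = 200L)
  has_data <- any(nzchar(trimws(lines)) &
                  !grepl("^(#|track|browser)", trimws(lines)))
  if (!has_data) {
    return(SignalTrack(data.frame(chrom = character(), start = numeric(),
                                  end = numeric(), value = numeric()),
                       assembly))
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  rec <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    value = as.numeric(gr$score))
  SignalTrack(rec, assembly)
}

#' Write a SignalTrack as bedGraph
#'
#' Zero-valued runs are omitted.
#'
#' @param track a [SignalTrack-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSignalBedGraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track@coverage)) {
    rle <- track@coverage[[chrom]]
    ends <- cumsum(as.numeric(S4Vectors::runLength(rle)))
    starts <- c(0, ends[-length(ends)])
    vals <- S4Vectors::runValue(rle)
    keep <- vals != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", chrom, as.integer(starts[keep]),
                         as.integer(ends[keep]), vals[keep]), con)
  }
  invisible(path)
}

#' Read a BED3/BED4 file as intervals on an assembly
#'
#' @param path BED file path.
#' @param assembly the [GenomeAssembly-class] to validate against.
#' @return A [GenomicRanges::GRanges] (1-based, per GRanges convention)
#'   with the assembly's seqinfo.
#' @export
readBed <- function(path, assembly) {
  gr <- rtracklayer::import(path, format = "bed")
  len <- chromLengths(assembly)
  chr <- as.character(GenomicRanges::seqnames(gr))
  if (!all(chr %in% names(len)))
    stop("BED interval on unknown chromosome in ", path)
  if (any(GenomicRanges::end(gr) > len[chr]))
    stop("BED interval out of chromosome bounds in ", path)
  GenomeInfoDb::seqlevels(gr) <- names(len)
  GenomeInfoDb::seqinfo(gr) <- seqinfo(assembly)
  gr
}

# Mean signal over 0-based half-open windows on one chromosome.
trackBinMeans <- function(track, chrom, starts, ends) {
  rle <- track@coverage[[chrom]]
  if (is.null(rle)) stop("no signal on chromosome ", chrom)
  v <- IRanges::Views(rle, start = starts + 1L, end = ends)
  IRanges::viewMeans(v)
}
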