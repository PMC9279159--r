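#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom GenomeInfoDb Seqinfo seqnames seqlengths
NULL

#' GenomeAssembly: a species label plus its chromosome sizes
#'
#' Thin wrapper around a [GenomeInfoDb::Seqinfo] carrying the species
#' identifier and the total genome size. All coordinates handled by this
#' package are validated against the assembly they live on.
#'
#' @slot species single character species identifier (e.g. `"danRer"`).
#' @slot seqinfo a `Seqinfo` with one entry per chromosome.
#' @export
setClass("GenomeAssembly",
  slots = c(species = "character", seqinfo = "Seqinfo"))

setValidity("GenomeAssembly", function(object) {
  msg <- character()
  if (length(object@species) != 1L || is.na(object@species) ||
      !nzchar(object@species))
    msg <- c(msg, "'species' must be a single non-empty string")
  len <- seqlengths(object@seqinfo)
  if (length(len) == 0L)
    msg <- c(msg, "assembly has no chromosomes")
  if (anyNA(len) || any(len <= 0))
    msg <- c(msg, "all chromosome lengths must be positive")
  if (anyDuplicated(seqnames(object@seqinfo)))
    msg <- c(msg, "chromosome names must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAssembly
#'
#' @param species species identifier.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @return A [GenomeAssembly-class] object.
#' @examples
#' GenomeAssembly("toy", c(chr1 = 1000, chr2 = 500))
#' @export
GenomeAssembly <- function(species, chrom_lengths) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("'chrom_lengths' must be a named vector")
  si <- Seqinfo(seqnames = names(chrom_lengths),
                seqlengths = as.integer(round(chrom_lengths)),
                genome = species)
  new("GenomeAssembly", species = species, seqinfo = si)
}

#' AnchorSet: collinear aligned blocks between two assemblies
#'
#' Each row of `blocks` is one ungapped aligned block (an "anchor point")
#' between the source and target assemblies. Coordinates are 0-based
#' half-open (BED convention). On the source side the blocks are
#' non-overlapping and sorted by `(chrom_a, start_a)`; overlapping input
#' blocks are resolved at construction by keeping the longer one.
#'
#' @slot source_species,target_species species identifiers.
#' @slot source_assembly,target_assembly the two [GenomeAssembly-class]s.
#' @slot blocks data.frame with columns `chrom_a, start_a, end_a, chrom_b,
#'   start_b, end_b, strand` (strand of the target relative to the source).
#' @export
setClass("AnchorSet",
  slots = c(source_species = "character", target_species = "character",
            source_assembly = "GenomeAssembly",
            target_assembly = "GenomeAssembly",
            blocks = "data.frame"))

.anchor_cols <- c("chrom_a", "start_a", "end_a",
                  "chrom_b", "start_b", "end_b", "strand")

setValidity("AnchorSet", function(object) {
  b <- object@blocks
  msg <- character()
  if (!all(.anchor_cols %in% names(b)))
    return(paste("blocks must have columns:", paste(.anchor_cols, collapse = ", ")))
  if (nrow(b)) {
    if (any(b$start_a >= b$end_a) || any(b$start_b >= b$end_b))
      msg <- c(msg, "all blocks must satisfy start < end on both sides")
    if (!all(b$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
    la <- chromLengths(object@source_assembly)
    lb <- chromLengths(object@target_assembly)
    if (!all(b$chrom_a %in% names(la)) || !all(b$chrom_b %in% names(lb)))
      msg <- c(msg, "unknown chromosome name")
    else if (any(b$start_a < 0) || any(b$end_a > la[b$chrom_a]) ||
             any(b$start_b < 0) || any(b$end_b > lb[b$chrom_b]))
      msg <- c(msg, "block coordinates out of chromosome bounds")
    o <- order(b$chrom_a, b$start_a)
    if (!identical(o, seq_len(nrow(b))))
      msg <- c(msg, "blocks must be sorted by (chrom_a, start_a)")
    else {
      same <- b$chrom_a[-1L] == b$chrom_a[-nrow(b)]
      if (nrow(b) > 1L && any(same & b$start_a[-1L] < b$end_a[-nrow(b)]))
        msg <- c(msg, "source-side blocks must be non-overlapping")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnchorSet, resolving source-side overlaps
#'
#' Input blocks that overlap on the source side are resolved
#' deterministically: the longer (source-side) block is kept, the shorter
#' dropped with a warning. Blocks are then sorted by `(chrom_a, start_a)`.
#'
#' @param blocks data.frame with columns `chrom_a, start_a, end_a, chrom_b,
#'   start_b, end_b, strand`; 0-based half-open coordinates.
#' @param source_assembly,target_assembly [GenomeAssembly-class] objects the
#'   coordinates are validated against.
#' @return An [AnchorSet-class].
#' @export
AnchorSet <- function(blocks, source_assembly, target_assembly) {
  blocks <- as.data.frame(blocks)[, .anchor_cols]
  for (col in c("start_a", "end_a", "start_b", "end_b"))
    blocks[[col]] <- as.numeric(blocks[[col]])
  blocks$strand <- as.character(blocks$strand)
  if (nrow(blocks)) {
    if (any(blocks$start_a >= blocks$end_a) || any(blocks$start_b >= blocks$end_b))
      stop("anchor block with end <= start")
    keep <- rep(TRUE, nrow(blocks))
    for (chrom in unique(blocks$chrom_a)) {
      idx <- which(blocks$chrom_a == chrom)
      w <- blocks$end_a[idx] - blocks$start_a[idx]
      # greedy by decreasing source width; drop anything hitting a kept block
      ord <- idx[order(-w, blocks$start_a[idx], idx)]
      kept_ir <- IRanges::IRanges()
      for (i in ord) {
        ir <- IRanges::IRanges(blocks$start_a[i] + 1L, blocks$end_a[i])
        if (IRanges::countOverlaps(ir, kept_ir) > 0L) {
          keep[i] <- FALSE
          warning(sprintf(
            "dropping source-overlapping anchor block %s:%d-%d (shorter of an overlapping pair)",
            chrom, blocks$start_a[i], blocks$end_a[i]), call. = FALSE)
        } else {
          kept_ir <- c(kept_ir, ir)
        }
      }
    }
    blocks <- blocks[keep, , drop = FALSE]
    blocks <- blocks[order(blocks$chrom_a, blocks$start_a), , drop = FALSE]
    rownames(blocks) <- NULL
  }
  new("AnchorSet", source_species = speciesId(source_assembly),
      target_species = speciesId(target_assembly),
      source_assembly = source_assembly, target_assembly = target_assembly,
      blocks = blocks)
}

#' SignalTrack: per-base coverage signal on an assembly
#'
#' Stores a non-negative step-wise signal (e.g. ChIP-seq coverage) as one
#' run-length encoded vector per chromosome; positions not covered by any
#' input record have value 0.
#'
#' @slot assembly the [GenomeAssembly-class] the signal lives on.
#' @slot coverage named list of [S4Vectors::Rle] vectors, one per
#'   chromosome, each of the full chromosome length.
#' @export
setClass("SignalTrack",
  slots = c(assembly = "GenomeAssembly", coverage = "list"))

setValidity("SignalTrack", function(object) {
  len <- chromLengths(object@assembly)
  if (!all(names(object@coverage) %in% names(len)))
    return("coverage chromosome not in assembly")
  for (chrom in names(object@coverage)) {
    rle <- object@coverage[[chrom]]
    if (length(rle) != len[[chrom]])
      return(sprintf("coverage length mismatch on %s", chrom))
    if (min(S4Vectors::runValue(rle)) < 0)
      return("signal values must be >= 0")
  }
  TRUE
})

#' Construct a SignalTrack from interval records
#'
#' @param records data.frame with columns `chrom, start, end, value`
#'   (0-based half-open); intervals must not overlap and values must be
#'   non-negative. May have zero rows (all-zero track).
#' @param assembly the [GenomeAssembly-class] the records live on.
#' @return A [SignalTrack-class].
#' @export
SignalTrack <- function(records, assembly) {
  len <- chromLengths(assembly)
  cov <- lapply(len, function(L) S4Vectors::Rle(0, L))
  if (nrow(records)) {
    if (any(records$value < 0))
      stop("negative signal value in track records")
    if (!all(records$chrom %in% names(len)))
      stop("track record on unknown chromosome")
    if (any(records$start < 0) || any(records$end > len[records$chrom]) ||
        any(records$start >= records$end))
      stop("track record with invalid coordinates")
    for (chrom in unique(records$chrom)) {
      r <- records[records$chrom == chrom, , drop = FALSE]
      ir <- IRanges::IRanges(r$start + 1L, r$end)
      if (!IRanges::isDisjoint(ir))
        stop(sprintf("overlapping signal records on %s", chrom))
      cov[[chrom]] <- IRanges::coverage(ir, weight = r$value,
                                        width = len[[chrom]])
    }
  }
  new("SignalTrack", assembly = assembly, coverage = cov)
}

#' ScoringParams: the anchor-distance scoring configuration
#'
#' The scoring function returns `f(d) = 2^(-d / half_life)` for a query at
#' distance `d` bp from its nearest flanking anchor: 1 on an anchor, 0.5 at
#' the distance half-life. Written with the per-species scaling factor
#' `s = -half_life / (g * log 0.5)` the same function is
#' `f(d) = exp(-d / (g * s))`; the genome size `g` cancels.
#'
#' @slot half_life distance half-life in bp (default 10000).
#' @export
setClass("ScoringParams", slots = c(half_life = "numeric"))

setValidity("ScoringParams", function(object) {
  if (length(object@half_life) != 1L || is.na(object@half_life) ||
      object@half_life <= 0)
    "'half_life' must be a single positive number" else TRUE
})

#' @param half_life distance half-life in bp.
#' @rdname ScoringParams-class
#' @examples
#' ScoringParams(10000)
#' @export
ScoringParams <- function(half_life = 10000) {
  new("ScoringParams", half_life = as.numeric(half_life))
}

#' SpeciesGraph: species as nodes, pairwise anchor sets as directed edges
#'
#' @slot species character vector of node identifiers.
#' @slot edges named list of [AnchorSet-class]s; element `"A|B"` is the
#'   anchor set used to project coordinates from species A to species B.
#' @export
setClass("SpeciesGraph", slots = c(species = "character", edges = "list"))

setValidity("SpeciesGraph", function(object) {
  for (key in names(object@edges)) {
    as_ <- object@edges[[key]]
    if (!is(as_, "AnchorSet")) return("all edges must be AnchorSet objects")
    expected <- paste(as_@source_species, as_@target_species, sep = "|")
    if (!identical(key, expected))
      return(sprintf("edge key '%s' does not match its AnchorSet (%s)", key, expected))
    if (!all(c(as_@source_species, as_@target_species) %in% object@species))
      return("edge references a species not in the node set")
  }
  TRUE
})

#' Construct a SpeciesGraph from anchor sets
#'
#' @param ... [AnchorSet-class] objects (or a single list of them). Each
#'   anchor set contributes one directed edge from its source to its target
#'   species; supply reciprocal sets to obtain both directions.
#' @return A [SpeciesGraph-class].
#' @export
SpeciesGraph <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "AnchorSet"))
    sets <- sets[[1]]
  edges <- list()
  sp <- character()
  for (as_ in sets) {
    stopifnot(is(as_, "AnchorSet"))
    key <- paste(as_@source_species, as_@target_species, sep = "|")
    if (key %in% names(edges))
      stop(sprintf("duplicate edge %s", key))
    edges[[key]] <- as_
    sp <- union(sp, c(as_@source_species, as_@target_species))
  }
  new("SpeciesGraph", species = sort(sp), edges = edges)
}

#' ProjectionResult: one projected coordinate with its score and path
#'
#' @slot query_chrom,query_pos the source coordinate (0-based).
#' @slot target_chrom,target_pos the projected coordinate (`NA` if
#'   unprojectable).
#' @slot score projection score in \[0, 1\]; the product of the
#'   anchor-distance scores along the species path (0 if unprojectable).
#' @slot path ordered character vector of species visited, starting at the
#'   source species (empty if unprojectable).
#' @slot step_distances per-step anchor distances in bp, one per traversed
#'   edge, attributed to the edge's source species.
#' @export
setClass("ProjectionResult",
  slots = c(query_chrom = "character", query_pos = "numeric",
            target_chrom = "character", target_pos = "numeric",
            score = "numeric", path = "character",
            step_distances = "numeric"))

#' EnrichmentTest: a 2x2 contingency table with Fisher's exact test
#'
#' @slot table 2x2 integer matrix of counts.
#' @slot odds_ratio sample odds ratio `ad / bc` (`Inf` or 0 when a
#'   denominator or numerator is zero; `NaN` if both).
#' @slot p_value two-sided Fisher's exact p-value.
#' @slot degenerate `TRUE` when a table margin is zero, in which case the
#'   test carries no information.
#' @export
setClass("EnrichmentTest",
  slots = c(table = "matrix", odds_ratio = "numeric", p_value = "numeric",
            degenerate = "logical"))
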