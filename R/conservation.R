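#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
NULL

# GRanges (1-based closed) -> internal 0-based half-open data.frame.
.gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) as.character(gr$name) else
               paste0("iv", seq_along(gr)),
             stringsAsFactors = FALSE)
}

.intervals_df <- function(x) {
  if (is(x, "GRanges")) return(.gr_to_df(x))
  x <- as.data.frame(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (is.null(x$name)) x$name <- paste0("iv", seq_len(nrow(x)))
  x
}

# TRUE for each interval overlapping >= 1 bp of a source-side anchor block.
.overlaps_direct <- function(df, anchor_set) {
  b <- anchorBlocks(anchor_set)
  out <- logical(nrow(df))
  if (nrow(b) == 0L || nrow(df) == 0L) return(out)
  for (chrom in unique(df$chrom)) {
    qi <- which(df$chrom == chrom)
    bi <- b$chrom_a == chrom
    if (!any(bi)) next
    q <- IRanges::IRanges(df$start[qi] + 1L, df$end[qi])
    s <- IRanges::IRanges(b$start_a[bi] + 1L, b$end_a[bi])
    out[qi] <- IRanges::countOverlaps(q, s) > 0L
  }
  out
}

#' Classify regulatory elements as DC / IC / NC
#'
#' Directly conserved (DC) elements overlap at least 1 bp of a direct
#' source-to-target anchor block. Elements that do not are projected
#' through the species graph: indirectly conserved (IC) if the projection
#' score strictly exceeds `threshold` (default 0.99, i.e. within < 150 bp
#' total anchor distance at the default 10 kb half-life), non-conserved
#' (NC) otherwise, including unprojectable elements. The three labels
#' partition the input.
#'
#' @param peaks query elements: a `GRanges` or a data.frame with columns
#'   `chrom, start, end` (0-based half-open) and optional `name`.
#' @param direct_anchor_set the direct source-to-target
#'   [AnchorSet-class] defining DC.
#' @param graph a [SpeciesGraph-class] containing the direct pair and any
#'   bridging species.
#' @param target_species target species identifier.
#' @param params a [ScoringParams-class].
#' @param threshold IC score threshold, strict inequality (default 0.99).
#' @param reference_point `"midpoint"` projects the peak midpoint;
#'   `"endpoints"` projects both ends and keeps the better score.
#' @param target_peaks optional target-species elements (same formats); when
#'   given, an annotation column flags whether the projected point falls in
#'   one (never used as a class criterion).
#' @return A data.frame with one row per peak: coordinates, `label`
#'   (`DC`/`IC`/`NC`), `score`, `path`, `target_chrom`, `target_pos`, and
#'   optionally `target_peak_overlap`.
#' @export
classifyConservation <- function(peaks, direct_anchor_set, graph,
                                 target_species, params = ScoringParams(),
                                 threshold = 0.99,
                                 reference_point = c("midpoint", "endpoints"),
                                 target_peaks = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  reference_point <- match.arg(reference_point)
  df <- .intervals_df(peaks)
  source_species <- direct_anchor_set@source_species
  n <- nrow(df)
  out <- data.frame(df[, c("chrom", "start", "end", "name")],
                    label = rep("NC", n), score = rep(NA_real_, n),
                    path = rep("", n),
                    target_chrom = rep(NA_character_, n),
                    target_pos = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  dc <- .overlaps_direct(df, direct_anchor_set)
  out$label[dc] <- "DC"
  project_one <- function(chrom, pos) {
    shortestPathProject(graph, source_species, target_species, chrom, pos,
                        params)
  }
  for (i in seq_len(n)) {
    mid <- floor((df$start[i] + df$end[i]) / 2)
    r <- if (reference_point == "midpoint") {
      project_one(df$chrom[i], mid)
    } else {
      r1 <- project_one(df$chrom[i], df$start[i])
      r2 <- project_one(df$chrom[i], df$end[i])
      if (projectionScore(r1) >= projectionScore(r2)) r1 else r2
    }
    out$score[i] <- r@score
    out$path[i] <- paste(r@path, collapse = ",")
    out$target_chrom[i] <- r@target_chrom
    out$target_pos[i] <- r@target_pos
    if (!dc[i] && r@score > threshold) out$label[i] <- "IC"
  }
  if (!is.null(target_peaks)) {
    tp <- .intervals_df(target_peaks)
    out$target_peak_overlap <- vapply(seq_len(n), function(i) {
      if (is.na(out$target_pos[i])) return(FALSE)
      any(tp$chrom == out$target_chrom[i] &
          tp$start <= out$target_pos[i] & out$target_pos[i] < tp$end)
    }, logical(1))
  }
  out
}

#' Summarize conservation calls
#'
#' @param calls output of [classifyConservation()].
#' @return List with `counts` and `fractions` over the labels DC, IC, NC
#'   (fractions sum to 1; all zero for empty input).
#' @export
conservationSummary <- function(calls) {
  labels <- c("DC", "IC", "NC")
  counts <- vapply(labels, function(l) sum(calls$label == l), numeric(1))
  fractions <- if (nrow(calls)) counts / nrow(calls) else counts
  list(counts = counts, fractions = fractions)
}
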