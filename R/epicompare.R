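#' Tile regions into fixed-width bins
#'
#' Each region is split into consecutive `bin_size` windows; a final
#' partial window is kept when it is at least half a bin wide, otherwise
#' dropped. Regions shorter than half a bin produce no bins (with a
#' warning).
#'
#' @param regions a `GRanges` or data.frame with `chrom, start, end`
#'   (0-based half-open) and optional `name`.
#' @param bin_size window width in bp (default 1000).
#' @return data.frame with columns `region, chrom, start, end, center`
#'   (0-based half-open; `center = floor((start+end)/2)`).
#' @examples
#' binRegions(data.frame(chrom = "chr1", start = 0, end = 10600))  # 11 bins
#' @export
binRegions <- function(regions, bin_size = 1000) {
  stopifnot(bin_size > 0)
  df <- .intervals_df(regions)
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    width <- df$end[i] - df$start[i]
    n_full <- width %/% bin_size
    rem <- width %% bin_size
    n <- n_full + (rem >= bin_size / 2)
    if (n == 0L) {
      warning(sprintf("region %s shorter than half a bin; no bins emitted",
                      df$name[i]), call. = FALSE)
      next
    }
    starts <- df$start[i] + bin_size * (seq_len(n) - 1)
    ends <- pmin(starts + bin_size, df$end[i])
    rows[[i]] <- data.frame(region = df$name[i], chrom = df$chrom[i],
                            start = starts, end = ends,
                            center = floor((starts + ends) / 2),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region = character(), chrom = character(),
                      start = numeric(), end = numeric(), center = numeric())
  rownames(out) <- NULL
  out
}

#' Empirical quantile ranks
#'
#' Replaces each value by its empirical quantile `rank / n` in `(0, 1]`;
#' ties receive the mean rank. Invariant under any strictly monotone
#' transform of the input.
#'
#' @param values numeric vector.
#' @return Quantiles in `(0, 1]`.
#' @examples
#' quantileRank(c(1, 2, 3, 4))  # 0.25 0.50 0.75 1.00
#' @export
quantileRank <- function(values) {
  if (length(values) == 0L) return(numeric())
  rank(values, ties.method = "average") / length(values)
}

#' Mean signal per bin, as quantiles
#'
#' Computes each bin's mean coverage and converts the distribution to
#' empirical quantile ranks (the two-track quantile normalization: applying
#' this to both species puts their signal on a common uniform scale).
#'
#' @param track a [SignalTrack-class].
#' @param bins data.frame from [binRegions()] (columns `chrom, start, end`).
#' @return Numeric vector of per-bin quantiles in `(0, 1]`.
#' @export
binQuantiles <- function(track, bins) {
  quantileRank(binMeans(track, bins))
}

#' Mean signal per bin
#'
#' @inheritParams binQuantiles
#' @return Numeric vector of per-bin mean coverage.
#' @export
binMeans <- function(track, bins) {
  out <- numeric(nrow(bins))
  for (chrom in unique(bins$chrom)) {
    i <- bins$chrom == chrom
    out[i] <- trackBinMeans(track, chrom, bins$start[i], bins$end[i])
  }
  out
}

.bin_categories <- c("mutually-enriched", "source-specific",
                     "target-specific", "neither", "unprojectable")

#' Per-bin cross-species signal comparison
#'
#' Categorizes each projected bin pair by thresholding both quantile
#' signals at `enrich_q`: enriched in both species (`mutually-enriched`),
#' in one (`source-specific` / `target-specific`), or neither. The signal
#' overlap is summarized by the log2 signal ratio floored at `floor` and
#' capped to `[-cap, cap]`, and the signal amplitude by
#' `max(q_source, q_target)^10` (raising to the 10th power spreads the
#' compressed upper quantile range).
#'
#' @param q_source,q_target per-bin quantile signals in `[0, 1]`
#'   (vectorized).
#' @param enrich_q enrichment quantile threshold (default 0.8).
#' @param cap cap on the absolute log ratio (default 1).
#' @param floor value floor applied before the ratio (default 0.01).
#' @return data.frame with `q_source, q_target, category, ratio, amplitude`.
#' @examples
#' compareBins(0.9, 0.9)    # mutually-enriched, ratio 0, amplitude 0.9^10
#' compareBins(0.99, 0.01)  # source-specific, ratio capped at 1
#' @export
compareBins <- function(q_source, q_target, enrich_q = 0.8, cap = 1,
                        floor = 0.01) {
  stopifnot(length(q_source) == length(q_target))
  category <- rep("neither", length(q_source))
  category[q_source >= enrich_q & q_target >= enrich_q] <- "mutually-enriched"
  category[q_source >= enrich_q & q_target < enrich_q] <- "source-specific"
  category[q_source < enrich_q & q_target >= enrich_q] <- "target-specific"
  ratio <- pmin(pmax(log2(pmax(q_source, floor) / pmax(q_target, floor)),
                     -cap), cap)
  amplitude <- pmax(q_source, q_target)^10
  data.frame(q_source = q_source, q_target = q_target,
             category = category, ratio = ratio, amplitude = amplitude,
             stringsAsFactors = FALSE)
}

#' Cross-species comparison of binned signal over projected regions
#'
#' Tiles the source regions into `bin_size` windows, projects each bin
#' center through the species graph, retrieves the target signal from the
#' fixed `bin_size` grid bin containing the projected point, quantile
#' normalizes both per-bin signal distributions, and categorizes every bin
#' pair with [compareBins()]. Bins whose center cannot be projected are
#' emitted with category `unprojectable`.
#'
#' @param regions source regions (`GRanges` or data.frame, see
#'   [binRegions()]).
#' @param track_source,track_target [SignalTrack-class]s on the source and
#'   target assemblies.
#' @param graph a [SpeciesGraph-class], or a single [AnchorSet-class] for a
#'   purely pairwise comparison.
#' @param source_species,target_species node identifiers.
#' @param params a [ScoringParams-class].
#' @param direct_anchor_set optional direct [AnchorSet-class]; when given,
#'   each bin gets an `alignable` flag (bin center overlaps a direct
#'   block).
#' @param bin_size window width in bp (default 1000).
#' @param enrich_q enrichment quantile threshold (default 0.8).
#' @param use_quantiles compare quantile-normalized signal (default); set
#'   to `FALSE` to compute the ratio on raw mean coverage instead.
#' @param cap,floor see [compareBins()].
#' @return List with `bins` (per-bin table: source/target coordinates,
#'   quantiles, category, ratio, amplitude, score, alignable) and `summary`
#'   (per-region fraction of mutually-enriched bins, the ordering key for
#'   region-level displays).
#' @export
compareRegions <- function(regions, track_source, track_target, graph,
                           source_species, target_species,
                           params = ScoringParams(),
                           direct_anchor_set = NULL, bin_size = 1000,
                           enrich_q = 0.8, use_quantiles = TRUE,
                           cap = 1, floor = 0.01) {
  if (is(graph, "AnchorSet")) graph <- SpeciesGraph(graph)
  bins <- binRegions(regions, bin_size)
  n <- nrow(bins)
  src_val <- binMeans(track_source, bins)
  q_source <- quantileRank(src_val)
  proj <- projectPoints(graph, source_species, target_species,
                        bins$chrom, bins$center, params)
  tlen <- chromLengths(track_target@assembly)
  tstart <- rep(NA_real_, n); tend <- rep(NA_real_, n)
  tval <- rep(NA_real_, n)
  ok <- !is.na(proj$target_pos)
  if (any(ok)) {
    tstart[ok] <- (proj$target_pos[ok] %/% bin_size) * bin_size
    tend[ok] <- pmin(tstart[ok] + bin_size, tlen[proj$target_chrom[ok]])
    # clamp a projected point sitting exactly at the chromosome end
    bad <- ok & tstart >= tend
    tstart[bad] <- pmax(tend[bad] - bin_size, 0)
    for (chrom in unique(proj$target_chrom[ok])) {
      i <- ok & proj$target_chrom == chrom
      tval[i] <- trackBinMeans(track_target, chrom, tstart[i], tend[i])
    }
  }
  q_target <- rep(NA_real_, n)
  q_target[ok] <- quantileRank(tval[ok])
  category <- rep("unprojectable", n)
  ratio <- rep(NA_real_, n)
  amplitude <- rep(NA_real_, n)
  if (any(ok)) {
    cmp <- compareBins(q_source[ok], q_target[ok], enrich_q = enrich_q,
                       cap = cap, floor = floor)
    if (!use_quantiles)
      cmp$ratio <- pmin(pmax(log2(pmax(src_val[ok], floor) /
                                  pmax(tval[ok], floor)), -cap), cap)
    category[ok] <- cmp$category
    ratio[ok] <- cmp$ratio
    amplitude[ok] <- cmp$amplitude
  }
  out <- data.frame(bins, source_value = src_val,
                    target_chrom = proj$target_chrom,
                    target_start = tstart, target_end = tend,
                    target_value = tval,
                    q_source = q_source, q_target = q_target,
                    category = category, ratio = ratio,
                    amplitude = amplitude, score = proj$score,
                    stringsAsFactors = FALSE)
  if (!is.null(direct_anchor_set)) {
    centers <- data.frame(chrom = bins$chrom, start = bins$center,
                          end = bins$center + 1)
    out$alignable <- .overlaps_direct(centers, direct_anchor_set)
  }
  shared <- tapply(out$category == "mutually-enriched", bins$region, mean)
  summary <- data.frame(region = names(shared),
                        n_bins = as.vector(table(bins$region)[names(shared)]),
                        shared_fraction = as.numeric(shared),
                        stringsAsFactors = FALSE)
  summary <- summary[order(-summary$shared_fraction), ]
  rownames(summary) <- NULL
  list(bins = out, summary = summary)
}

# Two-sided Fisher p for cell a with row totals m, n2 and column-1 total k:
# sum of hypergeometric probabilities not exceeding the observed one.
.fisher_p <- function(a, m, n2, k) {
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value computed by summing all hypergeometric table
#' probabilities (at fixed margins) not exceeding that of the observed
#' table; the odds ratio is the sample odds ratio `ad / bc`.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   `[[a, b], [c, d]]`.
#' @return An [EnrichmentTest-class].
#' @examples
#' pValue(fisherExact2x2(5, 5, 5, 5))  # 1
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  if (sum(counts) == 0) stop("all-zero contingency table")
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  degenerate <- m == 0 || n2 == 0 || k == 0 || (b + d) == 0
  p <- .fisher_p(a, m, n2, k)
  or <- if (a * d == 0 && b * c == 0) NaN
        else if (b * c == 0) Inf
        else (a * d) / (b * c)
  new("EnrichmentTest",
      table = matrix(as.numeric(counts), 2, 2, byrow = TRUE,
                     dimnames = list(c("row1", "row2"), c("col1", "col2"))),
      odds_ratio = or, p_value = p, degenerate = degenerate)
}

#' Shared enrichment vs direct alignability
#'
#' Tests (Fisher's exact) whether mutually enriched bins are associated
#' with direct alignability, over a bin comparison table carrying an
#' `alignable` flag. Bins with category `unprojectable` are excluded
#' (sharing cannot be assessed there).
#'
#' @param bin_comparisons the `bins` table from [compareRegions()] run with
#'   a `direct_anchor_set`, or any data.frame with columns `category` and
#'   `alignable`.
#' @return An [EnrichmentTest-class]; rows alignable / non-alignable,
#'   columns shared / not shared. A zero margin sets the `degenerate` flag.
#' @export
sharedEnrichmentByAlignability <- function(bin_comparisons) {
  stopifnot(all(c("category", "alignable") %in% names(bin_comparisons)))
  x <- bin_comparisons[bin_comparisons$category != "unprojectable", ,
                       drop = FALSE]
  if (nrow(x) == 0L) stop("no projectable bins to test")
  shared <- x$category == "mutually-enriched"
  fisherExact2x2(sum(x$alignable & shared), sum(x$alignable & !shared),
                 sum(!x$alignable & shared), sum(!x$alignable & !shared))
}

#' Target-signal enrichment inside projected source intervals
#'
#' Projects the endpoints of each source interval (e.g. an H3K27ac
#' ensemble) to the target species, tiles the target genome into
#' `bin_size` windows, flags windows whose quantile signal reaches
#' `enrich_q`, and Fisher-tests enrichment inside vs outside the projected
#' intervals.
#'
#' @param ensembles source intervals (`GRanges` or data.frame).
#' @param signal_target [SignalTrack-class] on the target assembly.
#' @param graph a [SpeciesGraph-class].
#' @param source_species,target_species node identifiers.
#' @param params a [ScoringParams-class].
#' @param enrich_q enrichment quantile threshold (default 0.8).
#' @param bin_size target window width in bp (default 1000).
#' @return An [EnrichmentTest-class]; rows inside / outside, columns
#'   enriched / not. Errors when no interval has both endpoints
#'   projectable onto a common target chromosome.
#' @export
ensembleEnrichment <- function(ensembles, signal_target, graph,
                               source_species, target_species,
                               params = ScoringParams(), enrich_q = 0.8,
                               bin_size = 1000) {
  df <- .intervals_df(ensembles)
  proj_iv <- list()
  for (i in seq_len(nrow(df))) {
    r1 <- shortestPathProject(graph, source_species, target_species,
                              df$chrom[i], df$start[i], params)
    r2 <- shortestPathProject(graph, source_species, target_species,
                              df$chrom[i], df$end[i], params)
    if (length(r1@path) && length(r2@path) &&
        identical(r1@target_chrom, r2@target_chrom)) {
      proj_iv[[length(proj_iv) + 1L]] <- data.frame(
        chrom = r1@target_chrom,
        start = min(r1@target_pos, r2@target_pos),
        end = max(r1@target_pos, r2@target_pos))
    }
  }
  if (length(proj_iv) == 0L) stop("no projectable ensemble interval")
  proj_iv <- do.call(rbind, proj_iv)
  len <- chromLengths(signal_target@assembly)
  grid <- binRegions(data.frame(chrom = names(len), start = 0, end = len,
                                name = names(len)), bin_size)
  q <- binQuantiles(signal_target, grid)
  enriched <- q >= enrich_q
  inside <- logical(nrow(grid))
  for (j in seq_len(nrow(proj_iv))) {
    inside <- inside | (grid$chrom == proj_iv$chrom[j] &
                        grid$center >= proj_iv$start[j] &
                        grid$center < proj_iv$end[j])
  }
  fisherExact2x2(sum(inside & enriched), sum(inside & !enriched),
                 sum(!inside & enriched), sum(!inside & !enriched))
}
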