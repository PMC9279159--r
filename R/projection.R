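#' Per-species scaling factor of the anchor-distance score
#'
#' `s = -d_h / (g * log 0.5)`, where `d_h` is the distance half-life and `g`
#' the genome size. The product `g * s = d_h / log 2` does not depend on
#' `g`, which is why the score itself is genome-size independent.
#'
#' @param half_life distance half-life `d_h` in bp (> 0).
#' @param genome_size genome size `g` in bp (> 0).
#' @return The scaling factor `s`.
#' @examples
#' scalingFactor(10000, 10000)  # 1/log(2)
#' @export
scalingFactor <- function(half_life, genome_size) {
  if (half_life <= 0) stop("'half_life' must be > 0")
  if (genome_size <= 0) stop("'genome_size' must be > 0")
  -half_life / (genome_size * log(0.5))
}

#' Anchor-distance score
#'
#' `f(d) = exp(-d / (g s)) = 2^(-d / d_h)`: 1 when the query overlaps an
#' anchor (`d = 0`), 0.5 at the distance half-life, decreasing
#' exponentially with distance. The genome size cancels through the scaling
#' factor, so it is not needed to evaluate the score.
#'
#' @param distance distance (bp) from the query to its nearest flanking
#'   anchor; vectorized, all values must be `>= 0`.
#' @param params a [ScoringParams-class].
#' @return Scores in `(0, 1]`.
#' @examples
#' scoreDistance(c(0, 10000, 20000), ScoringParams(10000))  # 1, 0.5, 0.25
#' @export
scoreDistance <- function(distance, params = ScoringParams()) {
  if (any(distance < 0)) stop("'distance' must be >= 0")
  2^(-distance / halfLife(params))
}

#' Score of a multi-species projection path
#'
#' The path score is the product of the per-step anchor-distance scores,
#' `prod(2^(-d_i / d_h)) = 2^(-sum(d_i) / d_h)`; the path length minimized
#' by the shortest-path search is `l_p = 1 - score`.
#'
#' @param step_distances numeric vector of per-step anchor distances (bp).
#' @param params a [ScoringParams-class].
#' @return List with elements `score` and `path_length`.
#' @examples
#' pathScore(c(100, 45), ScoringParams(10000))$score  # 2^(-145/10000)
#' @export
pathScore <- function(step_distances, params = ScoringParams()) {
  if (length(step_distances) == 0L) stop("empty path")
  if (any(step_distances < 0)) stop("step distances must be >= 0")
  score <- 2^(-sum(step_distances) / halfLife(params))
  list(score = score, path_length = 1 - score)
}

# Per-chromosome block table, or NULL when the chromosome has no anchors.
.chrom_blocks <- function(anchor_set, chrom) {
  b <- anchor_set@blocks
  b <- b[b$chrom_a == chrom, , drop = FALSE]
  if (nrow(b) == 0L) NULL else b
}

#' Flanking anchors of a position
#'
#' Finds the anchor block containing `pos`, or the nearest blocks ending
#' at/before and starting after it on the source side.
#'
#' @param anchor_set an [AnchorSet-class].
#' @param chrom source chromosome.
#' @param pos 0-based source position.
#' @return A list with `mode` (`"inside-block"`, `"between"`, or
#'   `"one-sided"`) and the flanking block row indices `upstream` /
#'   `downstream` (`NA` where absent) into `anchorBlocks(anchor_set)`
#'   restricted to `chrom`; `NULL` when the chromosome has no anchors.
#' @export
flankingAnchors <- function(anchor_set, chrom, pos) {
  b <- .chrom_blocks(anchor_set, chrom)
  if (is.null(b)) return(NULL)
  i <- findInterval(pos, b$start_a)
  if (i >= 1L && pos < b$end_a[i])
    return(list(mode = "inside-block", upstream = i, downstream = i,
                blocks = b))
  up <- if (i >= 1L) i else NA_integer_
  down <- if (i + 1L <= nrow(b)) i + 1L else NA_integer_
  mode <- if (is.na(up) || is.na(down)) "one-sided" else "between"
  list(mode = mode, upstream = up, downstream = down, blocks = b)
}

# Proportional in-block mapping of a point coordinate. '-' blocks map the
# source left edge onto the target right edge.
.map_in_block <- function(b, i, pos) {
  frac <- (pos - b$start_a[i]) / (b$end_a[i] - b$start_a[i])
  span <- b$end_b[i] - b$start_b[i]
  if (b$strand[i] == "+") b$start_b[i] + round(frac * span)
  else                    b$end_b[i]   - round(frac * span)
}

#' Project one point through one pairwise anchor set
#'
#' Inside a block the position maps proportionally within the block
#' (anchor distance 0). Between two blocks the relative position in the
#' source gap is transferred to the target gap, provided both flanking
#' blocks lie on the same target chromosome and strand and are collinear on
#' the target side; the anchor distance is the smaller of the distances to
#' the two inner block edges. One-sided or inconsistent flanks make the
#' position unprojectable through this pair.
#'
#' @param anchor_set an [AnchorSet-class].
#' @param chrom source chromosome.
#' @param pos 0-based source position.
#' @param params a [ScoringParams-class] (used only for the reported score).
#' @return A list with `chrom`, `pos` (target, 0-based), `distance` (bp),
#'   `mode`, and `score`; or `NULL` when unprojectable.
#' @export
projectPointPairwise <- function(anchor_set, chrom, pos,
                                 params = ScoringParams()) {
  fl <- flankingAnchors(anchor_set, chrom, pos)
  if (is.null(fl) || fl$mode == "one-sided") return(NULL)
  b <- fl$blocks
  if (fl$mode == "inside-block") {
    tpos <- .map_in_block(b, fl$upstream, pos)
    return(list(chrom = b$chrom_b[fl$upstream], pos = tpos, distance = 0,
                mode = "inside-block", score = scoreDistance(0, params)))
  }
  u <- fl$upstream; d <- fl$downstream
  if (b$chrom_b[u] != b$chrom_b[d] || b$strand[u] != b$strand[d])
    return(NULL)
  src_gap <- b$start_a[d] - b$end_a[u]
  frac <- (pos - b$end_a[u]) / src_gap
  if (b$strand[u] == "+") {
    if (b$end_b[u] > b$start_b[d]) return(NULL)   # target side not collinear
    tpos <- b$end_b[u] + round(frac * (b$start_b[d] - b$end_b[u]))
  } else {
    if (b$end_b[d] > b$start_b[u]) return(NULL)
    tpos <- b$start_b[u] - round(frac * (b$start_b[u] - b$end_b[d]))
  }
  dist <- min(pos - b$end_a[u], b$start_a[d] - pos)
  list(chrom = b$chrom_b[u], pos = tpos, distance = dist,
       mode = "interpolated", score = scoreDistance(dist, params))
}

.unprojectable <- function(chrom, pos) {
  new("ProjectionResult", query_chrom = chrom, query_pos = pos,
      target_chrom = NA_character_, target_pos = NA_real_, score = 0,
      path = character(), step_distances = numeric())
}

.result <- function(chrom, pos, tchrom, tpos, path, dists, params) {
  new("ProjectionResult", query_chrom = chrom, query_pos = pos,
      target_chrom = tchrom, target_pos = tpos,
      score = pathScore2(dists, params), path = path,
      step_distances = dists)
}

# pathScore for possibly-empty distance vectors (source == target).
pathScore2 <- function(dists, params) {
  if (length(dists) == 0L) 1 else pathScore(dists, params)$score
}

# Deterministic label comparison: smaller total distance wins; ties go to
# fewer hops, then lexicographically smaller species path.
.label_better <- function(dist_new, path_new, dist_old, path_old,
                          eps = 1e-9) {
  if (is.null(path_old) || dist_new < dist_old - eps) return(TRUE)
  if (dist_new > dist_old + eps) return(FALSE)
  if (length(path_new) != length(path_old))
    return(length(path_new) < length(path_old))
  paste(path_new, collapse = ",") < paste(path_old, collapse = ",")
}

#' Shortest-path projection through bridging species
#'
#' Runs Dijkstra's algorithm on the species graph: the cost of traversing
#' an edge is the anchor distance (bp) of projecting the coordinate
#' currently reached in the edge's source species, so minimizing total
#' distance minimizes the path length `l_p = 1 - prod(f(d_i))`. The
#' coordinate is propagated along relaxed edges; each species keeps a
#' single best label (a greedy strategy, since the coordinate reached can
#' depend on the route — see [enumeratePathsProject()] for the exhaustive
#' oracle). Ties are broken by
#' fewer path nodes, then lexicographic species order.
#'
#' @param graph a [SpeciesGraph-class].
#' @param source_species,target_species node identifiers.
#' @param chrom,pos query coordinate in the source species (0-based).
#' @param params a [ScoringParams-class].
#' @return A [ProjectionResult-class]; unprojectable queries yield score 0
#'   and an empty path.
#' @export
shortestPathProject <- function(graph, source_species, target_species,
                                chrom, pos, params = ScoringParams()) {
  stopifnot(source_species %in% graph@species,
            target_species %in% graph@species)
  if (source_species == target_species)
    return(.result(chrom, pos, chrom, pos, source_species, numeric(), params))
  nodes <- graph@species
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  coord <- stats::setNames(vector("list", length(nodes)), nodes)
  paths <- stats::setNames(vector("list", length(nodes)), nodes)
  steps <- stats::setNames(vector("list", length(nodes)), nodes)
  visited <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  dist[source_species] <- 0
  coord[[source_species]] <- list(chrom = chrom, pos = pos)
  paths[[source_species]] <- source_species
  steps[[source_species]] <- numeric()
  repeat {
    # pick the unvisited node with the best label
    u <- NA_character_
    for (v in nodes) {
      if (visited[v] || is.infinite(dist[v])) next
      if (is.na(u) ||
          .label_better(dist[v], paths[[v]], dist[u], paths[[u]]))
        u <- v
    }
    if (is.na(u) || u == target_species) break
    visited[u] <- TRUE
    for (key in names(graph@edges)) {
      as_ <- graph@edges[[key]]
      if (as_@source_species != u) next
      v <- as_@target_species
      if (visited[v]) next
      pr <- projectPointPairwise(as_, coord[[u]]$chrom, coord[[u]]$pos,
                                 params)
      if (is.null(pr)) next
      nd <- dist[u] + pr$distance
      npath <- c(paths[[u]], v)
      if (.label_better(nd, npath, dist[v], paths[[v]])) {
        dist[v] <- nd
        coord[[v]] <- list(chrom = pr$chrom, pos = pr$pos)
        paths[[v]] <- npath
        steps[[v]] <- c(steps[[u]], pr$distance)
      }
    }
  }
  if (is.infinite(dist[target_species]))
    return(.unprojectable(chrom, pos))
  .result(chrom, pos, coord[[target_species]]$chrom,
          coord[[target_species]]$pos, paths[[target_species]],
          steps[[target_species]], params)
}

#' Exhaustive path enumeration (oracle for the shortest-path search)
#'
#' Projects the query along every simple path from source to target and
#' returns the best-scoring result, with the same tie-breaking as
#' [shortestPathProject()]. Intended for testing on small graphs.
#'
#' @inheritParams shortestPathProject
#' @param max_nodes refuse graphs with more nodes than this (default 8).
#' @return A [ProjectionResult-class].
#' @export
enumeratePathsProject <- function(graph, source_species, target_species,
                                  chrom, pos, params = ScoringParams(),
                                  max_nodes = 8L) {
  stopifnot(source_species %in% graph@species,
            target_species %in% graph@species)
  if (length(graph@species) > max_nodes)
    stop("graph too large for exhaustive enumeration")
  if (source_species == target_species)
    return(.result(chrom, pos, chrom, pos, source_species, numeric(), params))
  edges_from <- split(names(graph@edges),
                      sub("\\|.*$", "", names(graph@edges)))
  best <- NULL
  recurse <- function(u, cchrom, cpos, path, dists) {
    for (key in edges_from[[u]]) {
      as_ <- graph@edges[[key]]
      v <- as_@target_species
      if (v %in% path) next
      pr <- projectPointPairwise(as_, cchrom, cpos, params)
      if (is.null(pr)) next
      npath <- c(path, v)
      ndists <- c(dists, pr$distance)
      if (v == target_species) {
        if (is.null(best) ||
            .label_better(sum(ndists), npath, sum(best$dists), best$path)) {
          best <<- list(chrom = pr$chrom, pos = pr$pos, path = npath,
                        dists = ndists)
        }
      } else {
        recurse(v, pr$chrom, pr$pos, npath, ndists)
      }
    }
  }
  recurse(source_species, chrom, pos, source_species, numeric())
  if (is.null(best)) return(.unprojectable(chrom, pos))
  .result(chrom, pos, best$chrom, best$pos, best$path, best$dists, params)
}

#' Project many points and return a table
#'
#' Vectorized front-end over [shortestPathProject()].
#'
#' @param graph a [SpeciesGraph-class].
#' @param source_species,target_species node identifiers.
#' @param chrom character vector of source chromosomes.
#' @param pos numeric vector of 0-based source positions.
#' @param params a [ScoringParams-class].
#' @return A data.frame with columns `chrom, pos, target_chrom, target_pos,
#'   score, path, step_distances` (the last two comma-joined strings).
#' @export
projectPoints <- function(graph, source_species, target_species,
                          chrom, pos, params = ScoringParams()) {
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  out <- data.frame(chrom = chrom, pos = pos,
                    target_chrom = NA_character_, target_pos = NA_real_,
                    score = 0, path = "", step_distances = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    r <- shortestPathProject(graph, source_species, target_species,
                             chrom[i], pos[i], params)
    out$target_chrom[i] <- r@target_chrom
    out$target_pos[i] <- r@target_pos
    out$score[i] <- r@score
    out$path[i] <- paste(r@path, collapse = ",")
    out$step_distances[i] <- paste(r@step_distances, collapse = ",")
  }
  out
}
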