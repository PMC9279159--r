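test_that("scoring function satisfies its defining identities", {
  p <- ScoringParams(10000)
  expect_identical(scoreDistance(0, p), 1)
  expect_identical(scoreDistance(10000, p), 0.5)
  expect_equal(scoreDistance(20000, p), 0.25)
  expect_equal(scoreDistance(10000, p)^2, scoreDistance(20000, p))
  expect_error(scoreDistance(-1, p), ">= 0")
  expect_error(ScoringParams(0))

  expect_equal(scalingFactor(10000, 10000), 1 / log(2))
  expect_error(scalingFactor(0, 1e9), "> 0")
})

test_that("the score is invariant to genome size (g cancels through s)", {
  set.seed(11)
  p <- ScoringParams(10000)
  for (i in 1:50) {
    d <- runif(1, 0, 5e4)
    g <- 10^runif(1, 4, 10)
    raw <- exp(-d / (g * scalingFactor(halfLife(p), g)))
    expect_equal(scoreDistance(d, p), raw, tolerance = 1e-12)
  }
})

test_that("score decreases strictly with distance", {
  p <- ScoringParams(5000)
  d <- sort(runif(100, 0, 1e5))
  s <- scoreDistance(d, p)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= 1))
})

test_that("path score composes multiplicatively", {
  p <- ScoringParams(10000)
  expect_identical(pathScore(c(0, 0, 0), p)$score, 1)
  expect_identical(pathScore(c(4000, 6000), p)$score, 0.5)
  expect_gt(pathScore(144, p)$score, 0.99)
  expect_lt(pathScore(150, p)$score, 0.99)
  expect_error(pathScore(numeric(), p), "empty")
  set.seed(3)
  for (i in 1:25) {
    d <- runif(sample(1:5, 1), 0, 2e4)
    ps <- pathScore(d, p)
    expect_equal(ps$score, prod(scoreDistance(d, p)), tolerance = 1e-12)
    expect_equal(ps$path_length, 1 - ps$score)
  }
})

test_that("pairwise interpolation matches hand-computed coordinates", {
  as1 <- toy_anchor_set()
  p <- ScoringParams(10000)
  r <- projectPointPairwise(as1, "chr1", 1500, p)
  expect_equal(r$pos, 2100 + round(400 / 900 * 1900))  # 2944
  expect_equal(r$pos, 2944)
  expect_equal(r$distance, 400)
  expect_equal(r$mode, "interpolated")

  r2 <- projectPointPairwise(as1, "chr1", 1050, p)
  expect_equal(r2$pos, 2050)
  expect_equal(r2$distance, 0)
  expect_equal(r2$mode, "inside-block")

  r3 <- projectPointPairwise(as1, "chr1", 1100, p)  # upstream inner edge
  expect_equal(r3$pos, 2100)
  expect_equal(r3$distance, 0)

  expect_null(projectPointPairwise(as1, "chr1", 50, p))    # one-sided
  expect_null(projectPointPairwise(as1, "chr1", 5000, p))  # one-sided
})

test_that("discordant flanking anchors are unprojectable", {
  ga <- toy_assembly("A"); gb <- toy_assembly("B", c(5000, 5000),
                                              c("chrX", "chrY"))
  mixed_chrom <- AnchorSet(data.frame(
    chrom_a = "chr1", start_a = c(1000, 2000), end_a = c(1100, 2100),
    chrom_b = c("chrX", "chrY"), start_b = c(2000, 2000),
    end_b = c(2100, 2100), strand = "+"), ga, gb)
  expect_null(projectPointPairwise(mixed_chrom, "chr1", 1500))
  mixed_strand <- AnchorSet(data.frame(
    chrom_a = "chr1", start_a = c(1000, 2000), end_a = c(1100, 2100),
    chrom_b = "chrX", start_b = c(2000, 4000), end_b = c(2100, 4100),
    strand = c("+", "-")), ga, gb)
  expect_null(projectPointPairwise(mixed_strand, "chr1", 1500))
})

test_that("minus-strand flanking pairs interpolate with reversed orientation", {
  ga <- toy_assembly("A"); gb <- toy_assembly("B")
  rev_set <- AnchorSet(data.frame(
    chrom_a = "chr1", start_a = c(1000, 2000), end_a = c(1100, 2100),
    chrom_b = "chr1", start_b = c(4000, 2000), end_b = c(4100, 2100),
    strand = "-"), ga, gb)
  # upstream source block maps to the right-hand target block
  r <- projectPointPairwise(rev_set, "chr1", 1100)
  expect_equal(r$pos, 4000)     # source inner edge -> target inner edge
  r2 <- projectPointPairwise(rev_set, "chr1", 1550)
  expect_equal(r2$pos, 4000 - round(450 / 900 * (4000 - 2100)))
  # inside a '-' block the left source edge maps to the right target edge
  r3 <- projectPointPairwise(rev_set, "chr1", 1000)
  expect_equal(r3$pos, 4100)
})

test_that("anchor inner edges project exactly onto their counterparts", {
  sim <- simulateSynteny(syntenyConfig(), 5)
  as1 <- sim$anchor_sets[["fishlike|mouselike"]]
  b <- anchorBlocks(as1)
  # "inner" edges are the gap-facing edges of a flanking pair, so the last
  # block's right edge (one-sided) is excluded
  for (i in seq_len(min(nrow(b) - 1L, 20))) {
    r <- projectPointPairwise(as1, b$chrom_a[i], b$start_a[i])
    expect_equal(r$pos, b$start_b[i])
    expect_equal(r$distance, 0)
    r2 <- projectPointPairwise(as1, b$chrom_a[i], b$end_a[i])
    expect_equal(r2$pos, b$end_b[i])
    expect_equal(r2$distance, 0)
  }
})

test_that("A->B->A round trip returns the original coordinate within 1 bp", {
  sim <- simulateSynteny(syntenyConfig(), 9)
  fwd <- sim$anchor_sets[["fishlike|bridge"]]
  rev <- sim$anchor_sets[["bridge|fishlike"]]
  set.seed(9)
  pos <- sort(round(runif(50, 5000, 195000)))
  for (x in pos) {
    r <- projectPointPairwise(fwd, "chr1", x)
    if (is.null(r)) next
    back <- projectPointPairwise(rev, r$chrom, r$pos)
    expect_lte(abs(back$pos - x), 1)
  }
  # exact at anchor edges
  b <- anchorBlocks(fwd)[1:5, ]
  for (i in 1:5) {
    r <- projectPointPairwise(fwd, "chr1", b$start_a[i])
    back <- projectPointPairwise(rev, r$chrom, r$pos)
    expect_identical(back$pos, b$start_a[i])
  }
})

test_that("a 2-node graph reduces to the pairwise projection", {
  as1 <- toy_anchor_set()
  g <- SpeciesGraph(as1)
  p <- ScoringParams(10000)
  r <- shortestPathProject(g, "A", "B", "chr1", 1500, p)
  pw <- projectPointPairwise(as1, "chr1", 1500, p)
  expect_equal(r@target_pos, pw$pos)
  expect_equal(projectionScore(r), pw$score)
  expect_equal(speciesPath(r), c("A", "B"))
  expect_equal(stepDistances(r), pw$distance)
  expect_equal(pathLength(r), 1 - pw$score)
})

test_that("a dense bridge beats the sparse direct pair", {
  fx <- conservation_fixture()
  p <- ScoringParams(10000)
  pos <- 101100  # between direct anchors, on no anchor
  full <- shortestPathProject(fx$graph, "A", "C", "chr1", pos, p)
  direct_only <- SpeciesGraph(fx$direct)
  direct <- shortestPathProject(direct_only, "A", "C", "chr1", pos, p)
  expect_length(speciesPath(full), 3L)  # routed through the bridge
  expect_gt(projectionScore(full), projectionScore(direct))
  # same best path found by exhaustive enumeration
  oracle <- enumeratePathsProject(fx$graph, "A", "C", "chr1", pos, p)
  expect_equal(speciesPath(oracle), speciesPath(full))
  expect_equal(projectionScore(oracle), projectionScore(full))
})

test_that("anchored queries score 1 down a multi-species chain", {
  sp <- lapply(c("A", "B", "C", "D"), toy_assembly)
  names(sp) <- c("A", "B", "C", "D")
  blocks <- data.frame(chrom_a = "chr1", start_a = c(1000, 5000),
                       end_a = c(1200, 5200), chrom_b = "chr1",
                       start_b = c(1000, 5000), end_b = c(1200, 5200),
                       strand = "+")
  edges <- list(AnchorSet(blocks, sp$A, sp$B),
                AnchorSet(blocks, sp$B, sp$C),
                AnchorSet(blocks, sp$C, sp$D))
  g <- SpeciesGraph(edges)
  r <- shortestPathProject(g, "A", "D", "chr1", 1100)
  expect_identical(projectionScore(r), 1)
  expect_equal(speciesPath(r), c("A", "B", "C", "D"))
  expect_equal(r@target_pos, 1100)
})

test_that("equal-score paths break ties toward fewer nodes", {
  sp <- lapply(c("A", "B", "C"), toy_assembly)
  names(sp) <- c("A", "B", "C")
  blocks <- data.frame(chrom_a = "chr1", start_a = c(1000, 5000),
                       end_a = c(1200, 5200), chrom_b = "chr1",
                       start_b = c(1000, 5000), end_b = c(1200, 5200),
                       strand = "+")
  g <- SpeciesGraph(AnchorSet(blocks, sp$A, sp$C),
                    AnchorSet(blocks, sp$A, sp$B),
                    AnchorSet(blocks, sp$B, sp$C))
  r <- shortestPathProject(g, "A", "C", "chr1", 1100)  # on an anchor
  expect_identical(projectionScore(r), 1)
  expect_equal(speciesPath(r), c("A", "C"))
  o <- enumeratePathsProject(g, "A", "C", "chr1", 1100)
  expect_equal(speciesPath(o), c("A", "C"))
})

test_that("unprojectable queries yield score 0 and an empty path", {
  ga <- toy_assembly("A"); gb <- toy_assembly("B"); gz <- toy_assembly("Z")
  g <- SpeciesGraph(toy_anchor_set(ga, gb),
                    AnchorSet(data.frame(chrom_a = "chr1", start_a = 1,
                                         end_a = 2, chrom_b = "chr1",
                                         start_b = 1, end_b = 2,
                                         strand = "+")[0, ], gb, gz))
  r <- shortestPathProject(g, "A", "Z", "chr1", 1500)
  expect_identical(projectionScore(r), 0)
  expect_length(speciesPath(r), 0L)
  o <- enumeratePathsProject(g, "A", "Z", "chr1", 1500)
  expect_identical(projectionScore(o), 0)
})

test_that("Dijkstra agrees with exhaustive enumeration on random graphs", {
  p <- ScoringParams(10000)
  for (seed in 1:25) {
    fx <- random_graph_sim(seed)
    set.seed(seed + 1000)
    pos <- round(runif(2, 1000,
                       genomeSize(fx$sim$assemblies[[fx$source]]) - 2000))
    for (x in pos) {
      a <- shortestPathProject(fx$sim$graph, fx$source, fx$target,
                               "chr1", x, p)
      b <- enumeratePathsProject(fx$sim$graph, fx$source, fx$target,
                                 "chr1", x, p)
      expect_equal(projectionScore(a), projectionScore(b), tolerance = 1e-12)
      expect_equal(speciesPath(a), speciesPath(b))
    }
  }
})

test_that("adding a bridging species never lowers the score", {
  p <- ScoringParams(10000)
  for (seed in 26:35) {
    fx <- random_graph_sim(seed)
    g <- fx$sim$graph
    direct_key <- paste(fx$source, fx$target, sep = "|")
    if (!direct_key %in% names(g@edges)) next
    direct_only <- SpeciesGraph(g@edges[[direct_key]])
    set.seed(seed)
    x <- round(runif(1, 1000, genomeSize(fx$sim$assemblies[[fx$source]]) -
                     2000))
    full <- shortestPathProject(g, fx$source, fx$target, "chr1", x, p)
    direct <- shortestPathProject(direct_only, fx$source, fx$target,
                                  "chr1", x, p)
    expect_gte(projectionScore(full), projectionScore(direct))
  }
})

test_that("projectPoints tabulates many queries", {
  g <- SpeciesGraph(toy_anchor_set())
  tab <- projectPoints(g, "A", "B", "chr1", c(1050, 1500, 50))
  expect_equal(tab$target_pos, c(2050, 2944, NA))
  expect_equal(tab$score[3], 0)
  expect_equal(tab$path[1], "A,B")
})
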