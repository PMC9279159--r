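# Shared fixtures built in code.

toy_assembly <- function(name, len = 10000, chrom = "chr1") {
  GenomeAssembly(name, stats::setNames(len, chrom))
}

# The canonical two-block pairwise fixture:
# A:[1000,1100) -> B:[2000,2100) and A:[2000,2100) -> B:[4000,4100), both '+'.
toy_anchor_set <- function(ga = toy_assembly("A"), gb = toy_assembly("B")) {
  AnchorSet(data.frame(chrom_a = "chr1", start_a = c(1000, 2000),
                       end_a = c(1100, 2100),
                       chrom_b = "chr1", start_b = c(2000, 4000),
                       end_b = c(2100, 4100), strand = "+"),
            ga, gb)
}

# A seeded random multi-species simulation with a connected random pair set,
# suitable for Dijkstra-vs-enumeration comparisons.
random_graph_sim <- function(seed) {
  set.seed(seed)
  n_sp <- sample(3:6, 1)
  sp <- paste0("sp", letters[seq_len(n_sp)])
  scales <- stats::setNames(sample(c(0.5, 1, 1.5, 2, 2.5), n_sp,
                                   replace = TRUE), sp)
  # a random spanning path plus extra random pairs
  ord <- sample(sp)
  pairs <- data.frame(source = ord[-n_sp], target = ord[-1])
  extra <- t(utils::combn(sp, 2))
  extra <- extra[sample(nrow(extra), sample(0:2, 1)), , drop = FALSE]
  pairs <- unique(rbind(pairs,
                        data.frame(source = extra[, 1], target = extra[, 2])))
  pairs$density <- stats::runif(nrow(pairs), 0.05, 0.4)
  pairs$dropout <- stats::runif(nrow(pairs), 0, 0.3)
  cfg <- syntenyConfig(species = scales, master_length = 200000,
                       pairs = pairs)
  sim <- simulateSynteny(cfg, seed)
  list(sim = sim, source = ord[1], target = ord[n_sp])
}

# Independent two-sided Fisher oracle: explicit enumeration of all tables
# with the observed margins, probabilities from choose() only.
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  ks <- lo:hi
  probs <- choose(m, ks) * choose(n2, k - ks) / choose(m + n2, k)
  p_obs <- probs[ks == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Deterministic signal track: given domain intervals (0-based, species
# coordinates) with high value, background elsewhere, in fixed steps.
flat_track <- function(assembly, domains = NULL, background = 1,
                       high = 10, step = 100, chrom = "chr1") {
  len <- chromLengths(assembly)[[chrom]]
  n <- len %/% step
  starts <- step * (seq_len(n) - 1)
  vals <- rep(background, n)
  if (!is.null(domains)) {
    for (i in seq_len(nrow(domains))) {
      hit <- starts >= domains$start[i] & starts + step <= domains$end[i]
      vals[hit] <- high
    }
  }
  SignalTrack(data.frame(chrom = chrom, start = starts, end = starts + step,
                         value = vals), assembly)
}

# Conservation fixture with known geometry: sparse direct anchors, a dense
# bridge, and peaks planted on direct anchors (DC), on/near bridge anchors
# (IC) and far from all anchors (NC).
conservation_fixture <- function() {
  ga <- toy_assembly("A", 400000)
  gb <- toy_assembly("bridge", 400000)
  gc <- toy_assembly("C", 400000)
  direct_pos <- c(10000, 210000, 390000)     # sparse direct anchors
  direct <- data.frame(chrom_a = "chr1", start_a = direct_pos,
                       end_a = direct_pos + 500, chrom_b = "chr1",
                       start_b = direct_pos, end_b = direct_pos + 500,
                       strand = "+")
  bridge_pos <- seq(0, 398000, by = 2000)    # dense bridge anchors
  bridge <- data.frame(chrom_a = "chr1", start_a = bridge_pos,
                       end_a = bridge_pos + 200, chrom_b = "chr1",
                       start_b = bridge_pos, end_b = bridge_pos + 200,
                       strand = "+")
  direct_ab <- AnchorSet(direct, ga, gc)
  ab <- AnchorSet(bridge, ga, gb)
  bc <- AnchorSet(bridge, gb, gc)
  graph <- SpeciesGraph(direct_ab, ab, bc)
  # 3 peaks on direct anchors, 4 on bridge anchors (not direct), 3 far
  dc_peaks <- data.frame(chrom = "chr1", start = direct_pos + 100,
                         end = direct_pos + 300)
  ic_pos <- c(50000, 100000, 150000, 300000)
  ic_peaks <- data.frame(chrom = "chr1", start = ic_pos + 20,
                         end = ic_pos + 120)  # midpoints inside bridge blocks
  nc_pos <- c(74000, 124000, 334000)
  nc_peaks <- data.frame(chrom = "chr1", start = nc_pos + 1050,
                         end = nc_pos + 1150) # midpoints 900 bp from anchors
  peaks <- rbind(dc_peaks, ic_peaks, nc_peaks)
  peaks$name <- c(paste0("dc", 1:3), paste0("ic", 1:4), paste0("nc", 1:3))
  list(peaks = peaks, direct = direct_ab, graph = graph,
       target = "C", truth = peaks$name)
}
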