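#' Configuration for the synthetic synteny simulator
#'
#' The simulator lays out every species along a common "master" coordinate
#' axis: species coordinates are the master coordinate times a per-species
#' genome-size scale factor (rounded to integers), so all genomes are
#' perfectly collinear and the true cross-species mapping is known. Anchor
#' blocks are placed along the master axis independently for each species
#' pair, at a configurable density with positional jitter, and dropped out
#' at a configurable rate. This mirrors a projection setup between a
#' compact fish-like genome and a roughly two-fold larger mammalian genome
#' joined by a bridging species whose pairwise alignments are denser than
#' the direct one.
#'
#' @param species named numeric vector of genome-size scale factors; names
#'   are species identifiers. Default: a 1x source, a 1.2x bridge and a 2x
#'   target (regulatory domains in fish vs mouse differ about two-fold in
#'   size).
#' @param master_length master axis length in bp (default 200000).
#' @param pairs data.frame with columns `source, target, density, dropout`:
#'   anchors per kb of master axis and per-anchor dropout probability for
#'   each (unordered) species pair; both edge directions are emitted.
#'   Default: sparse direct source-target anchors (1 per 50 kb) and dense
#'   anchors through the bridge (1 per 2 kb), dropout 0.
#' @param anchor_width 2-vector, min/max anchor block width in master bp
#'   (default `c(50, 200)`).
#' @param inversion_prob per-anchor probability of flagging the block as
#'   inverted (strand `-`); default 0. Inverted anchors exist to exercise
#'   the unprojectable (discordant-flank) pathway.
#' @return A `syntenyConfig` list.
#' @export
syntenyConfig <- function(species = c(fishlike = 1, bridge = 1.2,
                                      mouselike = 2),
                          master_length = 200000,
                          pairs = NULL,
                          anchor_width = c(50, 200),
                          inversion_prob = 0) {
  if (is.null(names(species)) || any(!nzchar(names(species))))
    stop("'species' must be a named vector of scale factors")
  if (any(species <= 0)) stop("scale factors must be > 0")
  if (is.null(pairs)) {
    sp <- names(species)
    if (length(sp) < 2L) stop("need at least two species")
    pairs <- data.frame(source = sp[1], target = sp[length(sp)],
                        density = 0.02, dropout = 0)
    if (length(sp) > 2L) {
      mids <- sp[-c(1L, length(sp))]
      chain <- data.frame(source = c(sp[1], mids),
                          target = c(mids, sp[length(sp)]),
                          density = 0.5, dropout = 0)
      pairs <- rbind(pairs, chain)
    }
  }
  stopifnot(all(c("source", "target", "density", "dropout") %in% names(pairs)),
            all(pairs$density > 0), all(pairs$dropout >= 0),
            all(pairs$dropout < 1),
            all(c(pairs$source, pairs$target) %in% names(species)))
  structure(list(species = species, master_length = master_length,
                 pairs = pairs, anchor_width = anchor_width,
                 inversion_prob = inversion_prob),
            class = "syntenyConfig")
}

.sim_assembly <- function(name, scale, master_length) {
  GenomeAssembly(name, c(chr1 = ceiling(master_length * scale) + 1000))
}

#' Simulate a multi-species synteny fixture
#'
#' Places anchors at jittered master-axis positions for every configured
#' species pair, realizes them in each species through its scale factor,
#' applies per-pair dropout, and returns assemblies, reciprocal anchor sets
#' and the exact truth map. Fully reproducible for a fixed seed.
#'
#' @param config a [syntenyConfig()].
#' @param seed integer random seed.
#' @return List with `assemblies` (named list of [GenomeAssembly-class]),
#'   `anchor_sets` (named list keyed `"A|B"`, both directions per pair),
#'   `graph` (a ready [SpeciesGraph-class]), `truth` (the scale map used by
#'   [truthProjection()]) and `config`.
#' @export
simulateSynteny <- function(config, seed = 1L) {
  stopifnot(inherits(config, "syntenyConfig"))
  set.seed(seed)
  scales <- config$species
  L <- config$master_length
  assemblies <- lapply(names(scales), function(sp)
    .sim_assembly(sp, scales[[sp]], L))
  names(assemblies) <- names(scales)
  anchor_sets <- list()
  for (j in seq_len(nrow(config$pairs))) {
    p <- config$pairs[j, ]
    n <- floor(L * p$density / 1000)
    if (n < 2L) stop(sprintf("pair %s-%s: density too low (<2 anchors)",
                             p$source, p$target))
    spacing <- L / n
    centers <- spacing * (seq_len(n) - 0.5) +
      stats::runif(n, -0.2, 0.2) * spacing
    widths <- round(stats::runif(n, config$anchor_width[1],
                                 config$anchor_width[2]))
    m0 <- pmax(0, round(centers - widths / 2))
    m1 <- pmin(L, m0 + widths)
    keep <- stats::runif(n) >= p$dropout
    m0 <- m0[keep]; m1 <- m1[keep]
    if (length(m0) < 2L)
      stop(sprintf("pair %s-%s: fewer than 2 anchors after dropout",
                   p$source, p$target))
    strand <- ifelse(stats::runif(length(m0)) < config$inversion_prob,
                     "-", "+")
    sa <- scales[[p$source]]; sb <- scales[[p$target]]
    blocks_fwd <- data.frame(
      chrom_a = "chr1", start_a = round(m0 * sa), end_a = round(m1 * sa),
      chrom_b = "chr1", start_b = round(m0 * sb), end_b = round(m1 * sb),
      strand = strand, stringsAsFactors = FALSE)
    blocks_rev <- blocks_fwd[, c(4:6, 1:3, 7)]
    names(blocks_rev) <- .anchor_cols
    anchor_sets[[paste(p$source, p$target, sep = "|")]] <-
      AnchorSet(blocks_fwd, assemblies[[p$source]], assemblies[[p$target]])
    anchor_sets[[paste(p$target, p$source, sep = "|")]] <-
      AnchorSet(blocks_rev, assemblies[[p$target]], assemblies[[p$source]])
  }
  truth <- structure(list(scales = scales, master_length = L),
                     class = "truthMap")
  list(assemblies = assemblies, anchor_sets = anchor_sets,
       graph = SpeciesGraph(anchor_sets), truth = truth, config = config)
}

#' Exact ground-truth projection between simulated species
#'
#' Composes the inverse of one species' master-coordinate map with
#' another's: `round(pos * scale_b / scale_a)`.
#'
#' @param truth the `truth` element of [simulateSynteny()] output.
#' @param species_a,species_b species identifiers.
#' @param pos 0-based position(s) in `species_a`.
#' @return True 0-based position(s) in `species_b`.
#' @export
truthProjection <- function(truth, species_a, species_b, pos) {
  stopifnot(inherits(truth, "truthMap"))
  if (!all(c(species_a, species_b) %in% names(truth$scales)))
    stop("unknown species")
  sa <- truth$scales[[species_a]]; sb <- truth$scales[[species_b]]
  master <- pos / sa
  if (any(master < 0 | master > truth$master_length))
    stop("position outside the simulated genome")
  round(master * sb)
}

#' Simulate paired signal tracks with planted enrichment domains
#'
#' Generates Poisson background signal in fixed steps for two simulated
#' species and plants rectangular enrichment domains: `shared` domains at
#' truth-corresponding coordinates in both species, plus species-specific
#' domains in only one. Domain positions are aligned to 1-kb master
#' coordinates so that domain edges coincide with analysis bin edges.
#'
#' @param sim output of [simulateSynteny()].
#' @param source_species,target_species species identifiers.
#' @param seed integer random seed.
#' @param n_shared,n_source_only,n_target_only numbers of planted domains
#'   (defaults 3, 1, 1).
#' @param domain_length domain length in master bp, multiple of 1000
#'   (default 5000).
#' @param background_mean Poisson mean of the background signal per step
#'   (default 5).
#' @param snr in-domain signal mean as a multiple of the background mean
#'   (default 4).
#' @param step signal step width in source-species bp (default 100).
#' @return List with `track_source`, `track_target`
#'   ([SignalTrack-class]s) and `domains` (master-coordinate table with
#'   columns `start, end, label`).
#' @export
simulateSignal <- function(sim, source_species, target_species, seed = 1L,
                           n_shared = 3L, n_source_only = 1L,
                           n_target_only = 1L, domain_length = 5000,
                           background_mean = 5, snr = 4, step = 100) {
  set.seed(seed + 7L)
  L <- sim$truth$master_length
  if (domain_length >= L) stop("domain longer than the genome")
  n_dom <- n_shared + n_source_only + n_target_only
  # choose non-adjacent domain slots on the 1-kb-aligned master grid
  slot_w <- domain_length + 2000
  n_slots <- L %/% slot_w
  if (n_slots < n_dom) stop("too many domains for the genome length")
  slots <- sort(sample(n_slots, n_dom))
  starts <- (slots - 1L) * slot_w + 1000
  labels <- sample(rep(c("shared", "source-only", "target-only"),
                       c(n_shared, n_source_only, n_target_only)))
  domains <- data.frame(start = starts, end = starts + domain_length,
                        label = labels, stringsAsFactors = FALSE)
  make_track <- function(species, use_labels) {
    scale <- sim$truth$scales[[species]]
    glen <- chromLengths(sim$assemblies[[species]])[["chr1"]]
    n_steps <- glen %/% step
    means <- rep(background_mean, n_steps)
    dom <- domains[domains$label %in% use_labels, , drop = FALSE]
    if (nrow(dom)) {
      s0 <- round(dom$start * scale); s1 <- round(dom$end * scale)
      for (k in seq_len(nrow(dom))) {
        i0 <- s0[k] %/% step + 1L
        i1 <- min(n_steps, (s1[k] - 1L) %/% step + 1L)
        means[i0:i1] <- background_mean * snr
      }
    }
    vals <- stats::rpois(n_steps, means)
    rec <- data.frame(chrom = "chr1",
                      start = step * (seq_len(n_steps) - 1),
                      end = step * seq_len(n_steps),
                      value = vals)
    SignalTrack(rec, sim$assemblies[[species]])
  }
  track_source <- make_track(source_species, c("shared", "source-only"))
  track_target <- make_track(target_species, c("shared", "target-only"))
  list(track_source = track_source, track_target = track_target,
       domains = domains)
}

#' Write a simulated fixture to disk
#'
#' Emits chrom.sizes per species, one anchor TSV per directed pair, a graph
#' configuration TSV (`source target file format`), optional bedGraph
#' tracks, and the domain truth table.
#'
#' @param sim output of [simulateSynteny()].
#' @param dir output directory (created if missing).
#' @param signal optional output of [simulateSignal()].
#' @param signal_species character 2-vector naming the species of
#'   `signal$track_source` / `signal$track_target` (required with
#'   `signal`).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir, signal = NULL, signal_species = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$assemblies))
    writeChromSizes(sim$assemblies[[sp]],
                    file.path(dir, paste0(sp, ".chrom.sizes")))
  cfg <- data.frame(source = character(), target = character(),
                    file = character(), format = character())
  for (key in names(sim$anchor_sets)) {
    sp <- strsplit(key, "|", fixed = TRUE)[[1]]
    fn <- paste0(sp[1], "-", sp[2], ".anchors.tsv")
    writeAnchorTable(sim$anchor_sets[[key]], file.path(dir, fn))
    cfg <- rbind(cfg, data.frame(source = sp[1], target = sp[2], file = fn,
                                 format = "tsv"))
  }
  utils::write.table(cfg, file.path(dir, "graph.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(signal)) {
    stopifnot(length(signal_species) == 2L)
    writeSignalBedGraph(signal$track_source,
                        file.path(dir, paste0(signal_species[1], ".bedgraph")))
    writeSignalBedGraph(signal$track_target,
                        file.path(dir, paste0(signal_species[2], ".bedgraph")))
    utils::write.table(signal$domains, file.path(dir, "domains.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a graph configuration directory into a SpeciesGraph
#'
#' Expects the layout written by [writeSimulation()]: a `graph.tsv` with
#' rows `source target file format` (`format` one of `tsv`, `chain`) and a
#' `<species>.chrom.sizes` per species, all relative to the config file's
#' directory.
#'
#' @param config_path path to the graph configuration TSV.
#' @return A [SpeciesGraph-class].
#' @export
readSpeciesGraph <- function(config_path) {
  dir <- dirname(config_path)
  cfg <- utils::read.table(config_path, sep = "\t",
                           col.names = c("source", "target", "file",
                                         "format"),
                           colClasses = "character")
  species <- unique(c(cfg$source, cfg$target))
  assemblies <- lapply(species, function(sp)
    readChromSizes(file.path(dir, paste0(sp, ".chrom.sizes")), sp))
  names(assemblies) <- species
  sets <- lapply(seq_len(nrow(cfg)), function(i) {
    path <- file.path(dir, cfg$file[i])
    src <- assemblies[[cfg$source[i]]]; tgt <- assemblies[[cfg$target[i]]]
    switch(cfg$format[i],
           tsv = readAnchorTable(path, src, tgt),
           chain = readChain(path, src, tgt),
           stop("unknown anchor format: ", cfg$format[i]))
  })
  SpeciesGraph(sets)
}
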