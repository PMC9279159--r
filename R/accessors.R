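#' @rdname GenomeAssembly-class
setMethod("speciesId", "GenomeAssembly", function(x) x@species)

#' @rdname GenomeAssembly-class
setMethod("chromLengths", "GenomeAssembly", function(x) {
  len <- as.numeric(seqlengths(x@seqinfo))
  names(len) <- seqnames(x@seqinfo)
  len
})

#' @rdname GenomeAssembly-class
setMethod("genomeSize", "GenomeAssembly", function(x) sum(chromLengths(x)))

#' @importFrom GenomeInfoDb seqinfo
#' @rdname GenomeAssembly-class
#' @exportMethod seqinfo
setMethod("seqinfo", "GenomeAssembly", function(x) x@seqinfo)

setMethod("show", "GenomeAssembly", function(object) {
  len <- chromLengths(object)
  cat(sprintf("GenomeAssembly '%s': %d chromosome(s), %s bp total\n",
              object@species, length(len),
              format(sum(len), big.mark = ",")))
})

#' @rdname AnchorSet-class
setMethod("anchorBlocks", "AnchorSet", function(x) x@blocks)

#' @rdname AnchorSet-class
setMethod("speciesId", "AnchorSet",
          function(x) c(source = x@source_species, target = x@target_species))

#' @rdname AnchorSet-class
#' @param object an AnchorSet.
setMethod("length", "AnchorSet", function(x) nrow(x@blocks))

setMethod("show", "AnchorSet", function(object) {
  cat(sprintf("AnchorSet %s -> %s: %d block(s)\n",
              object@source_species, object@target_species,
              nrow(object@blocks)))
})

#' @rdname ScoringParams-class
setMethod("halfLife", "ScoringParams", function(x) x@half_life)

setMethod("show", "ScoringParams", function(object) {
  cat(sprintf("ScoringParams: distance half-life %g bp (f(d) = 2^(-d/%g))\n",
              object@half_life, object@half_life))
})

setMethod("show", "SignalTrack", function(object) {
  tot <- sum(vapply(object@coverage,
                    function(r) sum(as.numeric(S4Vectors::runLength(r)) *
                                    S4Vectors::runValue(r)), numeric(1)))
  cat(sprintf("SignalTrack on '%s': %d chromosome(s), total signal %g\n",
              object@assembly@species, length(object@coverage), tot))
})

setMethod("show", "SpeciesGraph", function(object) {
  cat(sprintf("SpeciesGraph: %d species, %d directed edge(s)\n",
              length(object@species), length(object@edges)))
  if (length(object@edges))
    cat(" ", paste(sub("\\|", " -> ", names(object@edges)), collapse = ", "),
        "\n")
})

#' @rdname ProjectionResult-class
setMethod("projectionScore", "ProjectionResult", function(x) x@score)

#' @rdname ProjectionResult-class
setMethod("speciesPath", "ProjectionResult", function(x) x@path)

#' @rdname ProjectionResult-class
setMethod("stepDistances", "ProjectionResult", function(x) x@step_distances)

#' @rdname ProjectionResult-class
setMethod("pathLength", "ProjectionResult", function(x) 1 - x@score)

setMethod("show", "ProjectionResult", function(object) {
  if (length(object@path) == 0L) {
    cat(sprintf("ProjectionResult %s:%g -> unprojectable (score 0)\n",
                object@query_chrom, object@query_pos))
  } else {
    cat(sprintf("ProjectionResult %s:%g -> %s:%g\n  score %.6g, path %s, step distances [%s] bp\n",
                object@query_chrom, object@query_pos,
                object@target_chrom, object@target_pos, object@score,
                paste(object@path, collapse = " -> "),
                paste(object@step_distances, collapse = ", ")))
  }
})

#' @rdname EnrichmentTest-class
setMethod("oddsRatio", "EnrichmentTest", function(x) x@odds_ratio)

#' @rdname EnrichmentTest-class
setMethod("pValue", "EnrichmentTest", function(x) x@p_value)

setMethod("show", "EnrichmentTest", function(object) {
  cat("EnrichmentTest (Fisher's exact, two-sided)\n")
  print(object@table)
  cat(sprintf("  odds ratio %g, p = %g%s\n", object@odds_ratio,
              object@p_value,
              if (object@degenerate) " [degenerate margin]" else ""))
})
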