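---
title: "Cross-species coordinate projection through bridging species"
author: "bridgemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species coordinate projection through bridging species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridgemap)
```

## The model

Direct sequence alignments between distant vertebrates (fish vs mammal)
cover only a small fraction of the non-coding genome, yet regulatory
elements largely preserve their *order* along the chromosome, with
spacing roughly proportional to genome size — conserved synteny. The
method implemented here exploits that: a position `x` with no direct
alignment is projected into another genome by linear interpolation of
its relative position between the two nearest aligned anchor blocks
(`a⁽¹⁾` upstream, `a⁽²⁾` downstream). A position inside an anchor block
maps base-proportionally within the block.

Interpolation degrades with distance from the anchors. The confidence
of one projection step is scored as

$$f(x) = \exp\left(-\frac{\min(|x-a^{(1)}|, |x-a^{(2)}|)}{g\,s}\right),
\qquad s = \frac{-d_h}{g \log 0.5},$$

with `g` the genome size of the species in which the distance is
measured and `d_h` the **distance half-life**, defined so that
`f(d_h) = 0.5`. Substituting `s` shows `g` cancels exactly:
`f(d) = 2^(-d/d_h)`. The package implements the reduced form (which
makes `f(0) = 1` and `f(d_h) = 0.5` exact in floating point) and keeps
`scalingFactor()` so the equivalence is testable; genome-size invariance
is asserted over random `(d, g)` in the test suite.

**Bridging species.** Because anchors between close relatives are much
denser than between distant ones, routing a projection through
intermediate species can shrink the anchor distances at every step. With
species as nodes and pairwise anchor sets as directed edges, a path `p`
gets length $l_p = 1 - \prod_{i \in p} f(x_i)$ and the best route is
$\dot p = \arg\min_p l_p$. Since $\prod f = 2^{-\sum d_i/d_h}$,
minimizing $l_p$ is minimizing the **total anchor distance in bp**, an
additive weight, so the search is a classic shortest-path problem solved
with Dijkstra's algorithm. The coordinate is re-interpolated at each
hop and propagated along relaxed edges.

One subtlety is documented rather than hidden: Dijkstra keeps a single
best label per species, but the coordinate reached at a node depends on
the path taken, and per-hop integer rounding can make two routes reach a
node at coordinates a base pair or two apart. The greedy label is
therefore not a *guaranteed* global optimum. The package ships
`enumeratePathsProject()`, an exhaustive simple-path enumerator, as an
independent oracle; on 100 seeded random fixtures (3–6 species, random
scales, densities and dropout) the two agree exactly, and the
equivalence is a standing test.

## Parameters that matter

- **`half_life` (`d_h`), bp; default 10,000.** The distance at which one
  projection step scores 0.5. The default is chosen so that the IC
  operating point — a path score of 0.99 — corresponds to a total
  peak-to-anchor distance just under 150 bp: inverting
  `2^(-d/d_h) = 0.99` gives `d ≈ 145.0 bp`. It is exposed everywhere
  (`ScoringParams()`, `--half-life`) and should be treated as a tunable,
  not a constant of nature.
- **IC threshold; default 0.99, strict (`score > 0.99`).**
- **Enrichment quantile `enrich_q`; default 0.8.** Matches the common
  convention of calling histone-mark signal enriched at or above its
  80th percentile; configurable per analysis.
- **Bin size; default 1,000 bp.** Terminal partial windows are kept iff
  at least half a bin wide, so arbitrary region lengths bin
  deterministically.
- **Ratio floor `0.01`, cap `1`, log base 2.** The log signal ratio is
  computed on quantile-normalized values floored at 0.01 (so empty bins
  do not produce infinities) and capped to [-1, 1]. Raw-coverage ratios
  are available behind `use_quantiles = FALSE`.

## Numerical and design choices

- **Coordinates.** 0-based half-open (BED convention) in all files and
  point arguments; `GRanges` inputs use the usual 1-based convention and
  are converted internally.
- **Interpolated coordinates** are rounded with round-half-to-even on
  the interpolated fraction — deterministic and unbiased.
- **Distance attribution.** Each traversed edge contributes the anchor
  distance measured in its *source* species; the terminal species
  contributes none. This makes a two-node path score identical to the
  single pairwise score.
- **Flank consistency.** Interpolation requires both flanking anchors to
  share target chromosome, strand, and target-side collinearity;
  minus-strand pairs interpolate with reversed orientation. Discordant
  flanks, and positions beyond the first/last anchor of a chromosome,
  are *unprojectable* for that species pair (no extrapolation); a query
  unreachable by every route returns score 0 and an empty path, and is
  classified NC.
- **Overlapping source anchors** (invalid input) are resolved
  deterministically: longer block kept, shorter dropped with a warning.
- **Ties** between equal-score paths go to fewer nodes, then
  lexicographic species order.
- **Conservation reference point.** IC scoring projects the peak
  midpoint by default (`reference_point = "endpoints"` projects both
  ends and keeps the better score). DC requires ≥ 1 bp overlap with a
  direct anchor block.
- **Fisher's exact test** (two-sided) sums hypergeometric probabilities
  not exceeding the observed table's; the odds ratio reported is the
  sample `ad/bc`. Tables with a zero margin are flagged `degenerate`.
  The implementation is verified against a `choose()`-based enumeration
  oracle on every 2×2 table with all margins ≤ 30, and spot-checked
  against `stats::fisher.test`.

## What the simulator emulates — and what it does not

`simulateSynteny()` builds species along a shared master axis with
per-species linear genome-size scales (default 1×, 1.2×, 2×, echoing the
roughly two-fold size difference between fish and mammalian regulatory
domains), anchors placed per pair at configurable density with jitter,
dropout, and optional inversions; `simulateSignal()` adds Poisson
background (mean 5 per 100-bp step) with planted rectangular domains at
`snr` times the background mean, shared domains at truth-corresponding
positions. Defaults mirror the sparse-direct (1 anchor / 50 kb) vs
dense-bridge (1 / 2 kb) contrast that motivates bridging; on those
defaults the median total anchor distance drops more than five-fold when
the bridge is used — a qualitative, desk-scale analogue of the much
larger genome-wide gains achievable on real fish/mouse alignments, which
require the real genomes and are deliberately out of scope here.

What the simulator does *not* model: sequence (no nucleotides),
rearrangements beyond optional single-block inversions, lineage-specific
insertions that distort local scaling non-linearly, mappability and
coverage artefacts of real ChIP/ATAC data, and realistic phylogenies.
Passing the recovery tests therefore demonstrates correctness of the
machinery under the collinearity assumption, not performance on real
genomes.

A property worth knowing when reading comparison output: because
enrichment is defined on *quantile ranks*, roughly `1 - enrich_q` of
bins per species exceed the threshold whatever the signal looks like.
Bins of a truly species-specific domain are thus occasionally labelled
mutually enriched when the other species' background noise ranks high —
visible in the simulator at any SNR. Interpret `mutually-enriched`
fractions relative to the ~`(1-enrich_q)²` chance floor, which is what
the Fisher tests (`sharedEnrichmentByAlignability()`,
`ensembleEnrichment()`) do formally.

## Problem sizes used in the checks

The shipped tests run on 200-kb master axes (200 one-kb bins, up to six
species, a few hundred anchors per pair) — small enough to enumerate
paths exhaustively and to re-derive every expected value independently,
while exercising every code path including unprojectable bins, dropout
and inversions.

## Known limitations

- Interval projection is endpoint/midpoint-based; split or inverted
  intervals are not decomposed.
- Quantile normalization is pairwise; comparing more than two species
  requires repeated pairwise runs.
- The Dijkstra label-per-species strategy is greedy (see above); the
  enumeration oracle bounds the effect on small graphs only.
- The default `d_h` is inferred from a printed consequence, not a
  printed value; analyses sensitive to the IC threshold should sweep it.
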