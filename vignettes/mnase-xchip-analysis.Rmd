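---
title: "Fragment-level analysis of MNase X-ChIP-seq: models, conventions and design choices"
author: "mnasechip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-level analysis of MNase X-ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnasechip)
```

## The measurement model

Conventional ChIP-seq shears chromatin by sonication, which yields 200-500 bp
fragments — roughly tenfold larger than the footprint of a typical
DNA-binding factor — and breaks DNA preferentially in accessible regions, so
both the resolution and the position of the recovered signal are limited by
the fragmentation itself. When micrococcal nuclease (MNase) fragments
crosslinked chromatin instead, its combined endo- and exo-nuclease activity
digests DNA up to the edge of each bound protein. The sequenced paired-end
insert then *is* the protected footprint: its length approximates the
protein's DNA contact and its two ends delimit the contact almost exactly.

Everything in this package follows from that identification. Fragments are
intervals; all downstream statistics are functions of fragment intervals
relative to stranded anchor sites (motif matches, TSS):

* **size-class stratification** separates factor-sized footprints
  (e.g. 20-50 bp) from nucleosomal (~147 bp) and composite
  factor:nucleosome fragments, which arise because formaldehyde also forms
  protein-protein crosslinks;
* **normalized coverage** at a base is the fraction of mapped fragments
  spanning it, multiplied by the genome size — a depth-free scale on which
  1.0 means "as dense as the genome-wide expectation";
* **end profiles** count fragment termini per bp around anchors: if MNase
  has chewed back to the footprint on each side, the left- and right-end
  peaks flank the motif at exactly its width;
* **V-plots** place each (site, fragment) incidence at (midpoint offset,
  length); the apex of the V — the minimum occupied length above the
  anchor — estimates the minimal protected footprint;
* **per-site half-height widths** quantify resolution as the number of
  contiguous bp whose signal is at least half the local maximum.

## Coordinate and orientation conventions

These conventions are load-bearing; every offset in the package depends on
them.

* Intervals are 0-based half-open (BED convention) everywhere internally;
  BAM's 1-based positions are converted at the boundary.
* A site of width $w$ starting at $s$ has center $s + \lfloor (w-1)/2
  \rfloor$: base 10 of a 19-bp motif, and the left-of-center base for even
  widths.
* A fragment's *right end* is its half-open end coordinate — the first
  unprotected bp. Under this convention a fragment spanning a 19-bp motif
  exactly has its left end at offset $-9$ and its right end at $+10$, and
  the end-peak separation equals the footprint width, 19 bp. This is the
  only convention for which "ends separated by 19 bp at a 19-bp motif"
  holds, and it is asserted by tests.
* Minus-strand sites are flipped into motif orientation: offsets are
  negated and the left/right end roles swap. Note the flip is not a
  symmetry of the half-open convention: the same exactly-spanning fragment
  at a minus-strand site has peaks at $-10/+9$. Analyses that mix strands
  therefore smear each end peak over two adjacent offsets; this is
  inherent to integer end coordinates, not an artifact of the
  implementation.
* Fragment midpoints are $\lfloor (start+end)/2 \rfloor$ (left of the two
  central bases for even lengths).
* Sites whose window would cross a chromosome edge are dropped and
  counted, never zero-padded: padding fabricates signal.

## Normalization

`normalize_coverage()` computes $v' = (v / N) \cdot G$ with $N$ the number
of mapped fragments recorded at ingestion and $G$ the genome size. $N$ is
deliberately *not* recomputed after size-class filtering: per-class tracks
share the parent denominator, so classes remain comparable and the tracks
of disjoint exhaustive classes sum to the full track. An algebraic
consequence used as a test oracle: the genome-wide mean of a normalized
track equals the mean fragment length of the set, because $\sum_{bp} v =
\sum_i \ell_i$. ChIP/input ratio tracks are supported as an optional
division of two normalized tracks with a pseudocount (default 0.1) at
zero-input positions.

## The half-height width statistic

For one site, the signal over $\pm 1000$ bp is reduced to: the maximum; the
background, defined as the median over the two outermost 100-bp windows
($-1000..-900$ and $+900..+1000$, inclusive — 101 values per side, lower
median for even counts); and the width, the number of contiguous bp in the
run containing the maximum whose signal is at least the half-height.

The half-height itself admits two readings. Defining it through the ratio
of maximum to background rescales the signal by a positive constant, and a
positive rescaling does not change which offsets satisfy "at least half of
the maximum"; the default therefore thresholds at $\max/2$ on the given
signal and keeps the background purely for QC (`zero_background` flags
sites with non-positive background rather than dropping them silently).
The alternative reading — rise above background,
$bg + (\max - bg)/2$ — is available as `threshold_mode = "midrise"`. Scale
invariance of the default is asserted numerically, and the whole procedure
is checked against an independent exhaustive scan on a thousand random
signals.

Two smaller choices: the contiguous run is anchored at the run containing
the (leftmost, on ties) argmax, not the longest run anywhere — the
statistic describes the peak at the motif; and flat signals are flagged
`flat` with width equal to the whole span.

## End-peak pairs and site spacing

`peak_pair_separation()` reports the distance between the left-end and
right-end peaks. The default `split` source takes the argmax of each end
profile separately (leftmost position on exact count ties); `combined`
finds the two highest local maxima of the summed profile at least
`min_peak_distance` (default 5) bp apart, since it is not obvious a priori
which read-out a given dataset supports better. A peak pair is only
reported as a separation when the two peaks straddle the motif center;
unimodal profiles are flagged rather than forced into a pair. Predominant
peaks are local maxima, after min-distance suppression, reaching at least
half (configurable) of the global maximum.

`motif_spacing_filter()` retains sites whose nearest same-chromosome
neighbor (center-to-center, measured against the *original* input set) is
at least 500 bp away; both members of a crowded pair are removed. Measuring
against the original set makes the filter idempotent and
order-independent, and is validated against a quadratic brute force.

## What the synthetic generator emulates

The generator produces paired-end fragment intervals with ground truth; it
simulates no sequence, read errors, PCR duplicates or mappability — the
pipeline consumes intervals only.

* **Footprint fragments** (`simulate_tf_chip`): per site, a
  Poisson-distributed number of fragments spanning the site exactly,
  extended outward per side by independent geometric(`chew_p`) overhangs
  with support $0, 1, 2, \ldots$ This is the simplest process consistent
  with exonuclease chew-back that stalls at the bound protein: the modal
  overhang is 0, so the modal fragment ends are the footprint edges, and
  the split-mode end-peak separation recovers the footprint width. The
  default `chew_p = 0.5` is a free parameter — no quantitative chew-back
  distribution is established — chosen so that half of all fragment ends
  sit exactly at the footprint edge.
* **Background** is a mixture, half nucleosome-sized fragments
  (normal, 147 ± 10 bp) and half long composites (log-normal, median
  250 bp), placed uniformly at `background_rate` per kb (default 0.5).
  This reproduces the size-class structure of real MNase X-ChIP libraries
  — a minority of factor-sized fragments against a nucleosomal/composite
  majority — without a mechanistic crosslinking model, which the analysis
  does not need. Fragments that would extend past a chromosome end are
  discarded and counted, never truncated.
* **Sonication** (`simulate_sonicated_chip`): fragment lengths uniform on
  200-500 bp; one end of each fragment is a break drawn from a mixture of
  a genome-uniform component (weight 1) and Gaussian hotspots of sd 50 bp
  at anchor centers (weight `accessibility_bias_weight`), assigned to the
  left or right side with equal probability. We model per-fragment break
  draws rather than a genome-wide break point process: the analyses this
  feeds (end-position bias around anchors, length bounds) depend only on
  the marginal end distribution, which the two formulations share.
* **Size selection** (`apply_size_selection`): independent retention with
  logistic probability $1/(1+e^{k(\ell - m)})$, midpoint $m = 170$ bp
  (the unbound-fraction cutoff of a 1.1x bead:DNA ratio) and steepness
  $k = 0.08$/bp by default; $k = \infty$ is a hard cutoff retaining
  $\ell < m$. The report carries the fraction of fragments under 50 bp
  before and after, and their ratio — the fold-enrichment statistic of a
  short-fragment selection.

Each generator call seeds its own RNG stream from `config$seed` (offsets 0,
1, 2 for the three operations, so a pipeline combining them stays
reproducible) and restores the caller's stream afterwards.

What passing tests on these simulations do **not** show: real chromatin has
sequence-dependent MNase preferences, heterogeneous occupancy, overlapping
binding sites and mappability gaps, none of which are modelled. The
simulations validate the *computations* — conventions, aggregation,
statistics — not biological generality.

## Numerical and degenerate-input choices

* Background median over an even count of values: lower median.
* Argmax ties: leftmost, everywhere (half-height run anchor, split end
  peaks).
* Empty size-class results are legal; empty length distributions, all-zero
  end profiles and empty site lists are errors.
* Duplicate fragments are retained; deduplication is not part of the
  ingestion contract (a mapping-quality floor, default 20, is the only
  read-level filter, and applies to BAM input).
* Site windows are extracted per chromosome with integer indexing; all
  aggregation is exact integer counting, so identical inputs give
  bit-identical outputs.

## Problem sizes used by the test suite

The suite validates on simulations sized for quick iteration: the
end-separation and V-plot studies use 100-500 sites with 100-200 fragments
per site on 2-5 Mb chromosomes (~10^5 fragments); the sonication-bias
study uses 5 x 10^4 fragments (10^5 ends) on a 10-Mb chromosome; oracle
comparisons run on 200-1000 random instances of span up to 201 bp. These
sizes were chosen so each property is measured well inside its sampling
noise while the full suite stays interactive.

## Known limitations

* BAM ingestion takes each proper pair's leftmost record and its TLEN
  field as the insert; exotic alignments (supplementary-only pairs,
  TLEN-zero pairs) are discarded rather than reconstructed from CIGARs.
* `read_track()` materializes per-bp vectors, which is the right trade-off
  up to tens of megabases but not for a full mammalian genome in one call;
  the package's own analyses only ever materialize the chromosomes present
  in the genome table given.
* The thresholding peak caller is deliberately minimal (threshold, gap
  merge, width filter) — the low-noise regime it serves makes model-based
  significance unnecessary, and none is provided.
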