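---
title: "Calling sub-kilobase chromatin loops from restriction-fragment Hi-C"
author: "segloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling sub-kilobase chromatin loops from restriction-fragment Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segloop)
```

## The problem

In gene-dense genomes such as *Arabidopsis thaliana*, where genes and
intergenic spaces are each only 2-3 kb, regulatory chromatin loops are
expected at the scale of a few kilobases. Detecting them requires Hi-C
contacts binned at restriction-fragment resolution rather than the fixed
multi-kilobase windows used for mammalian topological domains. `segloop`
implements a complete fragment-level loop-calling pipeline: segment
construction, distance-decay modelling, explicit bias correction, a
negative-binomial (NB) convolution significance test, gene self-loop
classification, and permutation nulls for downstream enrichment claims, plus
a seeded synthetic-data generator that makes every stage testable without
external data.

## Segment universe

Chromosomes are digested in silico at a four-cutter motif (GATC by default,
the DpnII site; the cut is placed at the motif start, matching the enzyme's
blunt 5' cut — the exact offset only shifts boundaries by up to 4 bp and has
no statistical consequence). Because most fragments are shorter than 500 bp,
consecutive fragments are merged greedily left to right until each segment
reaches `min_len` (default 500 bp); a trailing remainder shorter than the
threshold is absorbed into the previous segment, and a single long fragment
is never split. The result is a tiling set of segments mostly 500 bp - 1 kb.
Each segment records its length $l$, its fragment-end count $E$ (the number
of restriction ends it contains: interior cut sites plus its two
boundaries), and its midpoint; the distance between two segments is the
distance between midpoints. Coordinates are 0-based half-open everywhere
inside the package, with GFF3's 1-based closed convention converted at the
I/O boundary — a single internal convention prevents off-by-one drift.

Analysis is restricted to intra-chromosomal segment pairs separated by
2-25 kb (both bounds inclusive; contacts below ~1.5-2 kb are dominated by
self-ligation artefacts, and the log-linear decay assumption below holds in
this window). Segments overlapping a user-supplied centromere mask are
tagged, and every pair touching a tagged segment is dropped: the mask
semantics are "any overlap excludes", the conservative reading.

## Distance decay

Contacts are sorted by distance and divided into 50 bins of (approximately)
equal read occupancy. All reads at one distance stay in one bin, so the bin
boundary moves to the next distinct distance where needed; with distinct
unit-count distances the occupancies are equal to within one. Each bin $i$
contributes a point $(D_i, C_i)$ where $C_i = N_i/(b-a+1)$ is the per-bp
contact intensity over the bin's distance span $[a, b]$ and $D_i$ is the
read-weighted mean distance. (A literal reading of the usual formula for
$D_i$ with a denominator $\sum_j j$ over distances does not produce a mean;
the read-count-weighted mean is used.)

The 50 log-log points are fitted with a cubic smoothing spline
(`stats::smooth.spline`). The smoothing knob defaults to ~8 effective
degrees of freedom on 50 bins, which reproduces power laws essentially
exactly while leaving room for smooth curvature; spline smoothing parameters
are not portable across implementations, so exact curve equality with any
particular historical fit is a non-goal. The fitted values are projected
onto the nearest non-increasing sequence (antitonic regression,
`stats::isoreg`), which is the minimal deterministic way to enforce the
physical requirement that contact intensity cannot increase with distance.
Between knots the model interpolates linearly in log-log space; outside the
fitted domain it clamps to the boundary values. Natural logarithms are used
throughout.

## Bias model

Two multiplicative per-segment visibility factors enter the contact
probabilities:

* **Sequencing bias $\beta$** — the ratio of a segment's length-normalized
  genomic-resequencing coverage to the genome-wide mean (so
  $\mathrm{mean}(\beta) = 1$). It proxies PCR and mappability effects.
  Multiple resequencing runs are pooled by summing depth. Contacts between
  segments with $\beta < 0.05$ or $\beta > 20$ are removed (bounds
  inclusive on the retained side), and such segments are excluded from
  anchor *and* partner sets — if a segment is invisible, its share of
  contact probability must redistribute to detectable partners.
* **Fragment-end density $f(E)$** — Hi-C depth grows with the number of
  restriction ends a segment carries. The effect is fitted as a log-linear
  regression of Hi-C marginal depth on $E$ and normalized to mean
  multiplier 1 (the normalization cancels in the probability ratio below;
  this is property-tested).

For an anchor segment $A$, the contact probability of partner $B$ among all
usable partners $j$ within 2-25 kb on both sides is

$$p_{AB} = \frac{f(D_B)\, f(E_B)\, l_B\, \beta_B}
                {\sum_j f(D_j)\, f(E_j)\, l_j\, \beta_j},$$

an explicit factor model rather than matrix balancing (ICE/KR); at
fragment-scale sparsity the explicit model is better conditioned and keeps
every factor interpretable.

## The NB convolution test

The observed count $k$ of a pair is modelled as $AB = X + Y$ with
$X \sim \mathrm{NB}(\hat A, p_{AB})$ and $Y \sim \mathrm{NB}(\hat B, p_{BA})$
— one term per anchoring of the pair. The NB pmf is the count form
$f(k, r, p) = \binom{k+r-1}{k} p^k (1-p)^r$, generalized to non-integer $r$
through the gamma function and evaluated in log space. The pmf of the sum is
the exact convolution
$P(AB = k) = \sum_i P(X = i)\,P(Y = k - i)$, computed as an $O(k^2)$ exact
sum (counts rarely exceed a few hundred at this scale, so no transform
tricks are needed), and the p-value is the upper tail
$1 - \sum_{j<k} P(AB = j)$, floored at zero against rounding. A printed
variant of the convolution in which both factors carry the same index is
treated as a typographical slip: it is not a convolution and contradicts the
defining sum $AB = X + Y$.

The background ("failed trials") parameter for anchor $A$ is
$\hat A = \sum_i C_{Ai} r_i$ over the anchor's observed partners, with

$$r_i = \frac{A_\mathrm{tot} - C_{Ai}}
             {(A_\mathrm{tot} - C_{Ai}) + (i_\mathrm{tot} - C_{Ai})},$$

set to $1/2$ when the denominator vanishes. Depths are each segment's total
read count within the 2-25 kb analysis window (a config-level choice; the
depth definition is not fully pinned by the method's description, and the
windowed reading matches the fact that the whole analysis operates on the
extracted window). When a pair $(A,B)$ is tested, its own contribution
$C_{AB} r_B$ is subtracted from $\hat A$, so the background excludes the
reads being tested. Benjamini-Hochberg correction is applied over the family
of all tested pairs — pairs with $k \ge 1$ passing all filters; zero-count
pairs are untestable ($p = 1$) and would only inflate the family size — and
loops are pairs with $q < 0.01$ (0.05 as a relaxed threshold).

### Known limitation: visibility-coupled backgrounds

The depth-share weights $r_i$ make the test's expected count approximately
$\lambda\,[A_\mathrm{tot}/(A_\mathrm{tot}+\bar I) +
B_\mathrm{tot}/(B_\mathrm{tot}+\bar J)]$, where $\bar I, \bar J$ are typical
partner depths. For pairs in which *both* segments have below-average
visibility (short, few restriction ends, low $\beta$), this undershoots the
true rate and the p-value tail is mildly anticonservative. In deep all-null
simulations with biases active this surfaces as an occasional (roughly 1 in
4 runs) single false call at $q < 0.01$ among tens of thousands of tested
pairs, while the bulk p-value distribution stays uniform (KS distance
$\approx 0.03$) and planted-loop FDR stays controlled. Users combining very
deep data with strong visibility heterogeneity should treat borderline calls
between two low-visibility segments with care.

## Gene self-loops

For each gene, focal points are placed at the TSS and at 400 and 800 bp
downstream (each used only if inside the gene body). Each focal point maps
to its containing segment; significant loop partners of that segment whose
centers lie within the search radius — the distance from the focal point to
the TTS, inclusive — are classified 3' (downstream in the direction of
transcription) or 5'. Minus-strand genes are handled by mirroring, so
"downstream" always follows transcription; a partner centered exactly on the
focal point counts as neither. A gene has a self-loop if any focal point has
a 3' partner; categories are `none`, `5'only`, `3'only`, `both`. Genes are
candidates when the TSS search radius (= gene length) is at least the 2 kb
minimum callable span — the weakest rule consistent with the caller's
distance floor. Directionality-bias scans place focal points 5, 2, 1, 0.5
and 0 kb upstream of TSSs and report the 3'/5' partner fractions per
expression group.

## Association and permutation nulls

Promoters are TSS±500 bp; a promoter is "marked" when at least 30% of its
bases are covered by (merged) peak intervals. Promoter-pair interactions are
significant loops of span ≥ 6 kb whose two segments overlap distinct
promoters (maximal-overlap assignment, ties to the nearest TSS). The
null for feature-enrichment claims translates the whole feature track by
±10/±20 kb (or ±4/±8 kb for strip-like tracks), wrapping circularly at
chromosome ends so feature count and total length are conserved exactly —
wrapping keeps the null comparable to the observed statistic; wrapped
features are stored as two rows sharing a `feature_id` so the shift is
invertible. Empirical p-values use the add-one estimator
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + \#\mathrm{null})$.
Expression nulls reassign each gene the level of its 20th or 50th neighbor
up- or downstream in chromosome order (wrapping within the chromosome),
preserving the per-chromosome level multiset. Signal/control tracks are
compared as natural-log ratios after scaling to equal totals, with a
one-read pseudocount; "enriched" means ratio > 1. Short loops (< 6 kb) with
both anchors in gene bodies are split into within-gene versus between-gene
counts, optionally restricted to dual-enriched anchors.

## The synthetic generator

`simulate_study()` emulates the study conditions end to end and is itself
first-class, tested code:

* **Genome** — chromosome sequences assembled from geometric inter-motif
  gaps (mean spacing 256 bp, the expectation for a 4-mer in uniform
  sequence) with accidental motif occurrences destroyed, so digestion
  recovers the configured spacing; non-overlapping genes with uniform
  lengths (default 1.5-4.5 kb) and random strands.
* **Contacts** — the generative mirror of the caller's factor model:
  $\lambda_{AB} \propto D^{-\alpha} (E_A E_B)^{\gamma} l_A l_B \beta_A
  \beta_B$ over the 2-25 kb window, scaled to the configured total. Defaults:
  $\alpha = 1$ (log-linear decay as observed in this window),
  $\gamma = 0.5$ (a moderate end-density effect), $\beta$ log-normal with
  $\sigma = 0.25$. Counts are Poisson given $\lambda$ — conditional on the
  rate, sequencing read counts are Poisson; marginal over-dispersion arises
  from the explicit factor heterogeneity. A `dispersion` knob switches to NB
  for sensitivity work.
* **Planted structure** — generic loops at 2-8 kb spans (gene-scale loops;
  genes here are 2-3 kb) with 10-fold enrichment by default; gene self-loops
  connecting the TSS segment to the segment 500 bp inside the 3' end of the
  transcribed region (so the 3' anchor's segment center stays within the
  classifier's search radius); promoter-pair loops at ≥ 6 kb spans between
  TSS segments.
* **Tracks** — ChIP peaks covering the promoters of planted promoter-pair
  genes with configurable coupling plus background peaks; expression levels
  uniform on 0-9; resequencing coverage Poisson with mean
  $\beta\, l \times 0.3$ reads/bp (≈30× with 100 bp reads).

What the generator does **not** emulate: real base composition, centromere
structure, long-range heterochromatic contacts, self-ligation artefacts
(the < 2 kb exclusion zone is simply empty), chromatin-state structure, or
correlated placement of genes and biases. Passing tests therefore
demonstrate the statistical machinery under the stated factor model, not
performance on any particular real genome.

## Problem sizes and seeds

The test suite validates at desk scale, chosen so each property is measured
where it is informative: null calibration on a 1 Mb genome with 5×10⁵
contacts (≈40,000 tested pairs, per-pair expectation ≈12, 20 seeds);
planted-loop recovery on 5×2 Mb chromosomes with 5×10⁵ contacts and 50
planted 10-fold loops (3 seeds, pooled recall/FDR); decay recovery at 10⁵
contacts per exponent; classifier equivalence on 1,000 random genes; shift
nulls on 20 seeded 0.5 Mb studies. All randomness is seeded; the pipeline is
byte-for-byte deterministic given (config, seed).

## Numerical choices

Convolution sums run in plain double precision over at most a few hundred
non-negative terms (relative error ~1e-14; verified against brute-force
enumeration to 1e-10). Probabilities at or above 1 (an anchor with no
alternative partner) make a pair untestable; such pairs are skipped and
counted. A zero background parameter degenerates the NB to a point mass at
zero. Equal-occupancy binning errors out when there are fewer distinct
distances than bins. Bias tables with missing segments drop the affected
contacts with a warning rather than guessing.
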