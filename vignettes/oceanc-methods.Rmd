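---
title: "Calling and interpreting hubs of open chromatin interactions"
author: "oceanc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and interpreting hubs of open chromatin interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Open-chromatin enrichment Hi-C assays capture proximity-ligation products in
which at least one end comes from nucleosome-depleted chromatin. After
alignment, the data are ordinary Hi-C-style read pairs, but the 1D pile-up of
ligation-product ends is strongly concentrated at open regulatory elements
that engage in many chromatin contacts. `oceanc` implements the downstream
computational chain for such data: read-pair filtering, calling the 1D peaks
(hubs of open chromatin interactions, HOCIs), classifying them into promoter
and enhancer elements, building the hub-hub contact network, relating gene
promoters and expression to hubs, intersecting hubs with super-enhancers and
broad H3K4me3 domains, and computing binned contact maps with ICE balancing,
A/B compartments and insulation boundaries.

Everything operates on 0-based half-open coordinates internally (BED
convention); conversion to 1-based happens only inside the interval-overlap
engine (which delegates to `GenomicRanges`) and at text export.

## Read-pair classification

A mapped pair is classified in a fixed decision order:

1. either mate's MAPQ below `mapq_min` (default 1): `LOW_MAPQ`;
2. mates on different chromosomes: `VALID_TRANS`;
3. both mates in one restriction fragment: `DANGLING_END` (inward),
   `SELF_CIRCLE` (outward) or `SAME_STRAND_DUMPED`, the orientation being
   read off after putting the mates in coordinate order so the call is
   invariant under mate swap;
4. mates in different fragments whose midpoints are closer than
   `min_separation` (default 1000 bp): `TOO_CLOSE`;
5. otherwise `VALID_CIS`.

The in-silico digest cuts at every occurrence of the recognition site (MboI
`GATC` by default), with the cut placed at the match start; `N` never
matches, and zero-length fragments at the chromosome ends are suppressed.
The "distance between fragments" in rule 4 is taken between fragment
midpoints, which is stable under where the read fell within its fragment; a
nearest-edge alternative is available (`distance_mode = "edge"`). Exact
coordinate-and-strand duplicates among valid pairs are removed by default
(PCR duplicates); the classification report always partitions the raw input.

The `cis_distance` column carries |pos1 - pos2| of the read 5' ends (this is
the quantity summarised per interaction category later); the
fragment-midpoint distance is kept separately as `frag_distance`.

## HOCI calling

Both ends of every valid pair are binned at 50 bp. Each non-empty bin is
tested against a Poisson null whose rate is the maximum of the genome-wide
mean and the local means in 5 kb and 20 kb windows centred on the bin (the
classic local-background construction used by MACS-style callers). P-values
are Benjamini-Hochberg adjusted over all tested bins genome-wide with ties
resolved in genomic order; significant bins closer than `merge_gap` (200 bp)
merge into peaks; peaks narrower than `min_width` (150 bp) are dropped;
`mode = "broad"` merges across `4 * merge_gap` first. The summit is the
maximum bin's centre.

The original assay's peak caller was a zero-inflated negative-binomial
mixture tool that is no longer maintained; a Poisson local-background test
is used here instead. The package's quantitative contract for the caller is
planted-hub recovery on synthetic data (recall and precision at least 0.9
under the standard simulation conditions, in practice 1.0), not
bit-equivalence with any specific historical tool. Two consequences are
worth knowing: deeper coverage increases detection power, so the significant
set can grow with depth while true-peak locations stay put; and the local
window means include the peak itself, which is conservative for broad
enrichments.

`saturation_curve()` downsamples the valid pairs without replacement at
given fractions and re-calls peaks, reproducibly for a fixed seed.

## HOCI classes, network and distance categories

A HOCI overlapping (>= 1 bp) both an H3K4me3 peak and a gene promoter
window is a promoter HOCI; otherwise one overlapping both H3K4me1 and
H3K27ac peaks is an enhancer HOCI; the rest are other. Promoter windows are
upstream-only by default, `[TSS - 2000, TSS)` on the plus strand and the
mirror image on minus, clipped to the chromosome; a symmetric +/- 2 kb
option exists because overlap-based promoter definitions in the literature
use both conventions. Promoter precedence makes the classification a
partition regardless of how the enhancer rule treats H3K4me3-positive
regions.

The interaction network assigns each read 5' end to the (non-overlapping)
HOCI containing it; an edge's weight is the raw number of pairs joining two
hubs (no distance-decay normalisation of weights, matching how individual
ligation products are drawn as loops in browser views). Pairs with both
ends in one hub count toward that node's interaction total but form no
edge. Valid pairs are categorised by the classes at their two ends with
both-end categories taking precedence over single-end ("related")
categories, and cis distances are summarised per category. Medians use the
lower of the two middle values for even sample sizes, so a reported median
is always an observed distance.

## Gene typing and condition comparisons

A gene is a hub gene if its promoter window overlaps a HOCI, an interacting
gene if at least one valid pair (configurable threshold, default 1) joins
the promoter window to any HOCI, and dissociative otherwise. "Expressed"
means RPKM strictly above 0.5. Between two conditions, genes are grouped
into same-type, hub-to-dissociative switches, and other changes; the
"promoter HOCI changed" flag is purely overlap-based (the promoter overlaps
a HOCI in exactly one condition). Expression changes use
`log2((RPKM_A + eps) / (RPKM_B + eps))` with `eps = 0.01` RPKM; the
pseudocount keeps silenced genes finite and is far below the expressed-gene
cutoff. Within down- and up-regulated genes separately, |log2FC| of
promoter-HOCI-changed genes is compared against unchanged genes with a
one-sided Mann-Whitney test.

## Super-enhancers and broad domains

Enhancer peaks fully contained in TSS +/- 2 kb zones are treated as
promoters and removed (an any-overlap mode exists); the rest are stitched
when gaps are below 12.5 kb. Each stitched region is ranked by its summed
background-subtracted signal (floored at zero). On the rank-signal curve
scaled to the unit square, the cutoff is the point where a slope-1 line is
tangent to the curve, computed exactly as `argmax(x - y)` with ties broken
to the rightmost index; entries strictly to the right are super-enhancers.
For a convex ascending curve this equals the tangency point of the
continuous construction, and it is robust to step noise where numerical
differentiation is not. A degenerate all-equal or linear curve yields no
super-enhancers.

Broad H3K4me3 domains are the widest `ceiling(0.05 * N)` peaks (ties broken
by genomic order); a fixed minimum-width mode (for instance 4 kb) is
provided as an alternative definition.

## Contact matrices, compartments, boundaries

Cis pairs are binned per chromosome at 40 kb by default. ICE balancing
iteratively divides rows and columns by their marginal sums (normalised to
mean one over unmasked bins) until the coefficient of variation of the
unmasked row sums falls below 1e-4 or 100 iterations; the lowest 2% of bins
by coverage are masked. On a matrix of the form `b_i * b_j * T` with `T`
doubly balanced, the recovered weights are proportional to `b`.

Compartments follow the eigenvector convention: observed/expected by
diagonal (diagonals with no unmasked entry are skipped), Pearson
correlation matrix, leading eigenvector; the sign is oriented so bins
richer in a user-supplied orientation track (HOCIs or gene density) are
positive, and A is the positive sign. A flat matrix gives a zero vector
flagged unreliable rather than arbitrary labels.

The insulation score of a bin is the mean contact in the `w x w` square
crossing it (default `w = 10` bins), log2-normalised to its chromosome
mean; boundaries are local minima whose depth below the lower flanking
maximum exceeds `delta_threshold`. Boundary-HOCI enrichment uses circular
permutations in which each HOCI midpoint is rotated independently around
the chromosome; a single common rotation is not used because any offset
smaller than one matrix bin reproduces the observed statistic exactly,
which floors the attainable p-value at roughly bin/chromosome-length.

Insulation-score boundaries stand in for TAD calls throughout: the claims
the package evaluates are enrichment statements at boundaries, for which
insulation minima are the simplest well-defined construction.

## The synthetic-data generator

All tests run against `simulate_bundle()`, which plants ground truth at
every level. The standard conditions are two 5-Mb chromosomes of uniform
random sequence (MboI sites occur at their natural ~1/256 bp rate), 40
hubs in 8 groups of {2 promoter, 2 enhancer, 1 other}, 200,000 read pairs,
5% each of dangling-end, self-circle, same-strand and too-close artifacts
placed on real restriction fragments of the synthetic genome, 2% low-MAPQ
pairs, 5% trans pairs, and a background cis distance law P(d) ~ 1/d on
[2 kb, 4.5 Mb]. Within each group the promoter-promoter, enhancer-enhancer
and promoter-enhancer hub separations are drawn log-normally around 44 kb,
13 kb and 117 kb (tight 10% jitter), and 300 pairs are planted on each of
the three within-group edges, so the per-category distance medians are
recoverable quantities rather than emergent accidents. 500 genes are
planted as 20% hub (promoter windows overlapping promoter hubs), 40%
interacting (8 pairs each joining the promoter to a random hub) and 40%
dissociative, with log-normal expression medians 20 / 5 / 0.2 RPKM
(sdlog 1). H3K4me3 peaks sit on promoter hubs, H3K4me1 + H3K27ac on
enhancer hubs. Compartments are alternating 1-Mb blocks; cross-block
background contacts are thinned by 0.5 and hub groups land in A blocks
with probability 0.8. The background sampler anchors each pair uniformly
on the span that keeps both ends on the chromosome, so the marginal
distance law is exactly the configured power law (verified by a KS
round-trip in the tests).

Two generator choices are deliberate idealisations. First, pairs that
would link a dissociative gene's promoter to a hub (within a 5-kb halo)
are rejected during generation — otherwise, at 200k pairs, essentially
every "dissociative" promoter would acquire accidental hub contacts and
the planted label would be meaningless. Second, planted edge counts are
exact rather than Poisson draws, which makes edge-weight recovery testable
without distributional slack. The generator therefore emulates the data
model the analysis assumes — sharp interaction hubs over distance-decay
background with class-specific contact distances — but not several
features of real libraries: mappability and GC structure, copy-number
variation, chromatin-state-dependent background, ligation-junction
chimeras, or overdispersed (non-Poisson) coverage noise. Passing the
planted-recovery tests shows the algorithms are correct under their own
model, not that real data meet that model.

`two_condition_bundle()` enlarges the layout to 18 groups with two hub
genes per promoter hub and removes 25 promoter hubs in condition B (their
planted contacts and H3K4me3 marks vanish; their genes' expression drops
4-fold times log-normal noise, sdlog 0.15), yielding 50 planted hub-loss
genes while the gene models stay shared between conditions.

## Problem sizes and numerical choices

The shipped tests use the standard 200k-pair bundle (built once and shared
across test files), a 50k-pair bundle for distance-median recovery, 200 x
200 matrices for the ICE contract, and a 100-bin two-class block model
(within:between contact ratio 5:1, interleaved 10-bin blocks) for
compartment recovery; a strictly alternating single-bin checkerboard is
deliberately not used there because diagonal normalisation absorbs a
period-2 pattern completely. The whole suite runs in about a minute on one
CPU; `scripts/acceptance.R` recomputes the headline quantities from
scratch in about half a minute.

Smaller numerical decisions, collected: fragment ids are genome-wide
consecutive integers; BH ties are broken by genomic order; `rank_and_cut`
breaks argmax ties to the rightmost index (so a linear curve yields zero
super-enhancers); the entry at the tangent cutoff is itself not a
super-enhancer; broad-domain ties at the 5% boundary are resolved by
genomic order and the count is exactly `ceiling(0.05 N)`; ICE leaves zero
entries at zero and is scale-equivariant; a completely tied two-sample
comparison reports p = 1; empty distance categories are reported as absent
rather than zero.

## Known limitations

The peak caller's Poisson null is underdispersed for real sequencing data;
on real libraries the q-values are anti-conservative and the planted-hub
contract is the honest statement of what is guaranteed. Compartment calls
need contacts spanning the block structure — matrices whose maximum contact
distance is much shorter than the compartment period give unreliable
eigenvectors. The network module requires non-overlapping HOCIs (merged
peak calls satisfy this by construction; arbitrary user interval sets may
not). Chromosome include-lists are honoured at genome reading; scaffolds
absent from the assembly raise explicit errors rather than being silently
dropped.
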