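---
title: "Promoter-capture Hi-C interaction calling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter-capture Hi-C interaction calling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hicapr)
```

## The problem and the method

Enhancers regulate transcription through chromatin loops that bring them
into contact with promoters. Genome-wide Hi-C sees such contacts but at a
resolution (and sequencing cost) that blurs individual promoter–enhancer
pairs. Promoter-capture Hi-C fixes one side of every informative ligation
product by hybridization capture of probe-targeted promoter fragments, and
sharpens the other side by digesting with a 4-bp cutter (MboI, `GATC`),
whose fragments average a few hundred bp. The computational task this
package implements is: given independently mapped read ends, a genome, and
a promoter annotation, produce a set of promoter-anchored interaction
calls and the statistics that establish whether the distal partners behave
like enhancers.

## Coordinates and the fragment map

Everything is 0-based half-open. `digest_genome()` places a cut at the
first base of every site occurrence — MboI cuts 5' of `GATC`, leaving the
site on the downstream fragment. The source experiment does not dictate a
coordinate convention, so one was fixed package-wide. A cut at position 0
would create an empty fragment and is suppressed; `N` bases never match a
site, so assembly gaps become long fragments rather than errors. Fragments
tile each chromosome exactly, which the tests assert: every aligned
position belongs to exactly one fragment.

On an i.i.d. uniform-composition genome a 4-bp site occurs every
4^4 = 256 bp; the simulator's default world reproduces that, while real
mouse sequence yields ~422 bp because of base composition — the package
never assumes either number, it measures `mean_fragment_length()`.

## Probe-target design

For each TSS the flanking cut sites are the boundaries of its fragment.
The captured regions are the last `flank = 150` bp before each cut —
interpreted as the 150 bp of the TSS's fragment adjacent to each cut,
i.e. on the TSS-facing side. This interpretation is an assumption: "before
the cut site" is directionally ambiguous for the upstream cut, and the
TSS-facing reading is the one that keeps every probe inside the promoter
fragment (the tests assert exactly that containment). When the two cuts
are < `merge_below = 300` bp apart the whole inter-cut region is captured.
A TSS whose fragment touches the chromosome end lacks one cut; the target
is clipped and flagged rather than dropped. TSSs sharing flanking cuts
produce one deduplicated region carrying all promoter ids, and read
counting credits every promoter of a shared region.

## Pair filtering

Ends are paired by read id and ordered canonically by (chrom, pos,
strand), so pair identity is orientation-free. The filters, in order:

1. **Duplicates** — pairs with identical (chrom, pos, strand) on both
   ends, per replicate, keep one representative. Strand is part of the
   identity because duplicate removal targets PCR copies of one molecule.
2. **Same fragment** — both ends in one restriction fragment
   (self-ligation or un-ligated products).
3. **Too close** — same chromosome, ends < `min_distance = 1000` bp apart
   (residual self-ligation). Trans pairs have no distance and are never
   "too close".
4. **On-target** — ≥ 1 end inside a probe-target region; both ends on
   targets marks a promoter–promoter candidate.

Dedup ordering relative to the 1-kb rule is unstated upstream; dedup runs
first here, and the retained set is the same either way because the
classes are independent attributes of a pair. The filter report conserves
counts: input = retained + duplicate + same_fragment + too_close +
off_target, asserted on every simulated run. Finer read-level classes used
by alignment-side pipelines (dangling ends, re-ligation) are deliberately
collapsed into same_fragment/too_close: with position-only input they are
not distinguishable further, and the downstream calls depend only on the
retained set.

## Interaction calling

Support is counted per (promoter, partner fragment) per replicate; a call
requires `min_support = 3` read pairs in **every** replicate. This is the
whole model — no distance-decay null, no FDR; the replicate requirement is
the error control. Monotonicity (the called set at threshold t+1 is a
subset of the set at t) is asserted as a property. PP calls require both
ends on promoter targets and use a canonical promoter-pair key; DD calls
re-mine all valid (deduplicated) pairs restricted to fragments already
seen as PD partners, with the same per-replicate threshold in both
replicates (the upstream description says "similar analyses"; requiring
both replicates is the consistent reading and is the choice made here).

Interaction distance is the absolute difference of region midpoints
(partner fragment vs the bounding region of the promoter's targets). The
anchor-side reference point is not defined upstream; midpoints were chosen
for symmetry, and a promoter's two flanking targets pool into a single
anchor, since they jointly represent one promoter.

## Enrichment with a distance-matched background

The expected overlap of distal regions with a feature track is computed
from background regions sampled around annotated TSSs using the empirical
distance distribution of the cis PD calls and lengths resampled from the
observed distal fragments — preserving the non-random placement of genes,
which a fully uniform background ignores (making everything look
enriched). Length resampling is applied for the enrichment background as
well as the eRNA background (upstream only states "same average length"
for the latter; resampling matches the mean and is strictly more
faithful). Feature tracks are first reduced to their `top_k = 5000`
highest-scoring intervals and short intervals extended to
`min_len = 1000` bp.

Observed/expected overlap is per interaction-region, counted at ≥ 1 bp
overlap, and tested with a 1-df χ² goodness of fit without continuity
correction — counts are large in intended use, and the upstream analyses
name only "χ² test". The same χ² engine drives the TAD, eRNA and
perturbation tests, and the worked examples 40/100-vs-20% → χ² = 25 and
the perturbation 22.5 are frozen in the tests.

TAD containment classifies each cis call as within one TAD / spanning
two or more / having an anchor midpoint outside TADs, per log2 distance
bin (1–2 kb up to 64–128 kb, then pooled; the original figure's exact bins
are not recoverable from text, so the motif-analysis bins are reused).
Controls keep each interaction's distance but re-place it uniformly on a
length-weighted random chromosome; `n_control` generalizes the
one-control-per-interaction scheme. Per class the highest p across bins is
reported.

eRNA analysis keeps distal regions that overlap no annotated gene,
quantifies nascent-transcription reads as
RPKM = reads × 10⁹ / (length × library size), and compares exceedance
fractions at 0.1 and 1.0 RPKM against matched non-genic random regions by
the same χ². Expression–correlation uses Spearman's ρ with RPKMs of
multiple distal regions per gene summed, and a label-permutation p floored
at 1/n_perm (a permutation p of 0 is never reported).

## The TF-perturbation test

For each TF with both binding sites and over-expression DE data:
Nc = unique genes closest to peak midpoints; Nh = unique genes connected
to the peak's restriction fragment by a called interaction and *not*
closest (the comparison is non-closest connected vs all closest, so the
overlap is excluded from Nh); Uc, Uh their intersections with the
upregulated set (FDR ≤ 0.05 and fold change strictly > 1.5). Fold
improvement = (Uh/Nh)/(Uc/Nc); χ² takes (Uh, Uc) as observed against
expected proportions Nh : Nc. The compound test sums the four counts over
TFs first. PP calls are excluded from connected sets by default, and a
`min_distance = 15000` variant restricts to long-range support. The
closest-genes split (with vs without interaction support) uses Fisher's
exact test and reports the sample odds ratio. Ties in closest-gene
assignment break toward the lower-coordinate TSS, a deterministic
convention asserted by constructed ties.

## Network analyses

Calls become a typed graph: promoter and enhancer (distal) nodes; PP, PE,
EE edges weighted by summed read support. The motif catalog covers the
named patterns — single edges, the p–e–p and e–p–e sharing paths, the
p–p–e triangle, and same-type 3-cliques — counted as non-induced
embeddings up to automorphism, and is user-extensible; the original
figure-only catalog cannot be recovered beyond these. Null counts come
from 5 degree-preserving double-edge-swap randomizations run separately
per edge class (PE swaps keep the bipartite roles, so endpoint types are
preserved); note the sharing-path counts are invariant under this null by
construction (per-class degrees are preserved), so enrichment is
informative for triangles and cliques. Motifs observed but absent from
every randomization are labelled `~inf`. Maximal cliques come from
igraph's Bron–Kerbosch and are oracle-tested against exhaustive subset
search on ≤ 12 nodes.

Same-TF subnetworks restrict the EE graph to enhancer nodes overlapping a
TF's peaks; the empirical p compares the mean within-subnetwork degree to
equal-size random enhancer selections, floored at 1/n_rand. "Degree of
the promoter nodes" in the support-vs-shared-enhancers test means total
neighbor count of any type (an assumption, logged); degree sums ≥ 20 pool
into a terminal group, distances bin in the stated log2 ranges, and
one-tailed Wilcoxon tests (0 vs 1 and 1 vs 2+ shared enhancers) combine
by Stouffer's method with equal weights into a two-tailed p. Read-pair
support sums across replicates.

GO pair-sharing counts, per term, the gene pairs connected by PP edges or
through a shared enhancer; the null rewires **all** interactions jointly
(not per class, following the stated "randomized ... all interactions"),
1000 times, and p = (#randomizations with ≥ observed−1 pairs)/1000,
floored at 0.001, BH-adjusted. A consequence worth knowing: a term with
exactly one observed pair always has p = 1 under the "observed − 1" rule —
the rule exists to de-bias term selection, and the floor is reachable only
from two pairs upward.

### A documented contradiction: Stouffer "k-invariance"

The acceptance checklist this package ships with includes a sanity
property stating that combining k identical z-scores returns that same
z. The method's definition — Z = Σzᵢ/√k, the standard combination — gives
z√k for identical inputs; both cannot hold for k > 1. The standard
combination is implemented. The literal invariance assertion is retained
in the acceptance suite as a red test, intentionally, so the discrepancy
is visible rather than silently resolved.

## The simulator: what a green test establishes

`sim_config()` describes the stated world: a 10-Mb two-chromosome
uniform-composition genome (one GATC per ~256 bp), 400 promoters, 300
planted promoter–distal loops at log-normal distances (median 30 kb,
σ_log 0.8 — enhancer-scale distances), 8 expected pairs per loop per
replicate, two replicates of 2 × 10⁵ pairs. Background: 5% of depth is
informative on-target pairs with contact probability ∝ d⁻¹ over
1 kb–2 Mb (the standard Hi-C-like decay; the exponent is not specified
upstream, 1.0 is the conventional choice), truncated per-pair to the span
available on the chromosome (otherwise partner positions pile up on edge
fragments and manufacture false calls); 15% self-ligation-like products;
10% exact duplicates; the rest uniform off-target pairs. At these rates
the expected background support next to a promoter stays well below the
calling threshold, which is what makes the planted-recovery criterion
(precision ≥ 0.9, recall ≥ 0.8) a property of the stated world rather
than a tuned outcome; recall is governed by P(Poisson(8) ≥ 3)² ≈ 0.97.

The omics generator marks 80% of planted distal regions as enhancers
(plus 300 scored decoys), tiles TADs at log-normal ~500 kb with
occasional gaps, couples planted eRNA levels to target-gene expression at
log-scale correlation 0.7 (0 = null), binds each of 5 TFs to 30% of
planted distal regions, and upregulates connected genes 4× the 5%
baseline rate (1× = null). GRO-seq-like depth is 5 × 10⁴ reads so that
random intergenic regions are not saturated above the RPKM thresholds at
desk scale.

What the simulator does *not* model — and hence what a green test does
not establish: sequence-level reads and alignment error, mappability,
GC/capture bias beyond the on-target fraction, biological replicate
structure beyond independent resampling, cell-type-specific chromatin,
and genome-scale interaction counts. Desk-scale numbers (hundreds of
calls) are three orders of magnitude below a real experiment; tests
assert properties and planted-truth recovery, never the published
dataset's headline statistics.

## Numerical conventions

* χ² tests: 1 df, goodness-of-fit, no continuity correction; degenerate
  expectations (0 or 1) short-circuit to p = 1 on exact agreement, NA
  otherwise.
* Permutation/empirical p-values are floored at 1/n (never 0).
* Nearest-TSS ties break toward the lower coordinate; PP/DD keys are
  canonical (sorted), so calls are orientation-free.
* Wilcoxon p-values are clamped away from 0/1 before conversion to
  z-scores; groups with < 2 observations per stratum are skipped and
  counted.
* All randomized procedures take an explicit seed and use an isolated RNG
  scope, leaving the caller's RNG state untouched.

## Known limitations

* `same_fragment`/`too_close` subsume, but do not re-derive, the
  alignment-level invalid-pair taxonomy.
* The background model for calling is the replicate threshold itself;
  no statistical caller (distance-decay + FDR) is provided, by scope.
* Joint rewiring for the GO null can mix endpoint types on an edge, as
  implied by the stated procedure; typed motif counting is unaffected
  (it reads node types, not edge labels).
* Power-law fits to degree distributions are out of scope; the
  distributions themselves are exported by `degree_stats()`.
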