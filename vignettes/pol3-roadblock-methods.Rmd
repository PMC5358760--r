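---
title: "Methods: detecting Pol III units nested in Pol II genes and the roadblocks they create"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting Pol III units nested in Pol II genes and the roadblocks they create}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological problem

RNA polymerase III transcribes short units -- tRNA genes and tRNA-derived
SINEs such as MIRs -- some of which lie fully inside Pol II transcription
units, often within an intron and on either strand. When such a nested unit
is actively occupied by the Pol III machinery, the elongating Pol II
accumulates just before it: a *roadblock* to elongation, a form of
transcriptional interference acting in cis. Detecting these arrangements
from ChIP-seq is complicated by two things this package addresses head-on:

1. **Repetitive loci multi-map.** SINEs exist in many near-identical copies,
   so a large fraction of sequence tags over Pol III loci match several
   genomic locations and are discarded by naive unique-read pipelines --
   exactly at the loci of interest.
2. **Intragenic Pol II accumulations are ambiguous.** A pileup inside a gene
   body could also be an unannotated internal TSS. The elongation factors
   disambiguate: NELF marks promoter-proximal pausing only, so NELF at the
   pileup argues for a cryptic TSS, while its absence (with or without DSIF,
   which travels with elongating Pol II) supports a roadblock.

## Tag weighting

Each collapsed tag carries a multiplicity $c$ (times sequenced) and a match
list of $m$ exact genomic locations. The reference scheme assigns each match
the weight $c/m$; the optional EM scheme starts there and iteratively
redistributes each tag's weight proportionally to the local coverage
anchored by uniquely mapping tags within ±500 bp of each match (the tag's
own mass is excluded from its windows, ties fall back to the uniform split;
tolerance $10^{-6}$ on the largest per-location change, at most 100
iterations). Under both schemes the weights of a tag sum to $c$ exactly, so
the total assigned weight equals sequencing depth -- the conservation
property the test suite asserts to $10^{-9}$.

The uniform split is the reference semantics because it is the minimal rule
consistent with weighting by times-sequenced and genomic match count; EM is
exposed for users whose repeat families have informative unique flanks. On
zero-divergence families the two agree on family totals by construction.

Coverage is binned (default 10 bp), strand-collapsed, with each placement's
weight prorated over the bins it overlaps. Masses are converted to tag units
(mass × bin/tag length) and to tags-per-million for cross-library ratios.

## Occupancy scoring

A locus is scored $S = \log_2\!\frac{ip + p}{input + p}$ on per-million
normalized masses with pseudocount $p = 1$ normalized tag (configurable).
Scores are reported as percentages $100 \cdot \max(S, 0) / S_{ref}$ of a
reference locus (or of the maximum); depleted loci are floored at 0 because
a negative percentage of a reference occupancy has no meaning in this
display. Class means ("all Pol III-occupied loci", "SINEs only") average $S$
over loci at or above the occupancy threshold, default $S \ge 1$ (two-fold).
Peak confirmation re-scores externally supplied peaks from the weighted
tracks and keeps those with $S$ at or above the threshold; the semantics of
the threshold are deliberately configurable and documented rather than tuned
to reproduce any particular published count, which depended on external
track and annotation versions.

Two numerical notes. The per-million normalization makes $S$ invariant to
library size but *not* to the planted fold exactly: enrichment elsewhere in
the library dilutes the denominator slightly, and tags overhanging locus
edges attenuate small loci (about 10 % for a 150 bp locus at 36 bp tags).
Rank order across folds is unaffected, which is why the recovery tests
assert rank concordance and a 25 % tolerance on the fold itself.

## Nesting and roadblock detection

A peak is *nested* when fully contained in the host gene span minus a
250 bp promoter exclusion downstream of the TSS (so pausing peaks are never
counted); orientation is sense iff strands agree. Cross-confirmation accepts
a second dataset's peak whose summit lies within 200 bp (configurable) of
the event summit.

The roadblock window (default 200 bp) abuts the Pol III unit boundary
facing the host TSS -- the side first encountered by the travelling
polymerase, regardless of the nested unit's own orientation. Background is
the *median* Pol II bin signal over the gene body excluding the TSS ± 500 bp
and the window itself (median, not mean, so the TSS shoulder and other
pileups cannot inflate it). The fold is window mean over background; the
p-value is a Poisson upper tail on the window tag mass against the
background-scaled expectation, with Benjamini--Hochberg correction across
the events of a run. Zero background flags the call `unclassified` rather
than emitting an undefined fold. The Poisson treats bin masses as
independent tag counts after converting mass to tag units; at the package's
default bin and tag lengths this is slightly conservative-to-nominal -- the
200-event null calibration in the test suite observes an empirical type-I
error of about 0.04--0.05 at nominal 0.05.

NELF/DSIF classification compares the window's NELF mass with the
expectation under a uniform genome-wide spread of the NELF library
(enrichment threshold 2). Enrichment against the track's own uniform
expectation rather than against a gene-body background was chosen because
NELF tracks are near-empty outside TSSs, which would make a body-level
denominator degenerate.

## Promoter scanning

Type-2 Pol III internal promoters are scanned as all (A box, B box) pairs
on both strands where each box passes its threshold and the B box lies
downstream of the A box at a spacer within the configured range, boxes
non-overlapping. Defaults: consensus A box `TRGCNNARYNNG`, B box
`GTTCRANNC`, ≤ 2 mismatches per box, `N` in the subject never matches,
spacer 20--40 bp for general scanning and a strict-MIR preset of 25--26 bp.
The spacer is measured from the base after the A box to the base before the
B box (0-based half-open). Boxes may alternatively be given as PWMs with a
minimum score. The scanner is asserted equal to a naive brute-force pair
enumeration on random sequences; mutating more than the mismatch budget of
either box flips classification, mirroring promoter-disabling mutagenesis.

## Percent-identity neighbor joining

Distances are $100 - \text{identity}$ with identity computed under
`pairwise_deletion` (default: only columns where both sequences have
residues are compared) or `count_as_mismatch` (a single-gapped column
counts as a mismatch; doubly gapped columns are never compared). Branch
lengths are therefore in percent units. Neighbor joining follows the
standard $Q$ criterion with the usual split formula for branch lengths;
ties on $Q$ are broken toward the lowest-index pair so output is fully
deterministic, and negative branch lengths are clamped to zero with the
original values kept in the `clamped` attribute. On additive matrices the
algorithm recovers the generating topology and branch lengths exactly
(asserted to $10^{-9}$ over random 4--8-taxon trees, and against exhaustive
least-squares over all 15 unrooted 5-taxon topologies). The default gap
rule is a package choice: tools differ in their gap treatment for "percent
identity", and equivalence with any specific viewer is not asserted.

## The synthetic-data generator

Every analysis stage is validated against generated genomes with planted
ground truth, because the genome-scale inputs of a real analysis (public
ChIP tracks, annotation builds) are neither small nor stable enough to pin
tests to. The generator plants, on random background sequence:

* repeat families copied from a consensus with substitution-only divergence
  (so exact-string mapping stays well defined), each copy mutated
  independently -- at zero divergence multi-mapping is exact and complete;
* Pol II gene models: uniform body density, a 200 bp TSS pausing peak at a
  configurable fold (default 10), oriented by strand;
* Pol III units with an IP enrichment fold over a uniform input;
* roadblock pileups of configurable fold and width (default 200 bp) abutting
  a nested unit's TSS-facing boundary, optionally with co-planted NELF
  signal to emulate an internal TSS;
* NELF (TSS peaks only) and DSIF (TSS peaks plus pileups) tracks.

Tags are single-end, fixed length (default 36 bp -- the original read
length of the re-analysed tracks is not recorded anywhere usable, so this
is an arbitrary, configurable choice), drawn from the piecewise density,
then mapped back to *all* exact matches on both strands and collapsed into
multiplicities. Identical spec + seed reproduces everything bit-exactly;
per-track sub-seeds are derived arithmetically from the base seed.

What the generator does **not** emulate: sequencing errors, indel
divergence, paired ends, mappability biases, fragment-length effects,
chromatin accessibility background, or realistic genome-scale repeat
landscapes. Passing tests therefore demonstrate the correctness of the
computational procedure under its stated model, not performance on real
libraries, where mapping software, duplicates and batch effects add noise
upstream of this package's inputs.

## Standard study designs and problem sizes

The shipped designs (`example_genome_spec()`) fix the conditions used
throughout the tests and the acceptance script: ten 8 kb genes hosting one
150 bp unit each (IP fold 8, alternating orientation) with fold-3, 200 bp
pileups for the funnel (depth $10^5$, body level ≈ 1 tag/bp); a matched
no-pileup null; a 200-event design for type-I calibration (depth
$2 \times 10^5$); four units at folds 1/2/4/8 for occupancy recovery; and a
3-copy zero-divergence 300 bp family in 60 kb for multi-mapper recovery.
These sizes give comfortable statistical resolution for the planted effects
(a fold-3 pileup over a 20-bin window at ~10 tags/bin is a ~20σ signal)
while keeping any single simulation under ~10 seconds.

## Known limitations

* Exact-match mapping means read-length changes alter the multi-mapping
  structure; the weighting, not the matching, is the transferable part.
* The Poisson window test ignores overdispersion of real ChIP coverage;
  on real data the q-values should be read as a ranking with an
  approximate error rate, and the NELF/DSIF logic as a filter.
* Percentage normalization is relative to a chosen reference; with an
  ambiguous reference convention ("the element" vs "the genome-wide
  maximum"), both are supported and the choice is the caller's.
* The funnel reproduces published-style stage counts only on synthetic
  manifests; re-deriving genome-scale counts requires the original external
  tracks and annotation versions, which is out of scope.
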