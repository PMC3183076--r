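---
title: "Calling meiotic recombination intermediates from octad genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling meiotic recombination intermediates from octad genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meihdna)
```

## The measurement model

A cross between two polymorphic yeast isolates gives a hybrid whose meiotic
products can be genotyped at every marker distinguishing the parents. In a
mismatch-repair deficient (*msh2*) meiosis, heteroduplex DNA (hDNA) formed
during recombination is not repaired; when the mother and daughter cell of
each spore's first mitotic division are separated and genotyped, the eight
cell populations report the parental origin of each of the eight DNA strands
of the four chromatids. The package's octad convention orders the cells
`s1m, s1d, s2m, s2d, s3m, s3d, s4m, s4d`, so columns `2k-1` and `2k` are the
two strands of chromatid `k`; a call of 1 is the parent-1 (S288C) allele and
0 the parent-2 (SK1) allele. Coordinates are 1-based inclusive bp.

At one marker the possible states are:

* **4:4** — Mendelian: four strands per parent, each chromatid homoduplex;
* **5:3 / 3:5** — half conversion: one chromatid heteroduplex
  (mother ≠ daughter), the signature of unrepaired hDNA;
* **6:2 / 2:6** — full conversion: one chromatid homoduplex for the other
  parent (gap repair, or repair-independent conversion);
* **aberrant 4:4 (`4:4*`)** — balanced ratio but two heteroduplex chromatids
  with opposite minorities: symmetric hDNA from Holliday-junction branch
  migration;
* **8:0 (4:0 chromatid-wise)** — a mitotic event prior to meiosis, excluded.

In wild-type (repair-proficient) mode the four spore genotypes carry the
repaired outcomes: 3:1 conversions and 2:2 Mendelian segments, with stars
marking equal-ratio segments of different spore distribution.

## From markers to events

1. **Segregation calls.** Each marker's ordered cell vector gives a ratio
   (parent-1 count first), the set of heteroduplex chromatids, and the full
   signature. Markers with missing calls beyond the tolerance
   (`caller_params()$max_missing`, default 0) or with 4:0 chromatid ratios
   are excluded and are transparent to everything downstream.
2. **Tracts.** Maximal runs of markers with *identical signatures* — not
   merely identical ratios — form tracts. The signature, rather than the
   ratio, defines boundaries because two adjacent hDNA tracts with the same
   global asymmetry but different strand distributions (`5:3_5:3*`) are the
   diagnostic of trans hDNA and must not be fused.
3. **Phase.** Background (Mendelian, homoduplex) tracts define a
   piecewise-constant chromatid-to-parent assignment. Each junction between
   different flanking phases is a candidate crossover; its position is the
   midpoint between the last Mendelian marker on the left and the first on
   the right.
4. **Events.** Every junction becomes a crossover absorbing the
   non-Mendelian tracts between its flanking backgrounds; remaining
   non-Mendelian clusters become non-crossovers. Events whose outermost
   affected markers are closer than 5 kb are combined as products of one
   DSB, *except* a conversion on a chromatid not involved in the nearby
   crossover, which remains separate. Non-crossovers supported by fewer than
   2 markers are discarded. Interior Mendelian stretches between merged
   tracts enter the pattern as `4:4` (or `2:2`) tokens.
5. **Lengths.** Tract and event lengths use the midpoints of the flanking
   inter-marker intervals; an event's strand-transfer length is the span
   from the midpoint before its first affected marker to the midpoint after
   its last, i.e. the sum of its constituent 5:3, 6:2 and 4:4 patches. At a
   chromosome end the estimate falls back to the terminal marker.

### Design choices made where the procedure was open

* **Kind by net phase change.** A merged event is a crossover only when the
  phases flanking the whole event differ. A short phase-swapped Mendelian
  patch flanked by identical phase (two reciprocal junctions within the
  merge distance) is therefore one non-crossover, rendered with a starred
  Mendelian token — this is the only reading consistent with the published
  wild-type NCO inventory, which contains `3:1_2:2*`-type patterns.
* **Merge distance between boundaries.** The 5 kb rule is measured between
  outermost affected marker positions, the conservative reading of
  "separated by".
* **Phase reference at junctions.** A tract lying at a crossover junction
  could be compared against either flanking phase; the side implying the
  fewer changed chromatids is used (ties go left). Without this, hDNA on the
  exchanged arm would be misattributed as an extra converted chromatid.
* **Octads are processed natively as eight strands**; the two-arbitrary-
  tetrads route is available as `octad_to_tetrads()` for compatibility.
* **Star assignment.** Within one event, the first distinct signature per
  ratio class is unstarred and each later distinct signature gains a star;
  aberrant balanced tracts always render `4:4*`. Printed tables mix parental
  orientations, so comparisons go through `canonicalize_pattern()`, which
  swaps every token so the first unbalanced token has its smaller count
  first.
* **Events touching three or more chromatids** are kept, summarised as
  `multi`, and routed to the `other` classes.

## Mechanistic classification

`classify_nco()` is rule-based: SDSA-like requires a single chromatid,
half-conversion terminals, one asymmetry direction, and a single
half-conversion distribution (canonical when the pattern is exactly one
tract); trans requires exactly two half-conversion distributions of one
direction (canonical when exactly `X_X*`); interior full conversions must
match the half-conversion direction; everything else — aberrant `4:4*`,
terminal full conversions, opposite directions, multi-chromatid — is
`other`. Trans is tested before SDSA so ties are deterministic. Three rows
of the shipped `other` inventory satisfy the SDSA/trans pattern rules yet
were curated as `other` in print; the fixtures carry the printed class so
both views are testable, and the classifier follows its stated rules.

`classify_co()` separates transfer-less crossovers, single-chromatid
transfers, and two-non-sister transfers; the latter are DSBR-compatible when
the transfers on the two chromatids do not overlap (overlap implies
symmetric hDNA), and flagged asymmetric when the longer/shorter hDNA length
ratio reaches 3 (configurable; the source material says only "clearly
asymmetric").

## The simulator

`simulate_meiosis()` writes strand states onto an 8 × markers matrix per
chromosome and logs every action. DSBs are Poisson in number (default mean
160 per meiosis), placed uniformly with a 10 kb exclusion distance
(re-drawn closer than that; the exclusion keeps truth events resolvable and
is well below typical inter-DSB spacing at this rate). The broken chromatid
is uniform on the four; the donor is a non-sister chromatid whose local
haplotype differs from the broken one's — repair between locally identical
sequences leaves no marker footprint and is logged as invisible.

Pathway write rules (donor allele `D`, recipient allele `R`, break at `x`):

* *simple SDSA*: one strand of the broken chromatid takes `D` over one
  side of `x`; the invading-end hDNA on the other side is transient —
  recorded but not written, visible only through mismatch repair;
* *double SDSA / dHJ dissolution*: opposite strands of the broken chromatid
  take `D` over the two sides of `x` (trans configuration); dissolution
  inserts a central restoration patch with probability `p_nick` (nick
  translation), double SDSA with probability `p_switch` (sister-first
  template switch);
* *dHJ resolution (NCO)*: on the invasion side the broken chromatid takes
  `D` on both strands and the donor takes `R` on one strand; on the capture
  side the broken chromatid takes `D` on one strand. Strand counting shows
  this yields two 5:3 tracts of the same global asymmetry on the two
  non-sister chromatids, the stated outcome of the canonical model;
* *dHJ resolution (CO) / nicked-HJ crossover*: arms distal to `x` are
  exchanged between broken and donor chromatid, then one strand of the
  broken chromatid takes `D` left of `x` and one strand of the donor takes
  `D` right of `x` — again two same-direction 5:3 tracts on the two
  recombinant chromatids.

Optional variants: complete D-loop erasure of the first-end hDNA
(`p_dloop_erase`), double-stranded gap conversions (`p_gap`), asymmetric
DSBR hDNA lengths (`p_asym`, ratio `asym_ratio`), junction branch migration
writing symmetric hDNA over `branch_len` bp (default 260 bp, the typical
inter-junction distance of visualised dHJs), inversion of a crossover hDNA
tract to the opposite direction (`p_invert`, default 0 as no frequency is
reported), inter-sister thinning (`p_sister`), and injected 4:0 mitotic
artifacts (`mito_rate`). `complications = FALSE` zeroes all of them.

**Parameter defaults and why.** Marker spacing 194 bp and 160 DSBs per
meiosis are the study conditions. Tract lengths are log-normal
(`len_sdlog = 0.7`) parameterised by median — only medians are reported, and
a positive right-skewed family matches the observed excess of short tracts —
with medians 1600 bp (crossover-associated) and 1000 bp
(non-crossover-associated) in *msh2* mode; the transient invading-end hDNA
median is set to 800 bp so that wild-type conversion tracts, which add the
converted transient segment, lengthen toward the reported 1.8 kb. The
pathway mix (`0.22/0.09/0.14/0.05/0.40/0.10` over simple SDSA, double SDSA,
dissolution, resolution-NCO, resolution-CO, nicked-HJ) puts crossovers and
non-crossovers near parity and reproduces the observed NCO class balance
(≈44% SDSA-like, ≈46% trans with dissolution favoured over double SDSA,
resolution a minor contributor). `p_nick = 0.5` matches the roughly half of
trans patterns that carry a central restoration patch; `p_switch = 0.1` is
the reported template-switch frequency; `p_dloop_erase = 0.75` yields the
observed preponderance of single-chromatid crossover transfers;
`p_asym = 0.68` reflects the 13/19 DSBR-compatible events with clearly
asymmetric tracts; `p_conv = 0.8` (wild type) favours conversion, consistent
with the dominance of uniform 3:1 tracts in repaired meioses.

**Mismatch repair.** `apply_mmr()` converts each hDNA tract — including
transient ones — with probability `p_conv` (both strands take the
transferred allele) or restores it, leaving homoduplex chromatids whose
genotype is the spore genotype. Restoration of a transient tract is a
no-op; conversion writes the donor allele, which is how wild-type
conversion tracts come to span both sides of the break.

**What the generator does not emulate.** Real marker density is locally
irregular (repeat-rich regions lack markers entirely); hybridisation noise,
heterozygous colony calls in wild-type mode, and chromatid interference are
absent; DSBs have no hotspot structure unless sizes are varied; partial
D-loop erasure and multi-event chromatids closer than the exclusion distance
are not generated. Passing recovery tests therefore demonstrate the caller's
correctness on clean strand-level data, not robustness to array noise.

## Numerical choices and degenerate inputs

Probabilities must sum to 1 within 1e-9; tract draws are floored at 50 bp;
an empty genotype table returns empty results without error; a chromosome
with no Mendelian background raises a phase-undefined error and is skipped
with a log entry by the genome-wide caller; a mean marker spacing at or
above the chromosome size is a degenerate-map error. The exact rank-sum path
enumerates all assignments when the smaller sample has at most 8
observations (ties via mid-ranks); beyond that a tie-corrected,
continuity-corrected normal approximation is used, which coincides with the
standard reference implementation; at the boundary size its p-values are
typically within 0.01 of exact and can deviate by a few hundredths in the
extreme tails, which is why the exact path is preferred for small samples.

## Problem sizes used in the tests

The validation suites run the study's densities on a reduced genome — four
250 kb chromosomes, ≈5100 markers, DSB rate scaled to the genome (≈13 per
meiosis) — over 50 seeds for the recovery, equivalence and determinism
properties, which keeps each suite to a few seconds while exercising several
hundred events. The worked example in the README uses the same
configuration.

## Limitations

Classification of two-non-sister crossovers from fixture rows (patterns
without tract geometry) cannot assess overlap or asymmetry beyond what the
pattern implies; phase-swap versus aberrant-hDNA `4:4*` tokens are
typographically identical in octad mode (both are starred balanced tokens),
matching the printed notation but requiring the signature to disambiguate
programmatically; and wild-type mode treats spore calls as strictly 0/1,
ignoring the mixed-colony heterozygosity that whole-colony genotyping can
produce.
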