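---
title: "Promoter-guided insertion-site design: models and methods"
author: "iprdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter-guided insertion-site design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iprdesign)
```

## The design problem

A phage payload (a reporter such as nanoluciferase, or an effector) is only
useful if the phage's own transcriptional machinery expresses it at a
worthwhile level and time during infection. Phage genomes are dense: almost
everything is coding sequence, essentiality is largely unannotated, and
transcription is organized into temporal blocks (early, middle, late genes).
`iprdesign` operationalizes a simple, auditable strategy: put the payload
immediately downstream of a native gene that sits just after a region dense
in strong predicted promoters, and deliver it by homologous recombination
with a donor whose design provably disturbs nothing else.

## Coordinate model and the intergenic search space

Internally every interval is 0-based half-open; GenBank and GFF3 are
converted at the boundary (1-based inclusive) and BED stays 0-based. This
makes widths `end - start` and abutment `end == start` exact, with no ±1
bookkeeping inside the algorithms.

Gene bodies come from the record's CDS features. Two normalization rules
precede intergenic extraction:

* **Split loci are merged.** A gene annotated in several parts — typically a
  locus interrupted by an intron-encoded homing endonuclease, with other
  genes nested between the parts — is collapsed to the hull of its parts.
  Genes wholly nested inside the merged span are kept as annotation but
  flagged *interior*: they create no intergenic boundary and therefore no
  insertion site can be proposed between the parts. A gene only partially
  overlapping the merged span does break intergenic space; nesting is the
  only configuration treated as interior, because that is the configuration
  in which an apparent "gap" is actually the inside of a functional locus.
* **Overlapping genes are unioned.** Phage annotations commonly overlap by a
  few bases; the coverage union defines the occupied space, and no error is
  raised.

Core intergenic spans are the maximal intervals not covered by any
non-interior gene body. The terminal spans before the first and after the
last gene are included for linear genomes: promoter elements near the
physical ends of the genome are real candidates. Abutting (but
non-overlapping) genes leave a **zero-width core**: the boundary is still a
legal search point once extended. Zero-width *terminal* spans are dropped as
vacuous. A boundary sweep over the sorted genes computes this directly; a
per-base coverage-mask oracle in the test suite confirms that the
positive-width cores are exactly the complement of the gene coverage. For
circular genomes (off by default; the topology is read from the LOCUS line)
the wrap-around gap is reported as a single region whose coordinates
continue past the sequence end.

Each core is extended `extension_bp` bases (default **50 bp**) into the
flanking genes, clamped to the genome bounds, because promoters frequently
overlap coding-sequence ends. The extension bounds how far into any
flanking gene a promoter may reach and still be credited to the region.

## Promoter scores and the exponential weighting

Predictions carry a probability-like score $s \in [0,1]$ from an external
predictor, ingested from a delimited table (tab or comma separated, header
auto-detected, documented column order strand / 1-based position / type /
sequence / score). Minus-strand positions are counted on the
reverse-complement frame and reflected into forward coordinates at parse
time, so all downstream interval logic is strand-agnostic. Scores below the
run threshold (default **0.5**, matching the predictor settings the defaults
mirror) are dropped *before* weighting; rows with scores outside $[0,1]$ are
rejected with a warning, and out-of-bounds footprints are errors.

The cumulative score of an Intergenic Promoter Region (IPR) — the
strand-partitioned set of predictions inside one extended region — is

$$\mathrm{IPR} = \sum_i e^{s_i}.$$

The exponential is the weighting: strictly increasing, convex, and equal to
1 at $s = 0$, it lets a few near-maximal promoters dominate many mediocre
ones while never zeroing any kept prediction. The function is pinned by a
worked anchor: a single-member IPR with $s = 0.921$ must score
$e^{0.921} = 2.51$ (2 dp), which the test suite asserts. Scoring is
per-strand; promoters on opposite strands of the same region form two IPRs
that compete independently in the ranking, since they drive different
downstream genes.

Two clustering knobs are deliberately conservative: the region itself is the
cluster (one IPR per region and strand), with an optional maximal
intra-cluster gap (`max_member_gap`, default off) that splits a region's
members where consecutive footprints are farther apart than the given
distance. A prediction whose footprint straddles two extended regions —
possible because extensions may overlap across a short gene — is assigned to
the region containing its footprint midpoint, with a logged message.

## The built-in σ70 scanner

So the pipeline runs without any external tool, a two-box position-weight-
matrix model of the bacterial σ70 promoter is included: −35 box `TTGACA`,
−10 box `TATAAT`, spacer 15–21 bp, consensus base probability 0.85 per
column against a uniform background. Every (position, spacer) pair on both
strands is scored by summed log-odds and mapped through a logistic
$1/(1 + e^{-(x - 7)/1.1})$ to $[0,1]$, calibrated so the exact consensus
scores above 0.999 and random sequence below 0.1 — commensurate with the
probability-like external scores the rest of the pipeline expects. The
scanner is deterministic, strand-symmetric (scanning the reverse complement
mirrors every hit with an identical score), and validated against an
exhaustive position-pair rescan in the tests. It is a consensus model, not a
trained predictor: it recovers planted consensus sites and obvious
σ70-like signals, and is not expected to match a machine-learning
predictor's sensitivity on real genomes.

## Site selection

IPRs are ranked by score, ties broken by smaller span start for
determinism. For each IPR in rank order, the first gene whose 5′ boundary
lies at or after the IPR hull *in the IPR's reading direction*, on the same
strand, is the expression proxy; the insertion point is immediately past its
stop (the gene's `end` on +, its `start` on −). The 5′-boundary test is
taken against the hull start (not end) because the extended region — and
hence the hull — may already overlap the first gene's 5′ end. IPRs with no
same-orientation downstream gene are skipped, and a gene claimed by a
higher-ranked IPR is not selected twice. No distance cap is applied by
default (`max_site_distance = Inf`): the first same-strand gene is the
proximal one in almost every real layout, and a cap is available where
annotation gaps make "first" unreasonably far.

When a temporal-class table is supplied (an *input*, typically derived from
published mRNA-seq time courses; the package never computes classes from
expression data), the top `per_class_sites` (default 1) sites are returned
per class, diversifying the designs across the infection cycle; otherwise
the global `top_n_sites` are returned.

## Donor construction and the RBS-preservation rule

A donor is `left arm + oriented cassette (+ duplicated context) + right
arm`. Arms start at `arm_max` = **400 bp** and shrink toward `arm_min` =
**200 bp** when the window would run off the genome (an error below 200), or
— best effort, with a warning when impossible — when the arm would fully
contain a gene whose product annotation matches the configurable keywords
`hypothetical`/`unknown`: full-length genes of unknown function are avoided
inside cloning intermediates because their products may be toxic to the
cloning host.

When the intergenic distance $d$ between the selected gene's stop and the
next gene's start (in reading direction) is below `rbs_window_bp` =
**20 bp**, inserting the cassette would separate the downstream gene from
its ribosome-binding context. The donor therefore appends the last
$20 - d$ bases of the selected gene after the cassette, restoring a full
20 bp of native sequence upstream of the downstream gene. The trigger
distance is 20 bp; the duplicated length $20 - d$ is this package's
quantification of "the required bases" (exactly enough to rebuild a 20 bp
window), asserted in the tests by bit-identity of the downstream gene's
20 bp upstream context before and after the edit.

`apply_edit_in_silico()` is the verification mirror of the recombination:
arms are checked base-by-base against the reference (first mismatching
offset reported), the insert is spliced in, downstream annotations are
shifted, and the payload is annotated. Tests assert the conservation
properties that make the design safe: every native CDS is retrievable
verbatim from the recombinant, and designing on the reverse-complemented
genome yields exactly the reverse complement of the forward donor.

## The synthetic-data generator

`simulate_genome()` emulates the statistical structure the pipeline
assumes: a genome of non-overlapping genes (lengths 600–1200 bp, gaps
150–300 bp, GC 0.35 — typical staphylococcal-phage figures) with consensus
σ70 motifs planted into chosen intergenic regions and a matching prediction
table whose scores are drawn per cluster from a normal clamped to $[0,1]$
(the clamp reproduces the pile-up of maximal scores that trained predictors
show). Temporal classes are assigned by thirds of the gene-occupied span —
the feasibility rule (the maximal layout must fit) leaves slack after the
last gene, so thirds of the raw length could leave the late third empty of
genes; the span-based split keeps the intended early/middle/late block
structure. All randomness flows from one seed through an isolated RNG
scope, so identical configs are byte-identical and the caller's RNG stream
is untouched.

What the generator does *not* emulate — realistic codon statistics, operonic
structure, promoter/terminator interplay, predictor noise correlated with
sequence context — bounds what passing tests show: they validate the
interval arithmetic, scoring, ranking, selection and donor construction
exactly, and the recovery of planted signal statistically, but they say
nothing about the sensitivity of any particular external predictor on a
real genome.

The demonstration configuration (`demo_sim_config()`) plants three clusters
of decreasing density and score — 5 promoters at mean 0.95, 4 at 0.8, 3 at
0.6, in regions 2, 7 and 12 of a 20 kb, 12-gene genome — one per temporal
third. Under the default 0.5 threshold the weakest cluster usually keeps
only its strongest members, which is the intended behavior, not an
artifact. A 200-seed run asserting that the densest cluster ranks first at
least 95% of the time is part of the acceptance suite; with these
parameters the expected cumulative weights (≈12.9 vs ≈8.9 vs ≈5.5) separate
the clusters far beyond the draw noise.

## Numerical and degenerate-input choices

* Weighted sums are plain double summation; region scores involve at most
  hundreds of terms, so no compensated summation is needed.
* Ranking ties break on span start; all orderings in output files are fully
  deterministic, making repeated runs byte-identical (the GenBank writer
  uses a fixed LOCUS date for the same reason).
* Zero-width cores are legal and carry the full 2·E extension; regions with
  no predictions produce no IPR; an annotation tiling the whole genome
  produces an empty region set, not an error.
* `N` bases are allowed in sequences; PWM windows containing `N` score
  −∞ and can never pass a threshold.
* Problem sizes in the test suite (toy genomes ≤50 kb, ≤40 genes; 200-fold
  replication for the statistical checks) were chosen as the smallest sizes
  at which the interval logic exercises all its edge cases and the
  statistical assertions have negligible flake probability.

## Known limitations

* The score a predictor emits is a proxy for promoter strength; the
  pipeline ranks by it but cannot model transcription-factor context, RNA
  secondary structure, promoter bidirectionality, or additive effects of
  multiple IPRs upstream of one gene — the ranking is per-IPR by design.
* Temporal classes are consumed, never inferred.
* Only single-record genomes are handled; donor output is a linear
  fragment (plasmid backbone assembly and primer design are out of scope).
* The GenBank reader covers the feature subset the pipeline consumes (CDS/
  gene features, join/complement locations, common qualifiers); it is not a
  general-purpose GenBank parser.
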