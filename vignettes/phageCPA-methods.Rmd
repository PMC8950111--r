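---
title: "Methods: characterizing fast-propagating white-plaque clones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing fast-propagating white-plaque clones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageCPA)
```

## Background and model

M13KE, the cloning vector behind the Ph.D. random peptide libraries,
carries a lacZα cassette inserted near the phage origin of replication
(Ori), so library clones form blue plaques on IPTG/X-gal plates. A clone
that loses the lacZα region forms white plaques, and because the insertion
burdens replication, losing it can confer a propagation advantage: during
the amplification steps of biopanning such a clone enriches independently
of target binding, and whatever peptide it happens to display behaves as a
propagation-related target-unrelated peptide (Pr-TUP). `phageCPA`
implements the computational side of diagnosing this situation. Three
independent lines of evidence are modeled:

1. **Provenance.** White plaques could also be environmental M13
   contamination. WT-M13KE differs from WT-M13 at a handful of signature
   nucleotides; in the region a single Sanger read can cover (M13KE
   1130–1680) there are five: 1610:G, 1613:A, 1631:G, 1634:C, 1662:T.
   Observing the M13KE bases in a white plaque places its origin in the
   library.
2. **Genotype.** Comparing the assembled white-clone genome with the
   reference exposes a single large deletion; its position relative to
   Ori, lacZα and gII explains the white phenotype and the replication
   benefit.
3. **Phenotype.** A competitive propagation assay (CPA) — co-amplifying
   the white clone with the naïve library in one culture and sampling over
   time — measures the propagation advantage directly, either by
   white/blue plaque counts or by deep sequencing of the displayed-peptide
   region.

## Coordinates and the genome model

All coordinates are 1-based inclusive, matching standard phage genome
numbering. `m13keGenomeModel()` fixes the geometry used throughout:
a 7222-nt genome, Ori at 5487–5867, lacZα at 6216–6695, the intergenic
region between them, and gII starting at 6821. The gII start is derived
from documented spacing (the recurrent deletion ends at 6705, 115 nt
before gII: 6705 + 115 + 1 = 6821) rather than from an annotation file,
and the feature is extended to the genome end; only its start coordinate
is ever used for distance computations.

WT-M13 and WT-M13KE numbering differ by one from position 1565 on (M13KE
lacks the T that M13 carries there). `m13ToM13keCoord()` treats 1565 as a
WT-M13 coordinate with no M13KE image (`NA`); positions below map to
themselves and positions above shift down by one. The map is strictly
increasing and injective over its defined domain.

`featureDistance()` reports the gap (nucleotides strictly between two
intervals, 0 when they touch) and a relation tag. `contains` requires the
query to extend beyond the feature on at least one side; two identical
intervals report `overlaps`, since neither strictly contains the other.
The gap itself is delegated to `IRanges::distance()`.

The genome sequence is an optional slot: every coordinate-level result
(offsets, deletion annotation) is independent of sequence content, so the
model is usable without redistributing the vendor's M13KE sequence. The
synthetic generator supplies a random sequence with the true coordinates.

## Read filtering and peptide frequencies

The displayed-peptide amplicon contains a 21-nt variable region (the
7-mer peptide) followed by a 12-nt Gly-Gly-Gly-Ser linker. A read is
**clean** iff the peptide region translates to seven canonical amino acids
and the linker region translates exactly to `GGGS`. Rejections are
reported as the first failing check in the order `too_short` (the read
cannot cover peptide + linker), `stop_in_peptide`, `invalid_aa_in_peptide`
(a codon containing N), `bad_linker`. Quality scores are parsed but
ignored: the filter acts on translation validity only.

Two deliberate interpretations, both configurable on `ReadLayout`:

* **Linker validity is judged at the amino-acid level** (any synonymous
  codons accepted), because the rule is stated on translated output. A
  strict-nucleotide mode (`linkerMode = "nucleotide"`) is provided since
  the original analysis script may have required one exact sequence; on
  data produced from a single clone per linker sequence the two modes
  agree.
* **The peptide offset within the read is explicit configuration**
  (default 12, matching the synthetic amplicon): the real amplicon
  architecture of a given sequencing design must be supplied by the user.

Relative abundance of a clone is `100 × count / clean_total`. Percentages
and ratios are reported half-up to one decimal everywhere
(`roundHalfUp()`), matching how titration tables are conventionally
printed; `base::round()`'s round-half-even would differ on exact ties.

Frequency tables iterate in descending count order with ties broken
lexicographically by peptide, making outputs deterministic.

## Competitive propagation summaries

For plaque counts, each time point yields the white/blue titer ratio
(undefined when no blue plaques are seen) and the percent of white
plaques, `100·white/(white+blue)`. The percent and ratio columns are
mutually consistent by construction: `percent/(100−percent)` equals the
ratio up to rounding. For NGS, the focal clone's percentage is its
relative abundance among clean reads at each time point.

`relativeFitness()` is a convenience statistic, not part of the published
assay: for consecutive time points with focal frequencies strictly inside
(0, 1), `s = [logit(f₂) − logit(f₁)]/(t₂ − t₁)` per minute. Under
logistic competition s is the selection coefficient; it is 0 for a stable
mixture, positive when the focal clone out-propagates the pool, and
antisymmetric under swapping focal and background. Intervals with a
frequency at exactly 0% or 100% yield `NA` rather than ±∞.

Plaque counts outside the reliable 50–300 window are flagged with a
warning, not an error, in `titerPfuPerMl()`.

## Provenance thresholds

The published analysis aligned eight Sanger reads visually; no numeric
rule is stated. The package's rule — `library` needs all covered signature
positions matching **and** at least 3 of 5 covered; `non_library` needs at
least 2 covered mismatches; anything else is `ambiguous` — is this
package's own calibration, chosen so a single Sanger miscall can never
flip a call between `library` and `non_library` (it lands in
`ambiguous`), and so short reads covering fewer than 3 positions never
give a confident `library` verdict. The WT-M13 bases at the signature
positions are not required: non-library origin is inferred from mismatch
to M13KE, not from match to M13, so the model carries them as optional.

Queries are placed by caller-supplied coordinate (or by exact anchor
search for peptide extraction); no general aligner is embedded. Minus
-strand queries are reverse-complemented internally and yield identical
calls.

## Deletion calling

Raw whole-genome sequencing reads are not required: the reproduced result
is a breakpoint interval, fully determined by the assembled sequences.
`callSingleDeletion()` computes the longest common prefix P and suffix S
of reference and mutant; a single contiguous deletion exists iff
`P + S ≥ |mutant|`. Among the (possibly several, when the breakpoint has
micro-homology) valid placements, the call is **left-aligned** — the
smallest start, the VCF convention — making calls deterministic;
`homology_len = P + S − |mutant|` when positive. Every call is verified by
reconstruction (excising the interval from the reference must reproduce
the mutant); sequences that differ by anything other than one contiguous
deletion raise a structured `complex_variant` error, and equal-length
inputs raise `no_indel`. The test suite checks the caller against an
independent brute-force oracle that enumerates every valid excision.

Annotation reports each model feature's relation and distance to the call
plus the genome fraction removed (`100 × length / genome length`, one
decimal).

## Quantitation arithmetic

`genomeCopiesPerUl()` evaluates
`gc/µL = (g/µL) / (bp × 607.4 + 157.9) × 6.02×10²³` exactly as printed
(607.4 g/mol/bp with a 157.9 g/mol end correction; the Avogadro constant
at the 3-digit precision the formula uses). The serial-dilution factor is
applied by the caller *after* the formula — where it enters is not
specified by the source protocol, and applying it outside keeps the
function a pure unit conversion. The plated volume in
`titerPfuPerMl()` defaults to 0.01 mL (10 µL), explicit configuration
since titer protocols vary. The qPCR standard curve is ordinary least
squares of Ct on log10 copies, inverted as `10^((ct − intercept)/slope)`;
ELISA binding ratios are reference-subtracted (540 nm) 450-nm absorbances,
target well over PBS well — arithmetic only, since replicate optical
densities behind published significance tests are not available.

## The synthetic generator

`generateFastq()` emulates the NGS arm of the CPA. Defaults are the study
conditions: three time points (0, 150, 270 min) with focal fractions
0.541, 0.759, 0.916 (the observed abundances of the fast-propagating
clone), 53-nt single-end reads, and a total corruption rate near the ~5%
read removal observed at the first time point. Because the published
totals do not reveal *why* individual reads failed, the split between the
two corruption mechanisms is this package's choice: 1% in-peptide stop
codons and 3.8% linker corruption by default, both independently
configurable.

Mechanics: library inserts are NNK codons (N any base, K ∈ {G, T} — all
20 amino acids reachable, TAG the only stop). The raw samplers
(`sampleNnkCodon`, `sampleLibraryPeptide`) emit TAG-containing inserts at
their natural ~1/32-per-codon rate, but `generateFastq()` draws
**stop-free** inserts for library reads — a clone must display a working
peptide to be in the pool — and injects stops only via `stopRate`, so
error-free settings produce exactly 0% removal and the generator's truth
labels reconcile exactly with the filter report. Linker corruption
substitutes the second codon base, which is always non-synonymous, so
every corrupted linker is guaranteed to fail the GGGS rule. With
`exact = TRUE` corruption counts are `round(rate × n)` instead of
binomial, which pins removal percentages deterministically. All output is
byte-identical under a fixed seed.

`generateGenomes()` emits a random 7222-nt reference with the fixture
coordinates and signature bases planted, and a mutant lacking positions
5879–6705 (827 nt, leaving a 6395-nt genome). Breakpoint flanks are forced
to differ so the placement is unique; `withHomology = TRUE` plants a 3-nt
micro-homology at the right flank whose left-aligned call is still 5879.
`generateSanger()` builds plus-strand reads spanning the signature region
followed by an anchored peptide cassette; environmental reads carry 2–5
signature mismatches.

What the generator does **not** emulate: Illumina error profiles and
quality scores, chimeric reads, real M13KE sequence content, primer
sequences, or between-run depth variation. Passing tests therefore
demonstrate the correctness of the arithmetic, filtering logic and
breakpoint geometry on data with the assumed structure — not robustness
to sequencing artifacts beyond the modeled corruption modes.

## Problem sizes and numerical choices

The test suite exercises the read filter at the published per-time-point
read totals (0.88–1.26 million reads) with exact corruption counts, runs
the NGS-CPA mixture-recovery check at 10⁵ reads per time point against a
3-binomial-SE band (plus 0.05 for the one-decimal reporting), and
validates the deletion caller against the brute-force oracle on 1000
random instances of length ≤ 200. Smaller sizes (2×10³–2×10⁴ reads) are
used in unit tests of bookkeeping identities, which hold exactly at any
size.

Degenerate inputs are rejected with typed conditions (`domain_error`,
`empty_input`, `no_indel`, `complex_variant`, `usage_error` in the CLI)
rather than producing partial results.

## Limitations

* The deletion caller supports exactly one contiguous deletion; any other
  difference is refused, not approximated.
* Provenance calls assume the query's genomic placement is known or
  anchor-findable; there is no alignment step.
* The fitness statistic assumes logistic competition between the focal
  clone and an aggregated background; it does not model infection
  dynamics.
* ELISA support is arithmetic only; significance testing would require
  replicate-level data.
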