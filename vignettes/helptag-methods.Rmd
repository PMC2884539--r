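---
title: "Angle-normalized HpaII/MspI tag counting: model and design notes"
author: "helptag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Angle-normalized HpaII/MspI tag counting: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helptag)
```

## The assay and its model

HELP-tagging infers cytosine methylation at CCGG sites from two
restriction libraries of the same DNA. HpaII and MspI both recognize
CCGG and cut C^CGG, but HpaII is blocked when the internal CG is
methylated while MspI cuts regardless. After cutting, a ligated
adapter positions the type III enzyme EcoP15I to cleave 25-27 bp into
the flanking DNA, so each cut yields short genomic tags whose counts,
site by site, encode methylation: an unmethylated site produces both
HpaII and MspI tags, a methylated one only MspI tags.

Counts are noisy in two ways that the method must separate:
methylation (what we want) and locus-specific capture efficiency
(fragment size, composition, amplification - what we do not want).
Because both libraries share the same loci, efficiency affects HpaII
and MspI alike. The package therefore scores each site by the angle

$$B = \operatorname{atan2}(h, m) \cdot 180 / \pi \in [0, 90],$$

where $h$ and $m$ are the HpaII and MspI *fixed counts* (each site's
fractional count divided by its sample's total, scaled per million).
$B = 0$ is fully methylated, $B = 90$ fully unmethylated, and scaling
both inputs by a common factor - which is what shared efficiency does
- leaves $B$ unchanged. The Euclidean norm
$c = \sqrt{h^2 + m^2}$ grows with read depth and ranks sites with
equal angles by the evidence behind them. Sites with $h = m = 0$ were
not assayed at all and are flagged `no_data` rather than scored 0: a
zero angle is a measurement (MspI signal, no HpaII signal), absence
of both is not.

Two design choices here were genuinely open:

* **Fixed, not raw, counts.** The angle could be computed on raw
  counts, but then $B$ would depend on lane depth; total-normalizing
  each sample first ("fixed counts") makes one MspI reference
  reusable across HpaII samples. The per-million scale affects only
  $c$, not $B$.
* **Zero-angle sentinel.** In wiggle tracks a methylated-but-tested
  site would be invisible at 0; it is written as -1.0, a value no
  scored site can take, so browsers show it as "tested, methylated".
  `no_data` sites are omitted from the wiggle and listed in a
  companion BED instead.

## From reads to counts

Reads are 36 bp. A genuine read carries `CGCTGCTG` near its 3' end:
the CG cohesive end of the HpaII/MspI cut followed by the EcoP15I
recognition site of the adapter. QC keeps reads containing this
anchor (leftmost exact match; an 8-mer with mismatch tolerance would
admit false anchors) and reports the anchor-position histogram, which
peaks at the EcoP15I cut lengths. The read geometry used throughout
is: cut_length-1 bp of genomic flank, the genomic CG, then `CTGCTG`
and adapter filler, so the anchor starts exactly at position
cut_length (25-27).

The 27-bp tag is the read's bases 2-28 after masking everything from
two bases past the anchor start (the adapter) with N. Tags are
aligned with at most 2 mismatches, N counting as a mismatch on either
side, and every location is reported up to a cap of 10; a tag with
$n$ locations contributes $1/n$ at each (fractional counting), so
repetitive loci are represented rather than silently dropped. Tags
with more than 2 Ns in their first 25 bases are unalignable within
the budget and are dropped up front.

The internal aligner is an exhaustive seed-and-extend: three disjoint
9-bp seeds at tag offsets 0/9/18 are looked up in an exact k-mer
index, candidates are verified by plain Hamming distance. With at
most 2 mismatches among three disjoint seeds, at least one seed is
clean (pigeonhole), so the search is complete; note that *two* seeds
would not suffice, since one mismatch can land in each. The test
suite checks the aligner against an independent exhaustive scan
(`Biostrings::matchPattern`) on twenty seeded genomes.

An alignment is assigned to the annotated site whose central CG its
cut-proximal end implies: a plus-strand alignment starting at 0-based
$t$ points at site position $t + 24$, a minus-strand one at $t - 1$
(the 27-bp cut nominal); cut lengths of 25-26 shift this by 1-2 bp,
absorbed by a +/- 2 bp slack with exact-match-first, then
smaller-distance, then lower-coordinate tie-breaking. Both flanks of
a cut aggregate into one per-site count. Alignments adjacent to no
annotated site are kept - they are the raw material for gained-site
discovery.

## Polymorphic CCGG sites

A variant destroying a CCGG makes an annotated site permanently
silent in MspI data; a variant creating one yields MspI tags at an
unannotated locus. Lost sites are called by a strict zero rule over
merged MspI lanes (any read disproves homozygous loss; heterozygotes
are deliberately not called - a documented limitation). Gained sites
are called from clusters of unassigned alignments (implied cut
positions within 2 bp) whose total fractional weight reaches 4 - the
genome-wide average MspI depth per site - and whose reference context
differs from CCGG by exactly one base. Substitutions are reported
strand-folded (`C:G>T:A` covers both C→T and G→A), the signature of
deamination of methylcytosine, which the simulator plants in 80% of
variants by default.

## Bias diagnostics

MspI counts are methylation-blind, so their distribution across
GC-composition bins (2% bins of 50-bp windows centered on the
tetramer midpoint, GC computed directly from sequence) and across
virtual-digest fragment-length bins (25-bp bins to 1 kb, then
open-ended; a width the data resolve around the 300-bp knee) exposes
assay bias as observed/expected ratios. The package diagnoses bias
but does not regress it out: because both enzymes share it, the angle
largely cancels it, and the suite verifies that toggling the planted
fragment-length bias moves the diagnostics without moving the
angle-truth correlation.

## The simulator

`simulateGenome()` / `simulateLibrary()` generate the entire
experiment with known truth: a single chromosome containing exactly
the planted CCGG sites (spurious CCGG occurrences and anchor motifs
are scrubbed from the background so truth is exact), GC-rich islands
around a subset of sites, identical copies of a 150-bp repetitive
element carrying one CCGG each (which multi-map, exercising 1/n
counting), optional lost/gained variants, and reads drawn per flank
as Poisson with intensity

$$\lambda = \tfrac{1}{2}\,\text{depth} \times \text{efficiency}
  \times \text{lenFactor}(\text{fragment}) \times f,$$

$f = 1 - m$ for HpaII and 1 for MspI. Defaults and the reasoning
behind the non-obvious ones:

| parameter | default | rationale |
|---|---|---|
| `depth` | 20 reads/site/enzyme | enough that Poisson noise does not dominate the angle at single-site resolution |
| `efficiency_sigma` | 1 (lognormal sdlog) | strong site-to-site capture heterogeneity, the nuisance the angle must cancel |
| `cut_length_probs` | 25:0.45, 26:0.45, 27:0.10 | EcoP15I cuts 25-27 bp with the bulk at 25-26 |
| `junk_fraction` | 0.30 | about a third of raw reads lack the anchor |
| `error_rate` | 0.005/base | typical substitution error for 36-bp short-read chemistry |
| `lenfactor_floor` | 0.25 | fragments >= 1 kb sequenced at a quarter efficiency; linear decline from the 300-bp knee |
| methylation mixture | 0.4 at m=0, 0.4 at m=1, 0.2 uniform | bimodal landscape; see below |
| `chrom_length` | 150 bp/site | desk-scale density for fast tests |

Two of these deserve explanation. First, the **methylation spikes are
point masses** at exactly 0 and 1. Single-CpG methylation in a pure
cell population is predominantly all-or-none; a point mass also makes
"fully methylated means zero HpaII reads" hold exactly. Diffuse
spikes (say, uniform on [0, 0.05]) would place mass on differences no
counting assay can rank at finite depth, capping rank-correlation
recovery regardless of implementation; the all-or-none landscape is
both the more realistic and the better-posed recovery target. Islands
are simulated unmethylated (m = 0) and repeat copies methylated
(m = 1), mirroring promoter CpG islands and transposable elements.

Second, **site density**. The default 150 bp/site keeps genomes small
and tests fast, but compresses the fragment-length distribution below
the 300-bp knee. Analyses that probe fragment-length effects use
1 kb/site, close to the genome-wide mean CCGG spacing, so that long
fragments are well represented.

What the simulator does *not* emulate: base-quality degradation
(filters here are sequence-based), indels, paired ends, bisulfite
chemistry, endogenous EcoP15I sites (absorbed into efficiency),
heterozygous variants, and chance CCGG/anchor octamers in the
background (scrubbed to keep truth exact). Passing tests therefore
show the pipeline recovers truth under the assay's own biochemical
logic and realistic count noise - not that it is robust to every
artifact of real instruments.

## Problem sizes and determinism

The package's validation runs at desk scale, chosen so the whole
suite completes in minutes: unit fixtures of 80-300 sites on 12-50 kb
genomes; recovery analyses at 2,000 sites / 300 kb; replicate
reproducibility at 5,000 sites / 600 kb; aligner-oracle equivalence
on twenty genomes of 60-100 kb with 500 tags each. Every random draw
flows from an explicit integer seed (libraries default to the genome
seed + 1 for HpaII and + 2 for MspI), and identical configurations
reproduce byte-identical outputs; `runPipeline()` writes a
provenance YAML (versions, seed, thresholds) next to its results.

## Known limitations

* The strict-zero lost-site rule conflates genuine polymorphism with
  low-efficiency dropout at shallow depth; the standard remedy,
  intersection with a known-variant catalog, is implemented as the
  variant-filtered candidate list.
* GC content is computed directly from sequence; pipelines that used
  precomputed 5-bp annotation windows will differ at the margin.
* Gained sites created by indels are out of scope; only
  single-substitution neighbors of CCGG are considered.
* Angles are not calibrated to absolute percent methylation; the
  package validates by correlation against reference values
  (`correlateWithReference()`), not by a calibration curve.
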