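---
title: "Methods: comparative plastome diversity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome diversity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
```

`plastomics` implements the statistics used when a newly assembled
chloroplast genome is screened against congeneric plastomes: site-level
SNP/indel classification of a whole-plastome alignment, the
private/shared SNP partition over species subsets, sliding-window
variability and hotspot detection, uncorrected distances, Tajima's
relative rate test, and quadripartite structure summaries. This
vignette records the models, the assumptions, and the design choices
that were genuinely open.

## The alignment model

All analyses consume a pre-built multiple alignment of whole plastomes
(building the alignment, e.g. with MAFFT, is out of scope). Rows are
uppercase over `{A, C, G, T, N, -}`; IUPAC ambiguity codes are
normalized to `N` on load and counted in a message. `N` is treated as
*missing data* throughout: the field's assemblers already use it for
unresolved positions, and folding the rare ambiguity codes into it
gives a single, conservative missing-data symbol. Only `-` is accepted
as gap; `.` is rejected outright because silently reinterpreting a
second gap dialect is a classic source of corrupt columns.

Internally all coordinates are 0-based half-open, which keeps window
arithmetic and BED output exact; every user-facing table is written
1-based inclusive (the convention of GenBank and of the formats users
actually read). The two conventions meet only inside the writers.

## Site classification and the subset partition

A column is a **SNP** when at least two distinct non-missing nucleotide
states occur among the rows; it is an **indel position** when any row
carries a gap. The two flags are deliberately independent — a gapped
column can still be a SNP among the non-gapped taxa — because SNP and
indel tracks are plotted and tabulated as separate series over the same
windows. Columns with fewer than two non-missing rows are
*uninformative*: neither SNP nor monomorphic. Missing data never
creates nor blocks a SNP call; it only shrinks the informative taxon
set. This is the conservative reading when a source does not specify
missing-data handling.

The private/shared partition credits, at every SNP column, each
**allele class** — the maximal set of non-missing taxa sharing one
state — that is a proper subset of the full taxon set. Singleton
credits are a species' private SNPs, *including* columns where the
remaining taxa are polymorphic among themselves; the credit for a
four-species subset counts columns where exactly those four share a
state the fifth lacks. This definition is the only one under which a
species' private count can exceed the complementary four-species shared
count (the difference being exactly the columns where the focal species
is unique while the others are polymorphic), which is the behaviour
published Venn summaries of this kind display. Because it remains an
inference about an informally described statistic, the rule is stated
prominently here and the test suite pins it to a brute-force enumerator
over every taxon subset. Monomorphic columns credit nothing, and each
(column, subset) pair is credited at most once.

## Sliding windows, hotspots, deletions, identity

Windows have fixed length `L` (default 500 bp) advanced by step `s`
(default 250 bp) — the standard resolution for plastome variability
scans; a trailing partial window is dropped by default so that all
emitted windows are directly comparable (a flag re-enables it). The
window midpoint `start + L/2` is the canonical plotting coordinate.
Hotspot detection selects windows either above a count threshold
(`min_count`) or the `top_k` highest-count windows (ties: count
descending, then leftmost), merges overlapping or adjacent selections,
and **recounts distinct SNP columns** per merged region — overlapping
windows share columns, and summing window counts would double-count
them. This is why merged hotspot regions come out with widths that are
multiples of the step (e.g. 750 bp from two overlapping 500 bp
windows).

High-deletion screening flags windows in which any single taxon's gap
proportion exceeds a threshold (default 0.70), listing the offending
taxa; this is the screen that separates "many small indels" from "one
long species-specific deletion" in an indel-density track.

Windowed percent identity against a reference taxon divides matching
columns by *comparable* columns: positions where either sequence is `N`
are excluded, gap-versus-gap is excluded, and gap-versus-base counts as
a mismatch. A window with zero comparable columns yields `NA`, never
0 — an undefined identity must not plot as maximal divergence.

Window annotation lifts a feature table given on the reference taxon's
ungapped coordinates onto alignment columns through the strictly
monotone gap-aware coordinate map, and names the gaps between
consecutive features `geneA-geneB spacer`, so hotspot regions can be
reported by locus name.

## Distances and the relative rate test

p-distances are uncorrected proportions of differing sites. The default
is **complete deletion**: every column containing a gap or `N` in *any*
row is removed before counting, so the whole matrix shares one
denominator (reported as the number of retained positions). This
matches how distance tables for plastome comparisons are conventionally
computed and makes the matrix entries directly comparable; a
pairwise-deletion option exists for sparse alignments but is not the
default.

Tajima's one-degree-of-freedom test compares two ingroup taxa A and B
against an outgroup O on the columns where all *three* are non-missing
and non-gap (deletion is per-triple, not global — the test is run pair
by pair and discarding columns for taxa not involved would waste
signal). With `mA` the number of sites where A alone differs (A ≠ B and
B = O) and `mB` its mirror image,

\[ \chi^2 = \frac{(m_A - m_B)^2}{m_A + m_B}, \qquad \text{1 df}, \]

and the p-value comes from the continuous chi-square upper tail with no
continuity correction, as in the standard implementations of the 1D
test. `mA + mB = 0` carries no information and is reported as
chi² = 0, p = 1 rather than an error. When the test is significant the
taxon with the *smaller* unique count is the slower lineage. The
all-pairs driver annotates significance at p < 0.01 by default, the
customary threshold for published tables of this test.

## Inverted-repeat detection and structure summaries

The IR detector finds the longest pair of disjoint spans such that one
equals the reverse complement of the other, by seed-and-extend: exact
k-mer matches (default k = 24, subsampled every k/2 positions) between
the doubled sequence and its reverse complement are grouped by match
diagonal and extended maximally in both directions. Doubling the
sequence handles circularity; reported starts are normalized to
`[0, length)` and an arm may wrap the origin. Matching is exact by
default — annotated IR lengths for plastomes are exact repeat spans —
and k-mers occurring more than 20 times are skipped as repeat masking.
Ties in length are broken by leftmost start, and the returned spans are
re-verified by direct reverse-complement equality before being
returned (a self-checking postcondition). If no repeat reaches
`minLength` (default 10,000 bp, the scale of plastome IRs), the error
reports the longest candidate found instead of silently returning one.

The two inter-IR arcs are assigned LSC (longer) and SSC (shorter); on a
tie the arc following the first arm is named LSC with a warning. IRa is
defined as the IR that follows the LSC, so region rows are reported in
the canonical LSC → IRa → SSC → IRb order and their lengths always sum
to the total length. GC content is (G+C)/(A+C+G+T) × 100 with `N`
excluded from the denominator (an all-N region yields `NA`). Note that
GC computed this way can differ in the first decimal from values
computed over all positions including `N`; the package always reports
the N-excluded value. The gene census counts annotated feature
*occurrences* by kind — a plastome with four rRNA genes duplicated in
the IRs reports eight rRNA features — because that is how published
per-genome gene tallies are constructed; multi-interval (`join`)
locations of a single occurrence count once.

GenBank flatfiles are parsed by a small internal reader (feature keys
CDS/tRNA/rRNA plus `join`/`order`/`complement` locations, and the
ORIGIN block); unparseable locations are skipped with a warning and
counted rather than aborting the run.

## The synthetic-data generator

The simulator exists so that every statistic above can be validated
against known truth without downloading anything. It emulates the study
conditions of a five-species congeneric plastome comparison:

- **Genome plan**: LSC 90,353 bp, IR 25,840 bp, SSC 18,955 bp (total
  160,988 bp), IRb built as the exact reverse complement of IRa; base
  composition A 31.1 / C 18.7 / G 18.0 / T 32.2 %. The junctions are
  adjusted so the planted arms are *maximal* exact repeats, making
  "detected spans equal planted spans" a well-defined contract.
- **Phylogeny**: a star tree with five ingroup branches at 0.002
  substitutions/site and one outgroup branch at 0.012 — chosen so
  ingroup pairwise p-distances land in the few-per-mille range typical
  of congeneric plastomes while the outgroup is clearly external.
  A user-supplied set of lineage multipliers skews individual branches
  for relative-rate power studies.
- **Regional rate structure**: substitution and indel rates are
  multiplied by 0.1 inside the IRs (reproducing the near-flat IR
  profile characteristic of plastomes) and by 12 inside four 750 bp
  hotspot intervals (three in the LSC, one near the SSC 3' end),
  standing in for variable intergenic spacers.
- **Indels**: gap runs initiate at 2 × 10⁻⁴ per site per taxon with
  geometric lengths (mean 8 bp), applied post-substitution as
  deletions in single taxa; one planted 600 bp deletion in one taxon
  drives the high-deletion screen. Events never overlap a column
  already gapped in another taxon, which keeps the truth bookkeeping
  exact. Substitutions are Jukes–Cantor style: a mutated site picks
  uniformly among the three alternative bases.

Because only deletions (no insertions) are simulated, alignment columns
coincide with reference coordinates and the truth table — per-column
classes computed by direct enumeration, subset credits, hotspot and
deletion spans, region coordinates — is exact by construction. A fixed
seed makes both the reference and the alignment byte-reproducible; the
replicate generator for rate tests uses flat rates (no regional
structure), since calibration should be measured under the test's own
assumptions.

What the simulator deliberately does **not** emulate: insertions (and
hence column/reference coordinate divergence), concerted evolution of
the IRs (the 0.1 multiplier mimics its *effect* on variability),
codon structure and selection, rate heterogeneity along branches
(heterotachy), recombination, and non-star tree shape by default.
Passing tests therefore demonstrate correctness of the statistics under
a clean neutral model, not robustness to every artefact of real
alignments — in particular, alignment errors around long indels, which
in real data are handled upstream by the aligner.

## Problem sizes and numerical choices in the test suite

The suite validates the classifier and subset partition against a
brute-force enumerator on 200 random alignments of up to 8 taxa × 200
columns; truth recovery end to end on a 20 kb five-taxon alignment
(scaled to 11,300 / 3,230 / 2,240 bp regions — the full-genome plan at
roughly one-eighth scale, keeping all four regions and hotspots
present); relative-rate calibration on 1,000 replicate triples of
10 kb, expecting an empirical type-I error within [0.035, 0.065] at
α = 0.05; and power on 20 kb triples with a 5× rate ratio. These sizes
keep the default test run fast while leaving every per-window and
per-column code path exercised at realistic densities.
`scripts/acceptance.R` runs the same pipeline once at the full
160,988 bp scale.

Degenerate inputs are specified, not accidental: an alignment shorter
than one window is an error suggesting a smaller `L`; a distance matrix
with zero complete columns is an error naming the cause; a
zero-information rate test returns chi² = 0, p = 1; an identity window
with no comparable columns is `NA`; an IR search with no qualifying
repeat reports the longest candidate found.
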