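---
title: "Methods: cap-dinucleotide mass identification and short-RNA cap profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cap-dinucleotide mass identification and short-RNA cap profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capscape)
```

# The problem

Short (<200 nt) human RNAs carry a richer repertoire of 5′ cap structures
than the canonical 7-methylguanosine cap of mRNA: trimethylguanosine caps on
snRNA/snoRNA, dimethyl intermediates, 2′-O-ribose-methylated first
nucleotides, and unmethylated GpppN caps. Three assay types see these caps
from different angles. LC-MS measures the monoisotopic [M−H]⁻ mass of the
cap released as a 5′-5′ dinucleotide triphosphate by nuclease digestion;
cap-sensitive sequencing chemistries reveal which RNA biotypes and length
classes carry caps; and 2D-TLC of the radiolabeled cap nucleotide identifies
its methylation state by co-migration with standards. `capscape` implements
the computation behind each leg and the joins between them.

# The mass model

## Elemental algebra

Every molecule is an integer vector of atom counts over C, H, N, O, P. The
four ribonucleosides are fixed (adenosine C10H13N5O4, cytidine C9H13N3O5,
guanosine C10H13N5O5, uridine C9H12N2O6); each N-methyl or 2′-O-methyl adds
one CH2. The cap dinucleotide is

$$F_\mathrm{cap} = F_{N_1} + F_{N_2} + \mathrm{H_5P_3O_{10}} - 2\,\mathrm{H_2O},$$

symmetric in the two nucleosides. Monoisotopic masses come from a frozen
atomic-mass table (C 12 exactly, H 1.0078250319, N 14.0030740,
O 15.9949146, P 30.97376151 Da) so that results are bit-stable across
platforms.

## The anion convention

Negative-mode ESI observes the deprotonated molecule. We subtract the
proton mass 1.00727646 Da from the neutral monoisotopic mass; the electron
is thereby accounted for implicitly. Published calculated-mass columns from
this field sit systematically about 2.5–2.8 mDa (≈3.2–3.4 ppm) *below* the
values this convention produces, on every row we recompute, and the source
tables do not state their convention. We therefore never compare masses for
exact equality against printed values; all agreement checks are expressed
in ppm with a 5-ppm ceiling, which absorbs the offset while remaining far
tighter than one methyl spacing (14.01565 Da ≈ 17 000 ppm).

## Assignment and isobars

An observation is matched by computing the ppm error against every cap in
the enumerated alphabet and keeping candidates within tolerance. Two facts
shape the report:

* mass cannot order the two nucleosides across the symmetric bridge, so
  caps are unordered pairs and labels canonicalize with the cap-guanosine
  side written first;
* mass resolves methyl counts, not positions, so all placements of the same
  methyl count on the same base pair are one *isobar group* (provably the
  same formula). The matcher groups candidates by formula and reports the
  group, not a single winner.

The default alphabet allows 0–3 base methyls on G (up to
trimethylguanosine), 0–1 on A (N6), none on C/U, and one optional
2′-O-methyl per nucleoside: 16 nucleosides, 136 unordered caps. This covers
every structure the assays name without inflating the candidate space;
wider alphabets are a constructor argument away. Observed masses with no
in-tolerance candidate are reported as `unknown` together with their
nearest out-of-tolerance candidates — unknowns are curation targets, and
deliberately never disappear. We do not attempt to resolve them against
speculative extended alphabets; that is reporting, not inference. (Under
the default alphabet two of the unknown masses near 843.126 do fall within
5 ppm of the G/G four-methyl group; the matcher reports this and leaves the
interpretation to the curator, since the original assignments rest on
evidence beyond precursor mass.)

Default tolerance is 5 ppm: the largest printed assignment error in the
reference detection table is 3.00 ppm, and 5 ppm also covers the
calculated-mass offset above.

## Cap typing

Type 0 caps carry no 2′-O-methyl on the first transcribed nucleotide; any
inner Nm makes the cap type I or higher. Because the pair is unordered, the
inner side is taken from the same canonicalization used for labels (the
non-cap-guanosine side). For symmetric G/G caps without ribose methylation
this is type 0, as expected.

# Sequencing-side procedures

**Adapter clipping.** The 17-nt 3′ adapter is found as the leftmost
position where an adapter *prefix* of at least `min_match = 8` bases
matches exactly through the read's end (or the full adapter internally).
Exact matching is deliberate; mismatch-tolerant clipping is out of scope.
The arithmetic consequence, which the tests enumerate exhaustively: with
100-nt reads the inferable insert lengths are exactly 0–92, and 93 is the
first length at which inference fails — reads without an adapter match
represent RNAs of at least that length and are flagged `unmeasured` rather
than assigned a length.

**rRNA dusting.** A tag is removed iff its clipped sequence is an exact
substring of the rDNA reference or its reverse complement. Strand-agnostic
removal is the conservative choice where the original tooling's behavior is
unspecified. The filter is idempotent by construction.

**Toy aligner.** An exhaustive exact-substring search on both strands,
equivalent by test to a naive quadratic scan. It exists so that desk-scale
analyses and tests are self-contained; production alignments arrive as
SAM/BED and are ingested, not computed. Coordinates are 0-based half-open
throughout (BED-native); SAM input is converted on ingestion. Multi-mapping
tags are excluded from annotation counts by default (`unique_only`),
with all hits reported and flagged.

**Annotation.** The resolved biotype of a tag is the maximum-priority
biotype among features it overlaps by ≥1 nt, in increasing priority:
unknown, intron, exon, miRNA, snRNA, snoRNA, tRNA. The priority order is a
total order, so ties cannot occur between categories, and ties within a
category do not affect the label. Overlap is strand-aware by default
(antisense tags do not inherit sense annotations) with an `ignore_strand`
escape hatch, since the original counting rule is not documented.

**Length bins.** The published size ranges overlap at 100 nt ("51–100" and
"100–200"); we resolve them to [51,100] and [101,200] so the bins
partition, and document this in output headers. Lengths above 200 and
unmeasured lengths get their own classes.

**Site windows.** TSS/TTS profiles count tags whose strand-aware 5′ end
falls in a window of 100 nt centered on the site, half-open
`[site − w/2, site + w/2)`, plus the fraction of all tags falling in any
window.

**Cluster enrichment.** Clusters are single-linkage merges of overlapping
tag intervals pooled across libraries. Counts are normalized to
counts-per-million within each library; enrichment is
`log2((mean treatment CPM + p) / (mean control CPM + p))` with pseudocount
`p = 1`, and mean CPM over all libraries serves as the expression scale.
This is a declared descriptive stand-in, not a count-model test: the
reference analysis reports fold changes only, and no statistical test is
named for it. Swapping treatment and control negates the fold change
exactly, which the tests assert.

# TLC quantification

Spot percentages are background-subtracted intensities normalized to the
total over all quantified spots on the same plate:
`pct_i = 100·max(raw_i − bg_i, 0)/Σ_j max(raw_j − bg_j, 0)`. Loading
origins are saturated in this assay and are excluded from numerator and
denominator via the `saturated` flag. Negative net intensities clamp to
zero with a warning rather than erroring, because small negative residuals
are routine densitometry noise. Replicate summaries report the arithmetic
mean, sample SD (n−1; zero for a single replicate) and count per
(fraction, spot); spots missing from a replicate count as absent, not zero,
unless `absent_as_zero` is requested. Ambiguously migrating spots are kept
as labeled: the package does not second-guess the spot assignment, which is
an input.

Joining TLC with MS identifications requires bridging two label grammars:
TLC names methyl *positions* ("2,2,7mGp" carries three methyls), MS names
*counts* ("3mG"). Both map onto a shared key (base, number of base methyls,
ribose methylation), which is exactly the information content common to the
two techniques; the join is a set intersection on that key with residual
sections for single-technique observations.

# The synthetic study conditions

The generators exist because the deposited raw data is not required at desk
scale; they emulate the *structure* of the study, with known truth:

* a 100-kb uniform-random genome with 20 non-overlapping planted features
  per biotype and a reserved synthetic 2-kb rDNA segment (the rRNA filter's
  reference is this segment, so no external reference is needed; a real
  rDNA FASTA can be passed instead);
* four library types over the same genome, 1 500 reads each by default,
  100-nt reads assembled as insert + adapter + random fill: an sRNA library
  dominated (60%) by miRNA inserts of 20–24 nt; a capped sRNA library with
  a broader snoRNA/tRNA-rich mixture; a CAGE library (35% snRNA) whose long
  5′ inserts are truncated enzymatically to 27 nt downstream; and an
  IP library with 55% snRNA fragments against a 5% background control
  (an ~11-fold planted enrichment). Insert lengths are truncated normals
  per biotype because the source material quotes ranges, not
  distributions; 5% of reads are rDNA contaminants;
* mass observations drawn from the catalog with Gaussian *relative* noise
  of 1.5 ppm SD, the scale at which a 5-ppm tolerance should recover ≥95%
  of true isobar groups (a >3σ margin);
* TLC plates built from fixed truth percentages scaled by a random
  per-plate exposure plus background and noise, three replicates, with a
  saturated origin row.

Everything derives deterministically from one seed (same seed, identical
bytes). What passing on this synthetic data does **not** show: robustness
to sequencing errors, quality-score effects, PCR duplication, repetitive
genomes (multi-mapping is rare by construction in a random genome),
adapter mismatches, or retention-time behavior of isomers. Those are real
phenomena the generators deliberately omit.

# Numerical and testing choices

* Atomic masses, the proton mass and CH2 are frozen constants; golden
  expectations in tests were computed by an independent per-atom summation
  written alongside the tests, not by the package itself.
* Formula subtraction that would produce a negative atom count is an error,
  never a silent clamp; plate normalization, by contrast, clamps negative
  net intensities because the domain expects them.
* Deterministic ordering everywhere a report is written: catalogs sort by
  (mass, label); CSV outputs fix column orders, 6-decimal masses, 2-decimal
  ppm.
* Test problem sizes are chosen to exercise the algorithms while keeping
  the suite fast: the annotation oracle runs 1 000 tags against 10 000
  random features; parameter recovery uses 200 observations; the
  end-to-end recovery run uses the default 1 500-read libraries on the
  100-kb genome; unit tests use smaller instances of the same generators.

# Interfaces

The package's functions are the primary interface, mirrored stage for
stage by `run_pipeline()`, which wires simulate → clip → dust → align →
annotate → profile → enrich plus the independent MS and TLC branches and
writes a manifest (seed, config hash, per-stage counts with
`reads_in = kept + removed` at every filter). A thin command-line
dispatcher over the same functions ships in `inst/scripts/capscape.R` for
shell use; it contains no logic of its own.

# Known limitations

* Precursor mass cannot distinguish retention-time isomers; the matcher
  reports one label per methyl-count arrangement and leaves isomer splits
  to chromatography.
* The enrichment statistic is descriptive; no significance is attached.
* The toy aligner is quadratic and intended for ≤10-kb–scale tests and the
  synthetic genome, not real genomes.
* Adapter clipping is exact-match by design; reads with sequencing errors
  inside the first 8 adapter bases will be misclassified as unmeasured.
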