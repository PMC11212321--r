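---
title: "Methods: simulating and analysing TRB CDR3 clonal repertoires"
author: "ClonoTRB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing TRB CDR3 clonal repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClonoTRB)
```

# Scope and model

ClonoTRB analyses T-cell receptor β-chain (TRB) repertoires at the level of
the CDR3 junction: the hypervariable region running from the conserved
V-segment cysteine (2nd-CYS) through the conserved J-segment
phenylalanine/tryptophan (J-PHE/J-TRP), anchor codons included.  A
*clonotype* is the set of sequenced molecules sharing one CDR3 nucleotide
sequence — V/J calls annotate a clonotype but do not key it, so two
rearrangements with identical junctions but different segment calls collapse
into one clone.  Molecules, not raw reads, are the unit of abundance: reads
are grouped by unique molecular identifier (UMI) and each UMI family counts
once, which removes PCR amplification bias and lets per-family consensus
absorb sequencing errors.

The package has four layers:

1. **Simulation** (`simulationConfig`, `presetConfig`,
   `simulateRepertoire`, `simulateReads`): ground-truth repertoires and
   error-bearing UMI-tagged reads.
2. **Assembly** (`runAssembly` and its parts): FASTQ → UMI families →
   consensus → V/J assignment → CDR3 extraction → productivity filter →
   clonotype table (a `Repertoire`).
3. **Per-repertoire statistics** (`clonalDiversity`, `segmentUsage`,
   `lengthDistribution`, `motifMatrix`, `expansionProfile`,
   `topCumulative`).
4. **Comparative analysis** (`repertoireOverlap`, `multiOverlap`,
   `bubSimilarity`, `similarityMatrix`, `trackClones`, `emergingClones`,
   `ksCompare`), orchestrated end to end by `runPipeline`.

# The synthetic-data generator

The generator stands in for a 5′-RACE TRB sequencing experiment on
humanized-mouse T cells, with two study arms:

* **untreated** — a polyclonal baseline: 400 clones, power-law rank
  abundance with exponent α = 1.1, ~8,400 molecules
  (`moleculesPerCloneScale = 21`), no emerging clones;
* **treated** — the post-stimulation state: 150 clones, steeper decay
  (α = 1.6), ~1,650 molecules, and 50 *emerging* clones — novel
  rearrangements absent from the matched baseline — whose base weights are
  multiplied by `emergingBoost = 20`, modelling preferential expansion of
  newly recruited clones until they dominate the repertoire.

## Why a power law rather than a geometric series

Two empirical regimes must hold simultaneously: dominant clones (the top 10
clonotypes carry more than half of all molecules in every sample) and a
long sampled tail (several hundred distinct clonotypes observed from a few
thousand molecules).  A geometric series $w_i = q^i$ cannot do both: strong
dominance needs $q \lesssim 0.93$, at which point rank-400 weights are
$\sim 10^{-13}$ and the tail is never sampled, while a tail-preserving
$q \gtrsim 0.99$ caps the top-10 share near 10%.  A power law
$w_i = i^{-\alpha}$ has both a heavy head and a heavy tail: at α = 1.1 the
top-10 share is ~53% while rank-400 clones still expect ~2 molecules.  The
geometric model remains available through
`simulationConfig(abundanceModel = "geometric")`.

## Junction construction

Each clone's junction is V-suffix (from the anchor codon) + $n$ uniformly
random untemplated bases + J-prefix (through the anchor codon).  D segments
are not modelled separately; the analyses never consume D calls, and the
random insert block carries the equivalent diversity.  The target
nucleotide length is drawn from a discretised normal (mean 42, sd 2.5),
reproducing the unimodal 35–45 bp CDR3 length distribution with a 14-residue
modal amino-acid length.  Frame handling is explicit: with probability
`unproductiveFraction` (default 0.08) a clone is frame-shifted by one base
(length ≢ 0 mod 3); all other clones are redrawn until their in-frame
translation is stop-free.  The redraw step reflects selection of expressed
clonotypes — a sequenced mRNA repertoire is overwhelmingly productive, and
without it ~20% of in-frame junctions would carry stops purely because
uniform inserts hit stop codons, leaving the unproductive rate uncontrolled
by its parameter.

## Paired treated/untreated simulation

Treated and untreated samples from one donor are not independent: the
treated repertoire consists of persisting baseline clones plus newly
emerging ones.  `simulateRepertoire(cfg, reference, baseline = <untreated
ground truth>)` therefore draws the non-emerging treated clones without
replacement from the baseline's *observed productive* clonotypes and
generates emerging clones as novel rearrangements guaranteed absent from
the baseline.  Under this pairing, `emergingClones(treated, untreated)`
recovers exactly the flagged ground-truth clones that received at least one
molecule — the detector's recovery property.  The required sampling depth
matters: at the preset depth a deeply ranked emerging clone expects less
than one molecule, so exhaustive (50/50) detection is exercised at a deeper
`moleculesPerCloneScale` in the tests, while preset-depth runs assert exact
recovery of the sampled flagged set.

## Reads, UMIs and errors

Every molecule receives a distinct random 12-nt UMI (distinctness is
enforced — at 8,400 molecules unconstrained draws would collide about twice
per run and corrupt ground-truth counts) and emits `readsPerMolecule`
(default 3) reads of the full rearrangement (whole V segment + inserts +
whole J segment, ~130 nt against the bundled reference).  Each read base is
substituted by a uniformly chosen different base with probability
`subErrorRate` (default 0.002); indels and UMI read errors are not
simulated (the directional UMI merge that would absorb UMI errors is
tested directly on constructed inputs).  All randomness flows from the
single config seed; the global RNG state is saved and restored.

## What the generator does not emulate

No thymic/HLA selection of specific amino-acid motifs, no shared "public"
clones between donors, no indel errors, no PCR chimeras, no per-position
quality variation (all bases written at Q40).  Passing recovery tests
therefore demonstrate correctness of the pipeline's bookkeeping and error
model under these assumptions, not performance on real instrument data.

# Assembly choices

* **UMI grouping**: exact groups first, then a directional merge — a
  smaller group folds into a larger one when the UMI Hamming distance is
  ≤ 1 (configurable) and the larger count is ≥ 2× the smaller, the
  standard adjacency rule for UMI error correction.  Candidate parents are
  scanned in descending-count order with lexicographic tie-breaks, so
  grouping is independent of read order.
* **Consensus**: per-position plurality over the family's reads of the
  modal length, ties broken A < C < G < T.  Three reads per molecule at
  error 0.002 leave the consensus wrong only when two reads err identically
  at one position (~$10^{-5}$ per base).
* **V/J assignment**: Smith–Waterman local alignment (+2 match, −2
  mismatch, −3 per gap base) of each distinct consensus against every
  reference segment; best score wins, ties resolve to the
  lexicographically first segment name, and hits below `minScore = 30`
  are unassignable (seeded random 50-mers score well below 30 against the
  bundled reference).  The J search is restricted to the region downstream
  of the projected V anchor, which rules out anchor inversions by
  construction.  Anchor positions are projected arithmetically for gapless
  alignments and through the gapped alignment otherwise.
* **Productivity**: a junction is productive iff its length is divisible
  by 3 and its translation contains no stop; unproductive molecules are
  counted in the QC report and removed, and clonotype fractions are
  normalised over the productive remainder.
* **Quality filtering** is available as a mean-Phred cutoff
  (`minMeanPhred`) but off by default — the simulator writes uniform
  qualities, and vendor-grade quality trimming is out of scope.

# Statistics conventions

Diversity uses plug-in estimators on clonotype fractions $p_i$: Simpson
$\sum p_i^2$, inverse Simpson $1/\sum p_i^2$ (the clonality index; equals
the clone number for a uniform repertoire), Shannon–Weaver
$-\sum p_i \ln p_i$ in natural log (ecology convention), Berger–Parker
$\max p_i$.  Motif matrices use bits: per-position information content is
$\log_2 20 - H_j$, and logo letter heights are frequency × information.
Expansion profiles expose the disjoint molecule-count classes 1, 2 and 3+,
with the overlapping "2+" of donut-chart legends derivable as their sum;
quintiles split the count-ranked clonotypes into five equal rank blocks
(remainders to the earlier blocks).  Reported percentages are rounded to 3
significant figures.

The Baroni–Urbani & Buser similarity
$(\sqrt{ad}+a)/(\sqrt{ad}+a+b+c)$ needs a clonotype universe to define
shared absences $d$; `similarityMatrix` fixes it to the union across the
full analysis set — a pairwise universe would force $d = 0$ and collapse
the index to a Jaccard-like form.  Overlap percentages use the
pairwise-union denominator, the reading consistent with the per-sample
unique counts it is reported against.  The two-sample Kolmogorov–Smirnov
comparison returns $D$ with the asymptotic Kolmogorov p-value at effective
size $n_a n_b/(n_a+n_b)$; exact small-sample p-values are out of scope.

A note on direction: under these presets the treated arm has fewer
molecules *and* lower inverse Simpson than the untreated arm (checked over
repeated seeds), i.e. treatment concentrates the repertoire into dominant
emerging clones.  Diversity readings in the motivating experimental setting
are ambiguous in this respect; the package commits to the
fewer-but-more-dominant interpretation that the emerging/expansion design
implies.

# Determinism and problem sizes

`runPipeline` fans a single master seed out to per-sample child seeds via a
stable string hash of the sample id, so adding a sample never changes
another sample's data.  Identical configurations reproduce bit-identical
text outputs (FASTQ, AIRR TSV, JSON reports), verified by checksum in the
tests.  The shipped test suite runs the full presets (400/150 clones,
~33,000 reads per donor pair) for the recovery checks and reduced sizes
(25–60 clones) elsewhere; the demonstration configuration
(`demoPipelineConfig`) uses 60/30 clones so a complete two-donor run
finishes in seconds.

# Known limitations

The bundled germline reference is synthetic (IMGT-style names, realistic
anchor geometry, generated segment bodies) and contains 8 V and 5 J
segments; analyses depending on fine-grained allele discrimination need a
real germline library in the same FASTA dialect.  The clonotype key ignores
V/J calls, so convergent junctions across segments merge.  Indel
sequencing errors are unhandled by design, and the consensus step assumes
substitution-only noise.  KS p-values are asymptotic and unreliable below
roughly 10 observations per group.
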