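# ClonoTRB

Simulation and clonality analysis of T-cell receptor β-chain (TRB) CDR3
immune repertoires.

Immune-repertoire sequencing reads out the CDR3 junction of rearranged TRB
genes — the hypervariable region spanning the conserved V-segment cysteine
through the conserved J-segment phenylalanine — and uses it as a molecular
barcode for T-cell clones. ClonoTRB implements the full analysis path for
such experiments, aimed at studies that compare a polyclonal baseline
("untreated") repertoire against a stimulated ("treated") repertoire in
which newly emerging clones expand preferentially:

* **Simulation** — a ground-truth V(D)J repertoire generator
  (`simulateRepertoire`, `presetConfig`) with a power-law or geometric
  rank-abundance model, emerging-clone boosting, and a UMI-tagged read
  simulator (`simulateReads`) with per-base substitution errors.
* **Assembly** — UMI-prefixed FASTQ in, AIRR Rearrangement TSV out
  (`runAssembly`): directional UMI grouping, per-family plurality
  consensus, Smith–Waterman V/J assignment against a germline reference,
  CDR3 extraction between anchor codons, and removal of out-of-frame and
  stop-codon junctions. Clone counts are UMI families (molecules), not
  reads.
* **Per-repertoire statistics** — clonality and diversity indices
  (`clonalDiversity`: Simpson Σp², inverse Simpson 1/Σp², Shannon–Weaver
  −Σp·ln p, Berger–Parker max p), V/J/V–J usage (`segmentUsage`,
  `topSegments`), CDR3 length distributions (`lengthDistribution`),
  sequence-logo motif matrices in bits (`motifMatrix`), expansion profiles
  (`expansionProfile`) and top-N cumulative dominance (`topCumulative`).
* **Comparative analysis** — clonotype overlap and Venn decomposition
  (`repertoireOverlap`, `multiOverlap`), Baroni–Urbani & Buser similarity
  (√(ad)+a)/(√(ad)+a+b+c) with a shared-absence universe
  (`bubSimilarity`, `similarityMatrix`), top-clone tracking
  (`trackClones`), emerging-clone detection (`emergingClones`) and
  two-sample Kolmogorov–Smirnov comparison of dominant clonotypes
  (`ksCompare`).
* **Orchestration** — `runPipeline` ties simulate → assemble → stats →
  compare into one deterministic, seeded run that writes FASTQ, AIRR TSV,
  QC/stats/comparison JSON and a checksum manifest.

A small synthetic germline V/J reference (8 TRBV, 5 TRBJ segments with
annotated anchor codons) ships with the package; real germline libraries
can be supplied in the same `name|kind|anchor` FASTA dialect via
`loadReference`.

## Worked example

A complete two-donor demonstration study (each donor with an untreated and
a treated sample, treated samples paired to their donor's baseline):

```r
library(ClonoTRB)

bundle <- runPipeline(demoPipelineConfig(file.path(tempdir(), "demo"),
                                         seed = 42))
summarizeBundle(bundle)
```

```
        type                         id     group total_count unique_cdr3
1     sample               d1_untreated untreated         475          52
2     sample                 d1_treated   treated         240          22
3     sample               d2_untreated untreated         464          51
4     sample                 d2_treated   treated         240          14
5 comparison d1_treated vs d1_untreated      <NA>          NA          NA
6 comparison d2_treated vs d2_untreated      <NA>          NA          NA
  inv_simpson berger_parker top10_cumulative percent_shared   bub emerging
1       10.79         0.238            0.695             NA    NA       NA
2        5.05         0.383            0.929             NA    NA       NA
3       10.29         0.256            0.694             NA    NA       NA
4        1.23         0.900            0.983             NA    NA       NA
5          NA            NA               NA           23.3 0.482        8
6          NA            NA               NA           10.2 0.320        8
```

Each sample row reports UMI-corrected molecule count, distinct CDR3
nucleotide sequences, inverse Simpson clonality, Berger–Parker dominance
and the cumulative fraction of the top 10 clones; treated samples are
smaller, more dominated (top-10 carries 93–98% of molecules) and less
even. Each comparison row reports the shared-clonotype percentage over the
pair's union, the BUB similarity, and the emerging-clone count — here both
donors recover exactly the 8 emerging clones the simulator planted.

Individual objects stay inspectable:

```r
rep <- bundle$repertoires[["d1_treated"]]
rep
#> Repertoire 'd1_treated' (donor d1, treated): 22 clonotypes, 240 molecules
#>   top clonotype: TGCGCCAGCAGTACCCGCTGTAGGAATTGTTACGAGCAGTACTTC (CASSTRCRNCYEQYF) fraction 0.3833
clonalDiversity(rep)$inv_simpson
#> [1] 5.049887
```

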