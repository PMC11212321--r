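# shared fixtures: the bundled reference and small hand-built repertoires

refFixture <- function() loadReference()

# the CDR3 printed for the dominant expanded clone of donor #1 (starts at the
# conserved TGT, ends at the J-PHE TTC)
PRINTED_CDR3 <- "TGTGCCAGCAGCGTAGAAGGGGTTCGGGATGAGCAGTTCTTC"

# distinct productive junctions: C (TGT GCC AGC AGC) + i encoded in non-stop
# codons + NEQFF-style tail ending at a TTC anchor
codonPool <- c("GCA", "GCC", "GGA", "GGC", "CTG", "CTC", "ACA", "ACC",
               "GTA", "GTC", "TCA", "TCC", "AGA", "AGC", "CAA", "CAC")
junctionFor <- function(i) {
  i <- i - 1L
  digits <- c(i %% 16L, (i %/% 16L) %% 16L, (i %/% 256L) %% 16L)
  paste0("TGTGCCAGCAGC", paste(codonPool[digits + 1L], collapse = ""),
         "GAGCAGTTCTTC")
}

# repertoire with the given molecule counts (and optional junctions/calls)
makeRep <- function(counts, junctions = NULL, v_call = "TRBV9*01",
                    j_call = "TRBJ2-1*01", sampleId = "s",
                    group = "unspecified") {
  n <- length(counts)
  if (is.null(junctions)) junctions <- vapply(seq_len(n), junctionFor,
                                              character(1))
  Repertoire(data.frame(cdr3_nt = junctions, v_call = v_call,
                        j_call = j_call, count = as.integer(counts)),
             sampleId = sampleId, group = group)
}

# repertoire over an abstract clonotype id set (ids mapped to junctions)
makeSetRep <- function(ids, sampleId, counts = NULL) {
  if (is.null(counts)) counts <- rep(1L, length(ids))
  makeRep(counts, junctions = vapply(ids, junctionFor, character(1)),
          sampleId = sampleId)
}

tinyZeroErrorConfig <- function(seed, ...) {
  simulationConfig(nClones = 25L, subErrorRate = 0,
                   readsPerMolecule = 2L, moleculesPerCloneScale = 6L,
                   seed = seed, ...)
}

# independent translation oracle (seqinr), for cross-checking productivity
oracleTranslate <- function(nt) {
  paste(seqinr::translate(strsplit(nt, "")[[1]]), collapse = "")
}
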